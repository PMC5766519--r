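#' @importFrom stats rnorm runif rbinom sd setNames
#' @importFrom utils write.csv read.csv packageVersion
NULL

#' Construct a topology object
#'
#' A topology holds the static atom metadata of a system: atom names,
#' elements, author residue numbers, residue names and chain identifiers.
#' Author residue numbering (303-552 for each monomer of the receptor
#' ligand-binding domain) is the only numbering exposed anywhere in the
#' package, because all the mechanistic signatures (E380, D351, K529, ...)
#' are stated in it.
#'
#' @param atoms data.frame with columns `name`, `element`, `resno`,
#'   `resname`, `chain` (one row per atom, file order).
#' @param chains character vector of allowed chain identifiers.
#' @return An object of class `topology`.
#' @export
topology <- function(atoms, chains = sort(unique(atoms$chain))) {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "element", "resno", "resname", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("no atoms")
  if (any(!nzchar(atoms$name)) || anyNA(atoms$name))
    stop("every atom must have a nonempty name")
  bad <- setdiff(unique(atoms$chain), chains)
  if (length(bad) > 0)
    stop("chain id(s) outside the declared set: ", paste(bad, collapse = ", "))
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch]
    if (any(diff(r) < 0))
      stop("residue numbers are not non-decreasing within chain ", ch)
  }
  # duplicate atom name within a residue is a modelling error, not an altloc
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key)) {
    d <- atoms[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate atom '", d$name, "' within residue ",
         d$chain, ":", d$resno)
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, n_atoms = nrow(atoms), chains = chains),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", x$n_atoms, " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), " residues, chains: ",
      paste(sort(unique(x$atoms$chain)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a topology from a PDB file
#'
#' Parses ATOM/HETATM records, preserving author residue numbers and chain
#' identifiers exactly as written. Only the first alternate location is
#' kept; insertion codes are not supported.
#'
#' @param path path to a PDB file.
#' @return A [topology] object.
#' @export
load_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no atoms in '", path, "'")
  short <- which(is_atom & nchar(lines) < 54)
  if (length(short) > 0)
    stop("malformed ATOM/HETATM record at line ", short[1], " of '", path,
         "' (record shorter than 54 columns)")
  ok_num <- function(s) !is.na(suppressWarnings(as.numeric(s)))
  xs <- substr(lines[is_atom], 31, 38)
  bad <- which(!ok_num(xs))
  if (length(bad) > 0)
    stop("malformed coordinate field at line ", which(is_atom)[bad[1]],
         " of '", path, "'")
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(!nzchar(trimws(elem))))
    elem <- substr(trimws(at$elety), 1, 1)
  atoms <- data.frame(
    name = trimws(at$elety),
    element = trimws(elem),
    resno = at$resno,
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    stringsAsFactors = FALSE
  )
  topology(atoms)
}

#' Write a topology (with one coordinate frame) to a PDB file
#'
#' @param top a [topology].
#' @param coords numeric matrix `n_atoms x 3`, Angstrom.
#' @param path output file.
#' @export
write_topology <- function(top, coords, path) {
  stopifnot(inherits(top, "topology"))
  coords <- as.matrix(coords)
  if (!all(dim(coords) == c(top$n_atoms, 3)))
    stop("coords must be n_atoms x 3")
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords)),
                   type = rep("ATOM", top$n_atoms),
                   resno = top$atoms$resno,
                   resid = top$atoms$resname,
                   eleno = seq_len(top$n_atoms),
                   elety = top$atoms$name,
                   chain = top$atoms$chain)
  invisible(path)
}

#' Construct a trajectory object
#'
#' @param coords numeric array `n_frames x n_atoms x 3`, Angstrom.
#' @param times numeric vector of frame times in ns, strictly increasing.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, times) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be an n_frames x n_atoms x 3 array")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  n <- dim(coords)[1]
  if (length(times) != n) stop("times length must equal the frame count")
  if (n > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(coords = coords, times = as.numeric(times),
                 n_frames = n, n_atoms = dim(coords)[2]),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$n_frames, " frames x ", x$n_atoms, " atoms, ",
      sprintf("%.4g", x$times[1]), "-", sprintf("%.4g", x$times[x$n_frames]),
      " ns\n", sep = "")
  invisible(x)
}

#' Extract one frame as an atoms-by-3 coordinate matrix
#' @param traj a [trajectory].
#' @param i frame index (1-based).
#' @export
traj_frame <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory"))
  if (i < 1 || i > traj$n_frames) stop("frame index out of range")
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  m
}

# frames x (3*n_atoms) interleaved matrix (x1,y1,z1,x2,...) -- the layout
# bio3d and the DCD format use
flatten_coords <- function(traj) {
  n <- traj$n_frames; na <- traj$n_atoms
  out <- matrix(0, n, 3 * na)
  for (d in 1:3) out[, seq(d, 3 * na, by = 3)] <- traj$coords[, , d]
  out
}

unflatten_coords <- function(xyz, n_atoms) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * n_atoms)
    stop("atom-count mismatch: expected ", n_atoms, " atoms, found ",
         ncol(xyz) / 3)
  arr <- array(0, c(nrow(xyz), n_atoms, 3))
  for (d in 1:3) arr[, , d] <- xyz[, seq(d, 3 * n_atoms, by = 3)]
  arr
}

#' Read a coordinate trajectory (multi-model PDB or DCD)
#'
#' Frame times are synthesised as `frame_index * dt_ns` starting at 0,
#' because the DCD dialect carries no trustworthy time stamps; the caller
#' supplies the sampling interval.
#'
#' @param path trajectory file; `.dcd` is read as CHARMM/NAMD DCD,
#'   anything else as a multi-model PDB.
#' @param top the matching [topology]; atom counts must agree.
#' @param dt_ns sampling interval in ns.
#' @return A [trajectory].
#' @export
load_trajectory <- function(path, top, dt_ns) {
  stopifnot(inherits(top, "topology"))
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (dt_ns <= 0) stop("dt_ns must be positive")
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
  }
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 0) stop("trajectory '", path, "' contains zero frames")
  if (ncol(xyz) != 3 * top$n_atoms)
    stop("atom-count mismatch: expected ", top$n_atoms,
         " atoms, found ", ncol(xyz) / 3, " in '", path, "'")
  trajectory(unflatten_coords(xyz, top$n_atoms),
             times = (seq_len(nrow(xyz)) - 1) * dt_ns)
}

#' Write a trajectory as a multi-model PDB
#' @param top a [topology].
#' @param traj a [trajectory].
#' @param path output file.
#' @export
write_trajectory_pdb <- function(top, traj, path) {
  stopifnot(inherits(top, "topology"), inherits(traj, "trajectory"))
  if (top$n_atoms != traj$n_atoms) stop("topology/trajectory atom-count mismatch")
  bio3d::write.pdb(file = path,
                   xyz = flatten_coords(traj),
                   type = rep("ATOM", top$n_atoms),
                   resno = top$atoms$resno,
                   resid = top$atoms$resname,
                   eleno = seq_len(top$n_atoms),
                   elety = top$atoms$name,
                   chain = top$atoms$chain)
  invisible(path)
}

#' Resolve an atom selection to ordered atom indices
#'
#' Filters are combined with AND; `NULL` means "no constraint". The result
#' is always in topology (file) order, so identical inputs yield identical
#' index lists.
#'
#' @param top a [topology].
#' @param chain chain id(s) or NULL.
#' @param resno residue number(s) or NULL.
#' @param name atom name(s) or NULL.
#' @param allow_empty if FALSE (default), an empty resolution is an error.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(top, chain = NULL, resno = NULL, name = NULL,
                         allow_empty = FALSE) {
  stopifnot(inherits(top, "topology"))
  keep <- rep(TRUE, top$n_atoms)
  if (!is.null(chain)) keep <- keep & top$atoms$chain %in% chain
  if (!is.null(resno)) keep <- keep & top$atoms$resno %in% resno
  if (!is.null(name))  keep <- keep & top$atoms$name %in% name
  idx <- which(keep)
  if (length(idx) == 0 && !allow_empty)
    stop("selection resolved to zero atoms (chain=",
         paste(chain, collapse = ","), " resno=",
         paste(resno, collapse = ","), " name=",
         paste(name, collapse = ","), ")")
  idx
}

#' Split a dimer into per-chain topology/trajectory views
#'
#' Monomers A and B are analysed separately throughout the assay (their
#' correlation maps and cluster populations differ), so every downstream
#' stage works on the views returned here. Frame count and times are
#' preserved; atom order within each chain is preserved.
#'
#' @param top a [topology].
#' @param traj a [trajectory] (optional).
#' @return Named list, one entry per chain, each a list with elements
#'   `topology` and (if `traj` given) `trajectory`.
#' @export
split_monomers <- function(top, traj = NULL) {
  stopifnot(inherits(top, "topology"))
  chains <- unique(top$atoms$chain)
  out <- list()
  for (ch in chains) {
    idx <- which(top$atoms$chain == ch)
    tch <- topology(top$atoms[idx, , drop = FALSE], chains = top$chains)
    ent <- list(topology = tch)
    if (!is.null(traj)) {
      stopifnot(inherits(traj, "trajectory"))
      ent$trajectory <- trajectory(traj$coords[, idx, , drop = FALSE],
                                   traj$times)
    }
    out[[ch]] <- ent
  }
  out
}

#' Restrict a trajectory to a set of frames
#' @param traj a [trajectory].
#' @param frames integer frame indices to keep (order preserved as given).
#' @export
subset_frames <- function(traj, frames) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(frames) == 0) stop("empty frame subset")
  if (any(frames < 1 | frames > traj$n_frames)) stop("frame index out of range")
  trajectory(traj$coords[frames, , , drop = FALSE], traj$times[frames])
}
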