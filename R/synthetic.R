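# Synthetic dimer trajectories with planted statistical structure.
#
# The generator emulates the statistical content of microsecond-scale
# ligand-binding-domain simulations -- inter-region correlated Calpha
# fluctuations, per-pair H-bond occupancies, conformer mixtures and
# per-segment helicity -- without any physical realism, so that every
# downstream analysis stage has an exact ground truth to be tested
# against.

# side-chain pseudo-atoms carried by the mechanistic signature residues;
# offsets are local Angstrom displacements from the Calpha
signature_sidechains <- function(isoform = "WT") {
  sc <- list(
    "348" = list(resname = "ASN",
                 atoms = list(OD1 = c(0.3, 2.4, 0.9), ND2 = c(-0.6, 2.6, 1.8),
                              HD21 = c(-1.3, 3.3, 2.4))),
    "351" = list(resname = "ASP",
                 atoms = list(OD1 = c(0.4, 2.5, 0.8), OD2 = c(-0.7, 2.7, 1.6))),
    "377" = list(resname = "HIS",
                 atoms = list(CG = c(0.0, 2.2, 0.8),
                              ND1 = c(1.1, 2.9, 1.1), CD2 = c(-1.0, 3.0, 1.0),
                              CE1 = c(0.8, 4.2, 1.4), NE2 = c(-0.5, 4.3, 1.4),
                              HD1 = c(2.1, 2.6, 1.1), HE2 = c(-1.1, 5.2, 1.6))),
    "380" = list(resname = "GLU",
                 atoms = list(OE1 = c(0.5, 3.0, 1.0), OE2 = c(-0.6, 3.2, 1.8))),
    "383" = list(resname = "TRP",
                 atoms = list(CZ2 = c(0.4, 2.9, 1.3), CH2 = c(-0.7, 3.1, 2.0))),
    "529" = list(resname = "LYS",
                 atoms = list(NZ = c(0.0, 3.4, 1.2), HZ1 = c(0.0, 4.4, 1.6))),
    "531" = list(resname = "LYS",
                 atoms = list(NZ = c(0.0, 3.4, 1.2), HZ1 = c(0.0, 4.4, 1.6))),
    "536" = list(resname = "LEU",
                 atoms = list(CD1 = c(0.7, 2.7, 1.1), CD2 = c(-0.8, 2.9, 1.7))),
    "537" = list(resname = "TYR",
                 atoms = list(CG = c(0.0, 2.2, 0.8),
                              CD1 = c(1.2, 2.9, 1.0), CD2 = c(-1.2, 2.9, 1.0),
                              CE1 = c(1.2, 4.3, 1.3), CE2 = c(-1.2, 4.3, 1.3),
                              CZ = c(0.0, 5.0, 1.5), OH = c(0.0, 6.4, 1.8),
                              HH = c(0.9, 7.0, 1.9))),
    "538" = list(resname = "ASP",
                 atoms = list(OD1 = c(0.4, 2.5, 0.8), OD2 = c(-0.7, 2.7, 1.6))),
    "539" = list(resname = "LEU",
                 atoms = list(CD1 = c(0.7, 2.7, 1.1), CD2 = c(-0.8, 2.9, 1.7))),
    "540" = list(resname = "LEU",
                 atoms = list(CD1 = c(0.7, 2.7, 1.1), CD2 = c(-0.8, 2.9, 1.7)))
  )
  if (isoform == "L536Q") {
    sc[["536"]] <- list(resname = "GLN",
                        atoms = list(OE1 = c(0.5, 3.0, 1.0),
                                     NE2 = c(-0.6, 3.2, 1.8),
                                     HE21 = c(-1.3, 4.0, 2.3)))
  } else if (isoform == "Y537S") {
    sc[["537"]] <- list(resname = "SER",
                        atoms = list(OG = c(0.0, 2.3, 0.9),
                                     HG = c(0.0, 3.3, 1.3)))
  } else if (isoform == "Y537N") {
    sc[["537"]] <- list(resname = "ASN",
                        atoms = list(OD1 = c(0.3, 2.4, 0.9),
                                     ND2 = c(-0.6, 2.6, 1.8),
                                     HD21 = c(-1.3, 3.3, 2.4)))
  } else if (isoform == "D538G") {
    sc[["538"]] <- list(resname = "GLY", atoms = list())
  } else if (isoform != "WT") {
    stop("unknown isoform '", isoform,
         "'; expected WT, L536Q, Y537S, Y537N or D538G")
  }
  sc
}

# Calpha path of one monomer: a wide, gently rising coil so consecutive
# residues are ~3.8 A apart, the chain is non-collinear, and successive
# turns stay ~12 A apart
monomer_ca_path <- function(n_res, origin = c(0, 0, 0)) {
  radius <- 30
  step_arc <- 3.8
  dphi <- step_arc / radius
  rise <- 12 / (2 * pi / dphi)   # 12 A per turn
  k <- seq_len(n_res) - 1
  phi <- k * dphi
  list(ca = cbind(origin[1] + radius * cos(phi),
                  origin[2] + radius * sin(phi),
                  origin[3] + k * rise),
       phi = phi)
}

# local atom offsets are expressed in a frame that follows the coil:
# x along the chain tangent, y radially outward, z vertical -- so
# side chains always point away from the path and the same local
# geometry holds at every residue
local_frame_offsets <- function(offs, phi) {
  u_t <- c(-sin(phi), cos(phi), 0)
  u_r <- c(cos(phi), sin(phi), 0)
  u_z <- c(0, 0, 1)
  offs %*% rbind(u_t, u_r, u_z)
}

backbone_offsets <- function() {
  list(N = c(-1.2, 0.0, 0.9), H = c(-1.8, 0.8, 0.9),
       C = c(1.2, 0.0, 0.9), O = c(1.7, 0.0, 1.9))
}

#' Build the synthetic reference dimer
#'
#' Constructs an idealised two-chain topology with residues 303-552 per
#' monomer: every residue carries Calpha plus backbone N, H, C, O at fixed
#' local offsets, and the mechanistic signature residues (E380, H377,
#' D351, N348, K529/K531, W383, 536-540 and the 537 variants) additionally
#' carry named side-chain pseudo-atoms, including the donor hydrogens the
#' geometric H-bond rule needs. The geometry is non-physical but
#' metrically valid: no two atoms are closer than 1 Angstrom.
#'
#' @param isoform one of `"WT"`, `"L536Q"`, `"Y537S"`, `"Y537N"`,
#'   `"D538G"`; controls residue 536/537/538 identity.
#' @param chains chain identifiers (default A and B).
#' @param first_res,last_res residue range per monomer.
#' @return list with elements `topology` and `coords`
#'   (`n_atoms x 3` reference frame, Angstrom).
#' @export
build_reference_dimer <- function(isoform = "WT", chains = c("A", "B"),
                                  first_res = 303, last_res = 552) {
  sc <- signature_sidechains(isoform)
  bb <- backbone_offsets()
  resnos <- first_res:last_res
  n_res <- length(resnos)
  rows <- list(); coords <- list()
  for (ci in seq_along(chains)) {
    ch <- chains[ci]
    # chains are separated by a large rigid offset
    path <- monomer_ca_path(n_res, origin = (ci - 1) * c(90, 0, 0))
    ca <- path$ca
    for (ri in seq_len(n_res)) {
      rn <- resnos[ri]
      entry <- sc[[as.character(rn)]]
      resname <- if (is.null(entry)) "ALA" else entry$resname
      names_i <- c("N", "CA", "C", "O", "H")
      offs <- rbind(bb$N, c(0, 0, 0), bb$C, bb$O, bb$H)
      if (!is.null(entry) && length(entry$atoms) > 0) {
        names_i <- c(names_i, names(entry$atoms))
        offs <- rbind(offs, do.call(rbind, entry$atoms))
      }
      rows[[length(rows) + 1]] <- data.frame(
        name = names_i,
        element = substr(names_i, 1, 1),
        resno = rn, resname = resname, chain = ch,
        stringsAsFactors = FALSE)
      coords[[length(coords) + 1]] <-
        sweep(local_frame_offsets(offs, path$phi[ri]), 2, ca[ri, ], "+")
    }
  }
  atoms <- do.call(rbind, rows)
  xyz <- do.call(rbind, coords)
  rownames(xyz) <- NULL
  list(topology = topology(atoms, chains = chains), coords = xyz)
}

# ideal alpha-helix backbone for a segment of n residues: Calpha on a
# 2.3 A / 1.5 A-rise / 100 deg-per-residue helix; carbonyl O placed on the
# segment between Calpha(i) and Calpha(i+4) and the amide H aimed at
# O(i-4), so interior residues satisfy the i -> i+4 H-bond rule exactly
helix_segment_coords <- function(n, anchor = c(0, 0, 0),
                                 conformation = c("helical", "extended")) {
  conformation <- match.arg(conformation)
  stopifnot(n >= 1)
  k <- seq_len(n) - 1
  if (conformation == "helical") {
    phi <- k * 100 * pi / 180
    ca <- cbind(anchor[1] + 1.5 * k,
                anchor[2] + 2.3 * (cos(phi) - 1),
                anchor[3] + 2.3 * sin(phi))
  } else {
    ca <- cbind(anchor[1] + 3.8 * k, anchor[2] + 0 * k, anchor[3] + 0 * k)
  }
  N <- H <- C <- O <- matrix(0, n, 3)
  bb <- backbone_offsets()
  for (i in seq_len(n)) {
    if (conformation == "helical") {
      N[i, ] <- if (i > 1) ca[i, ] + 0.30 * (ca[i - 1, ] - ca[i, ])
                else ca[i, ] + c(-1.2, 0.6, 0)
      O[i, ] <- if (i + 4 <= n) ca[i, ] + 0.55 * (ca[i + 4, ] - ca[i, ])
                else ca[i, ] + c(1.7, 1.9, 0)
      C[i, ] <- O[i, ] + c(0.0, 0.0, 1.25)
    } else {
      N[i, ] <- ca[i, ] + bb$N
      O[i, ] <- ca[i, ] + bb$O
      C[i, ] <- ca[i, ] + bb$C
    }
  }
  for (i in seq_len(n)) {
    if (conformation == "helical" && i > 4) {
      u <- O[i - 4, ] - N[i, ]
      H[i, ] <- N[i, ] + u / sqrt(sum(u^2))
    } else {
      H[i, ] <- N[i, ] + c(-0.6, 0.8, 0.0)
    }
  }
  list(CA = ca, N = N, H = H, C = C, O = O)
}

#' Specification for a synthetic trajectory
#'
#' @param seed integer master seed; a fixed seed makes the output
#'   bit-identical across runs.
#' @param n_frames number of frames.
#' @param dt_ns sampling interval in ns.
#' @param sigma per-coordinate Calpha fluctuation scale in Angstrom.
#' @param region_correlations list of plants, each a list with elements
#'   `region_a`, `chain_a`, `region_b`, `chain_b`, `rho` in `[-1, 1]`.
#'   Every residue pair across the two planted regions gets expected
#'   displacement correlation exactly `rho` (within-region pairs become
#'   equicorrelated at `|rho|`, the single-factor construction that keeps
#'   the covariance positive semi-definite).
#' @param hbond_plants list of plants, each a list with single-atom
#'   selections `donor`, `hydrogen`, `acceptor` (lists with `chain`,
#'   `resno`, `name`), an `occupancy` in `[0, 1]` and a `label`. In a
#'   formed frame the acceptor sits 2.8-3.1 A from the donor on the D-H
#'   axis (angular deviation 0); otherwise 4.5-6.5 A away.
#' @param cluster_mixture optional list with `weights` (summing to 1;
#'   first conformer is the reference) and `separation_rmsd` (Calpha RMSD
#'   between conformers, Angstrom, default 8).
#' @param helicity_plants list of plants, each a list with `chain`,
#'   `first`, `last`, `fraction`: the backbone of that segment adopts
#'   ideal-helix geometry in `fraction` of frames and stays extended
#'   otherwise.
#' @param isoform passed to [build_reference_dimer()].
#' @param atoms `"full"` (default) or `"calpha"`; the reduced form keeps
#'   only Calpha atoms, which is sufficient (and much lighter) for
#'   correlation studies.
#' @param keep_latent record the latent Calpha displacement draws in the
#'   ground truth (memory-heavy; off by default).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed, n_frames, dt_ns = 0.1, sigma = 1.0,
                           region_correlations = list(),
                           hbond_plants = list(),
                           cluster_mixture = NULL,
                           helicity_plants = list(),
                           isoform = "WT",
                           atoms = c("full", "calpha"),
                           keep_latent = FALSE) {
  atoms <- match.arg(atoms)
  stopifnot(n_frames >= 1, dt_ns > 0, sigma >= 0)
  for (p in region_correlations) {
    stopifnot(all(c("region_a", "chain_a", "region_b", "chain_b", "rho")
                  %in% names(p)))
    if (abs(p$rho) > 1) stop("|rho| must be <= 1")
  }
  for (p in hbond_plants) {
    stopifnot(all(c("donor", "hydrogen", "acceptor", "occupancy", "label")
                  %in% names(p)))
    if (p$occupancy < 0 || p$occupancy > 1)
      stop("occupancy must be in [0, 1]")
  }
  if (!is.null(cluster_mixture)) {
    w <- cluster_mixture$weights
    if (is.null(w) || abs(sum(w) - 1) > 1e-9)
      stop("cluster mixture weights must sum to 1")
    if (is.null(cluster_mixture$separation_rmsd))
      cluster_mixture$separation_rmsd <- 8
  }
  for (p in helicity_plants) {
    stopifnot(all(c("chain", "first", "last", "fraction") %in% names(p)))
    if (p$fraction < 0 || p$fraction > 1)
      stop("helical fraction must be in [0, 1]")
  }
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 dt_ns = dt_ns, sigma = sigma,
                 region_correlations = region_correlations,
                 hbond_plants = hbond_plants,
                 cluster_mixture = cluster_mixture,
                 helicity_plants = helicity_plants,
                 isoform = isoform, atoms = atoms,
                 keep_latent = keep_latent),
            class = "synthetic_spec")
}

# residue-level correlation matrix from the planted couplings
assemble_residue_correlation <- function(res_chain, res_no, plants, scheme) {
  n <- length(res_no)
  R <- diag(n)
  for (p in plants) {
    ia <- which(res_chain == p$chain_a &
                  res_no %in% region_residues(scheme, p$region_a))
    ib <- which(res_chain == p$chain_b &
                  res_no %in% region_residues(scheme, p$region_b))
    if (length(ia) == 0 || length(ib) == 0)
      stop("correlation plant references residues absent from the system (",
           p$region_a, "@", p$chain_a, " x ", p$region_b, "@", p$chain_b, ")")
    rho <- p$rho
    if (rho == 0) next
    R[ia, ia] <- abs(rho); R[ib, ib] <- abs(rho)
    R[ia, ib] <- rho; R[ib, ia] <- rho
    diag(R) <- 1
  }
  ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("planted correlation matrix is not positive semi-definite; ",
         "reduce |rho| or remove overlapping plants")
  R
}

#' Generate a synthetic dimer trajectory with known ground truth
#'
#' Per frame, each residue's Calpha is displaced from the reference by a
#' zero-mean multivariate normal draw whose residue-residue correlation
#' encodes the planted inter-region couplings; the three Cartesian
#' components are independent and identically correlated, so the expected
#' displacement cross-correlation of a planted residue pair is exactly
#' `rho`. Side-chain and backbone atoms ride rigidly with their Calpha.
#' Conformer mixtures add a fixed per-conformer displacement field;
#' H-bond plants then override the acceptor-atom position frame by frame,
#' and helicity plants override segment backbones with ideal-helix or
#' extended template geometry.
#'
#' @param spec a [synthetic_spec].
#' @param scheme region scheme used to resolve plant regions.
#' @return list with elements `topology`, `trajectory` and `truth`
#'   (a list: `frames` data.frame of per-frame latent labels, plus
#'   `latent` displacement draws when requested).
#' @export
generate_trajectory <- function(spec, scheme = default_region_scheme()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ref <- build_reference_dimer(spec$isoform)
  top <- ref$topology; base <- ref$coords
  if (spec$atoms == "calpha") {
    idx <- which(top$atoms$name == "CA")
    top <- topology(top$atoms[idx, , drop = FALSE], chains = top$chains)
    base <- base[idx, , drop = FALSE]
  }
  n <- spec$n_frames
  at <- top$atoms
  res_key <- paste(at$chain, at$resno)
  res_uniq <- unique(res_key)
  res_of_atom <- match(res_key, res_uniq)
  ca_rows <- which(at$name == "CA")
  res_chain <- at$chain[ca_rows][match(res_uniq, res_key[ca_rows])]
  res_no <- at$resno[ca_rows][match(res_uniq, res_key[ca_rows])]
  n_res <- length(res_uniq)

  set.seed(spec$seed)
  R <- assemble_residue_correlation(res_chain, res_no,
                                    spec$region_correlations, scheme)
  U <- chol(R)
  lat <- vector("list", 3)
  for (d in 1:3) {
    Z <- matrix(rnorm(n * n_res), n, n_res)
    lat[[d]] <- (Z %*% U) * spec$sigma
  }

  # conformer mixture: deterministic per-conformer displacement fields
  mix <- spec$cluster_mixture
  labels <- rep(1L, n)
  deltas <- NULL
  if (!is.null(mix)) {
    K <- length(mix$weights)
    labels <- sample.int(K, n, replace = TRUE, prob = mix$weights)
    deltas <- vector("list", K)
    deltas[[1]] <- matrix(0, n_res, 3)
    for (k in seq_len(K)[-1]) {
      d0 <- matrix(rnorm(n_res * 3), n_res, 3)
      d0 <- d0 * mix$separation_rmsd / sqrt(mean(rowSums(d0^2)))
      deltas[[k]] <- d0
    }
  }

  coords <- array(0, c(n, nrow(at), 3))
  for (d in 1:3) {
    disp <- lat[[d]][, res_of_atom, drop = FALSE]
    if (!is.null(deltas)) {
      dk <- vapply(deltas, function(m) m[, d], numeric(n_res))  # n_res x K
      disp <- disp + t(dk)[labels, res_of_atom, drop = FALSE]
    }
    coords[, , d] <- matrix(base[, d], n, nrow(at), byrow = TRUE) + disp
  }

  truth_frames <- data.frame(frame = seq_len(n),
                             time_ns = (seq_len(n) - 1) * spec$dt_ns,
                             conformer = labels)

  # helicity plants: override segment backbone with template geometry
  for (p in spec$helicity_plants) {
    seg_res <- p$first:p$last
    helical <- runif(n) < p$fraction
    tpl_h <- helix_segment_coords(length(seg_res),
                                  conformation = "helical")
    tpl_e <- helix_segment_coords(length(seg_res),
                                  conformation = "extended")
    a0 <- select_atoms(top, chain = p$chain, resno = p$first, name = "CA")
    anchor <- base[a0, ]
    # template coordinates are anchored at the reference position of the
    # segment's first Calpha; no per-residue noise inside the segment, so
    # the planted per-frame helicity labels are exact ground truth
    for (w in c("CA", "N", "H", "C", "O")) {
      for (si in seq_along(seg_res)) {
        ai <- select_atoms(top, chain = p$chain, resno = seg_res[si],
                           name = w, allow_empty = TRUE)
        if (length(ai) == 0) next
        for (d in 1:3) {
          coords[helical, ai, d] <- anchor[d] + tpl_h[[w]][si, d]
          coords[!helical, ai, d] <- anchor[d] + tpl_e[[w]][si, d]
        }
      }
    }
    truth_frames[[paste0("helical_", p$chain, "_", p$first, "_", p$last)]] <-
      helical
  }

  # H-bond plants: place the acceptor relative to the current donor/H
  for (p in spec$hbond_plants) {
    di <- do.call(select_atoms, c(list(top), p$donor))
    hi <- do.call(select_atoms, c(list(top), p$hydrogen))
    ai <- do.call(select_atoms, c(list(top), p$acceptor))
    if (length(di) != 1 || length(hi) != 1 || length(ai) != 1)
      stop("H-bond plant '", p$label,
           "' must resolve to single donor/hydrogen/acceptor atoms")
    formed <- runif(n) < p$occupancy
    dist <- ifelse(formed, runif(n, 2.8, 3.1), runif(n, 4.5, 6.5))
    D <- coords[, di, , drop = FALSE]; dim(D) <- c(n, 3)
    H <- coords[, hi, , drop = FALSE]; dim(H) <- c(n, 3)
    u <- H - D
    u <- u / sqrt(rowSums(u^2))
    A <- D + u * dist
    for (d in 1:3) coords[, ai, d] <- A[, d]
    truth_frames[[paste0("hbond_", make.names(p$label))]] <- formed
  }

  truth <- list(frames = truth_frames,
                residues = data.frame(chain = res_chain, resno = res_no))
  if (spec$keep_latent) truth$latent <- lat
  list(topology = top,
       trajectory = trajectory(coords, times = (seq_len(n) - 1) * spec$dt_ns),
       truth = truth)
}

#' Write a synthetic fixture to disk
#'
#' Emits `topology.pdb`, `traj.pdb` (multi-model), `traj.dcd`,
#' `truth.csv` and, if a spec is given, `spec.yaml`. Re-running with the
#' same inputs overwrites each file with identical bytes.
#'
#' @param top a [topology].
#' @param traj a [trajectory].
#' @param dir output directory (created if needed).
#' @param truth optional ground-truth list from [generate_trajectory()].
#' @param spec optional [synthetic_spec] echoed as YAML.
#' @return Named character vector of the files written.
#' @export
write_fixture <- function(top, traj, dir, truth = NULL, spec = NULL) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create fixture directory '", dir, "'")
  files <- c(topology = file.path(dir, "topology.pdb"),
             traj_pdb = file.path(dir, "traj.pdb"),
             traj_dcd = file.path(dir, "traj.dcd"))
  write_topology(top, traj_frame(traj, 1), files[["topology"]])
  write_trajectory_pdb(top, traj, files[["traj_pdb"]])
  write_trajectory_dcd(traj, files[["traj_dcd"]])
  if (!is.null(truth)) {
    files[["truth"]] <- file.path(dir, "truth.csv")
    write.csv(truth$frames, files[["truth"]], row.names = FALSE)
  }
  if (!is.null(spec)) {
    files[["spec"]] <- file.path(dir, "spec.yaml")
    dump <- spec
    class(dump) <- NULL
    writeLines(yaml::as.yaml(dump), files[["spec"]])
  }
  files
}
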