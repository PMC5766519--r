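# Superposition, fluctuation and clustering machinery: Kabsch fits,
# RMSD/RMSF, equilibration-window detection, GROMOS (Daura) clustering and
# alpha-helix content tracking.

#' Optimal rigid superposition of two structures (Kabsch)
#'
#' Least-squares optimal proper rotation (det = +1) and translation
#' mapping `mobile` onto `reference`, computed by singular value
#' decomposition of the covariance of the centered coordinate sets.
#'
#' @param mobile,reference `n x 3` coordinate matrices with matching rows.
#' @param sel optional row indices to fit on (the returned RMSD refers to
#'   these atoms).
#' @return list with `rotation` (3x3, apply as
#'   `sweep(mobile, 2, center_mobile) %*% rotation + center_reference`),
#'   `center_mobile`, `center_reference`, and the post-fit `rmsd` in
#'   Angstrom.
#' @export
kabsch_superpose <- function(mobile, reference, sel = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!is.null(sel)) {
    mobile <- mobile[sel, , drop = FALSE]
    reference <- reference[sel, , drop = FALSE]
  }
  if (nrow(mobile) != nrow(reference))
    stop("mobile and reference must have equal atom counts")
  if (nrow(mobile) < 3) stop("superposition under-determined: need >= 3 atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); R <- sweep(reference, 2, cr)
  if (svd(R)$d[2] < 1e-8 || svd(M)$d[2] < 1e-8)
    stop("degenerate (collinear) atom selection: rotation not determined")
  A <- crossprod(M, R)                       # 3 x 3
  sv <- svd(A)
  s <- sign(det(sv$u) * det(sv$v))
  D <- diag(c(1, 1, s))
  rot <- sv$u %*% D %*% t(sv$v)
  fitted <- M %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - R)^2)))
  list(rotation = rot, center_mobile = cm, center_reference = cr,
       rmsd = rmsd)
}

# RMSD after optimal superposition without building the rotation: the
# Kabsch/Theobald identity rmsd^2 = (Ga + Gb - 2*sum(d~)) / n, where d~
# are the singular values of the 3x3 covariance with the smallest one
# sign-flipped if the fit would be improper. Used in the O(n^2) pairwise
# loops where speed matters.
fit_rmsd_centered <- function(A, B, Ga, Gb) {
  M <- crossprod(A, B)
  sv <- svd(M)
  d <- sv$d
  if (det(M) < 0) d[3] <- -d[3]
  sqrt(max(0, (Ga + Gb - 2 * sum(d)) / nrow(A)))
}

#' Per-frame RMSD of a trajectory against a reference structure
#'
#' Each frame is optimally superposed (Kabsch) on the reference over the
#' selected atoms before the RMSD is taken.
#'
#' @param traj a [trajectory].
#' @param reference `n_atoms x 3` matrix (default: the first frame).
#' @param sel atom indices to fit/measure on (default: all).
#' @return Numeric vector of per-frame RMSD, Angstrom.
#' @export
rmsd_series <- function(traj, reference = NULL, sel = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(reference)) reference <- traj_frame(traj, 1)
  if (is.null(sel)) sel <- seq_len(traj$n_atoms)
  ref <- as.matrix(reference)[sel, , drop = FALSE]
  ref_c <- sweep(ref, 2, colMeans(ref))
  Gr <- sum(ref_c^2)
  vapply(seq_len(traj$n_frames), function(f) {
    m <- traj$coords[f, sel, , drop = FALSE]
    dim(m) <- c(length(sel), 3)
    m <- sweep(m, 2, colMeans(m))
    fit_rmsd_centered(m, ref_c, sum(m^2), Gr)
  }, numeric(1))
}

#' Detect the equilibrated portion of an RMSD series
#'
#' Returns the earliest time `t` such that the running mean of the series
#' over `[t, end]` stays within `tol` of the final mean for at least
#' `min_plateau` of the remaining frames. The equilibrated portion must
#' span at least `min_remaining` of the trajectory; without that floor a
#' short enough tail of any drifting series trivially "plateaus". A series
#' that never satisfies the rule yields `NA` (not converged), not an
#' error.
#'
#' @param series numeric RMSD series, Angstrom.
#' @param times frame times in ns (same length).
#' @param tol plateau tolerance, Angstrom.
#' @param min_plateau minimum fraction of remaining frames whose running
#'   mean must sit within `tol` of the final mean.
#' @param min_remaining minimum fraction of the trajectory the plateau
#'   must cover.
#' @return Start time in ns, or `NA_real_` if the series never converges.
#' @export
detect_equilibration <- function(series, times, tol = 0.5,
                                 min_plateau = 0.95, min_remaining = 0.5) {
  n <- length(series)
  if (n < 10) stop("need at least 10 frames")
  if (length(times) != n) stop("times must match the series length")
  last_start <- n - ceiling(min_remaining * n) + 1
  for (s in seq_len(max(1, last_start))) {
    x <- series[s:n]
    run <- cumsum(x) / seq_along(x)
    frac <- mean(abs(run - run[length(run)]) <= tol)
    if (frac >= min_plateau) return(times[s])
  }
  NA_real_
}

#' Root-mean-square fluctuation per selected atom
#'
#' `RMSF_i = sqrt(<|r_i - <r_i>|^2>)` over the window frames of an
#' aligned trajectory.
#'
#' @param traj an aligned [trajectory].
#' @param sel atom indices (default all).
#' @param window frame indices to analyse (default all).
#' @return Numeric vector of per-atom RMSF, Angstrom.
#' @export
rmsf <- function(traj, sel = NULL, window = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(sel)) sel <- seq_len(traj$n_atoms)
  if (is.null(window)) window <- seq_len(traj$n_frames)
  if (length(window) < 2) stop("RMSF needs at least 2 frames")
  out <- numeric(length(sel))
  for (d in 1:3) {
    X <- traj$coords[window, sel, d, drop = FALSE]
    dim(X) <- c(length(window), length(sel))
    X <- sweep(X, 2, colMeans(X))
    out <- out + colMeans(X^2)
  }
  sqrt(out)
}

# all-pairs post-fit RMSD matrix over the selected atoms
pairwise_rmsd <- function(traj, sel = NULL, window = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(sel)) sel <- seq_len(traj$n_atoms)
  if (is.null(window)) window <- seq_len(traj$n_frames)
  n <- length(window)
  frames <- vector("list", n)
  G <- numeric(n)
  for (i in seq_len(n)) {
    m <- traj$coords[window[i], sel, , drop = FALSE]
    dim(m) <- c(length(sel), 3)
    m <- sweep(m, 2, colMeans(m))
    frames[[i]] <- m
    G[i] <- sum(m^2)
  }
  D <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      Ai <- frames[[i]]; Gi <- G[i]
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- fit_rmsd_centered(Ai, frames[[j]], Gi, G[j])
      }
    }
  }
  D
}

#' GROMOS (Daura) conformational clustering
#'
#' Greedy neighbour-count clustering of frames under a pairwise post-fit
#' RMSD cutoff: repeatedly take the frame with the most neighbours within
#' the cutoff (ties broken by the lowest frame index) as a cluster centre
#' together with its neighbours, remove them, and continue until no frame
#' remains. Clusters are reported in decreasing population order.
#'
#' @param traj a [trajectory] (typically one monomer).
#' @param top matching [topology]; used to resolve the default selection.
#' @param rmsd_cutoff RMSD cutoff in Angstrom (default 2.75).
#' @param sel atom indices for the RMSD (default: Calpha).
#' @param window frame indices to cluster (default all).
#' @return Object of class `cluster_result`: `assignment` (cluster id per
#'   window frame, 1 = most populated), `centers` (frame indices, window
#'   numbering), `populations` (%, decreasing), `window`.
#' @export
daura_cluster <- function(traj, top = NULL, rmsd_cutoff = 2.75, sel = NULL,
                          window = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (rmsd_cutoff <= 0) stop("rmsd_cutoff must be > 0")
  if (is.null(sel)) {
    sel <- if (!is.null(top)) select_atoms(top, name = "CA")
           else seq_len(traj$n_atoms)
  }
  if (is.null(window)) window <- seq_len(traj$n_frames)
  n <- length(window)
  D <- pairwise_rmsd(traj, sel = sel, window = window)
  adj <- D <= rmsd_cutoff          # includes self
  remaining <- rep(TRUE, n)
  assignment <- integer(n)
  centers <- integer(0)
  sizes <- integer(0)
  k <- 0L
  while (any(remaining)) {
    counts <- colSums(adj[remaining, , drop = FALSE])
    counts[!remaining] <- -1L
    center <- which.max(counts)    # ties -> lowest index
    members <- which(remaining & adj[, center])
    k <- k + 1L
    assignment[members] <- k
    centers[k] <- center
    sizes[k] <- length(members)
    remaining[members] <- FALSE
  }
  # report in decreasing population order (discovery order breaks ties)
  ord <- order(-sizes, seq_along(sizes))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  structure(list(assignment = relabel[assignment],
                 centers = centers[ord],
                 populations = 100 * sizes[ord] / n,
                 n_frames = n, window = window,
                 rmsd_cutoff = rmsd_cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$populations), " clusters over ",
      x$n_frames, " frames (cutoff ", x$rmsd_cutoff, " A)\n", sep = "")
  show <- utils::head(seq_along(x$populations), 5)
  for (i in show)
    cat(sprintf("  #%d: %.1f%% (center frame %d)\n", i, x$populations[i],
                x$window[x$centers[i]]))
  invisible(x)
}

#' Centre frame of the rank-th most populated cluster
#'
#' @param result a `cluster_result`.
#' @param rank 1-based population rank (1 = most populated).
#' @param traj optional [trajectory]; when given, the centre frame's
#'   coordinates are returned instead of its index.
#' @return Frame index (trajectory numbering), or an `n_atoms x 3` matrix.
#' @export
representative_structure <- function(result, rank = 1, traj = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  if (rank < 1 || rank > length(result$centers))
    stop("rank ", rank, " out of range: ", length(result$centers),
         " cluster(s)")
  idx <- result$window[result$centers[rank]]
  if (is.null(traj)) idx else traj_frame(traj, idx)
}

#' Alpha-helix assignment by the i -> i+4 backbone hydrogen bond
#'
#' A residue is helical in a frame iff the backbone hydrogen bond
#' `C=O(i-4) ... H-N(i)` it accepts from, or `O(i) ... H-N(i+4)` it
#' donates to, satisfies the geometric rule `d(O, N) <= d_max` and
#' deviation of N-H...O from linearity `<= theta_max`. This is an
#' alpha-helix-only criterion (3_10 and pi helices are not classed),
#' sufficient for tracking helical content of a segment.
#'
#' @param traj a [trajectory].
#' @param top matching [topology]; backbone N, H, O atoms are required.
#' @param window frame indices (default all).
#' @param chains chains to assign (default: all in the topology).
#' @param d_max O(i-4)..N(i) distance cutoff, Angstrom.
#' @param theta_max maximum deviation of the N-H...O angle from 180 deg.
#' @return Object of class `helix_assignment`: `helical` (frames x
#'   residues logical matrix, columns `chain:resno`), `content`
#'   (per-residue % of frames helical), `residues`.
#' @export
assign_helix <- function(traj, top, window = NULL, chains = NULL,
                         d_max = 3.5, theta_max = 40) {
  stopifnot(inherits(traj, "trajectory"), inherits(top, "topology"))
  if (is.null(window)) window <- seq_len(traj$n_frames)
  if (is.null(chains)) chains <- unique(top$atoms$chain)
  cols <- list(); labels <- character(0); res_tab <- list()
  for (ch in chains) {
    resnos <- sort(unique(top$atoms$resno[top$atoms$chain == ch]))
    get1 <- function(rn, nm) {
      idx <- select_atoms(top, chain = ch, resno = rn, name = nm,
                          allow_empty = TRUE)
      if (length(idx) == 0) 0L else idx[1]
    }
    iN <- vapply(resnos, get1, integer(1), nm = "N")
    iH <- vapply(resnos, get1, integer(1), nm = "H")
    iO <- vapply(resnos, get1, integer(1), nm = "O")
    miss <- resnos[iN == 0 | iH == 0 | iO == 0]
    if (length(miss) > 0)
      stop("missing backbone N/H/O atoms on chain ", ch, " residue(s): ",
           paste(utils::head(miss, 10), collapse = ", "))
    nr <- length(resnos)
    # bond[f, i] : O(i-4) ... H-N(i) present (i indexes resnos)
    bond <- matrix(FALSE, length(window), nr)
    seq_ok <- seq_len(nr)[-(1:4)]
    # only i-4 partners that are sequence neighbours four apart
    seq_ok <- seq_ok[resnos[seq_ok] - resnos[seq_ok - 4] == 4]
    for (i in seq_ok) {
      O <- traj$coords[window, iO[i - 4], , drop = FALSE]
      N <- traj$coords[window, iN[i], , drop = FALSE]
      H <- traj$coords[window, iH[i], , drop = FALSE]
      dim(O) <- dim(N) <- dim(H) <- c(length(window), 3)
      dON <- sqrt(rowSums((O - N)^2))
      u <- N - H; v <- O - H
      cosang <- rowSums(u * v) /
        (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      bond[, i] <- dON <= d_max & (180 - ang) <= theta_max
    }
    helical <- bond
    helical[, seq_len(nr - 4)] <- helical[, seq_len(nr - 4)] |
      bond[, 5:nr]
    cols[[ch]] <- helical
    labels <- c(labels, paste0(ch, ":", resnos))
    res_tab[[ch]] <- data.frame(chain = ch, resno = resnos,
                                stringsAsFactors = FALSE)
  }
  helical <- do.call(cbind, cols)
  colnames(helical) <- labels
  residues <- do.call(rbind, res_tab)
  rownames(residues) <- NULL
  structure(list(helical = helical,
                 content = 100 * colMeans(helical),
                 residues = residues, window = window,
                 d_max = d_max, theta_max = theta_max),
            class = "helix_assignment")
}

#' Mean helical content of a residue segment
#'
#' @param ha a `helix_assignment`.
#' @param chain chain id.
#' @param first,last inclusive residue range.
#' @return Mean per-residue helical content of the segment, in percent.
#' @export
segment_helicity <- function(ha, chain, first, last) {
  stopifnot(inherits(ha, "helix_assignment"))
  keep <- ha$residues$chain == chain & ha$residues$resno >= first &
    ha$residues$resno <= last
  if (!any(keep)) stop("segment resolves to no residues")
  mean(ha$content[keep])
}
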