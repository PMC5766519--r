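# Dynamic cross-correlation analysis and the helix-12 activation metric.
#
# The assay's central quantity is the normalized covariance of per-residue
# Calpha displacement vectors,
#   C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>),
# aggregated over residue regions with a +/-0.6 coefficient threshold, and
# summed per helix-12 residue against H3/H5 to give the activation score
# whose reference value is 4.

#' Iteratively superpose all frames onto their mean structure
#'
#' The fit is a single joint fit of the selected atoms (for a dimer: the
#' whole dimer Calpha set), because correlations *between* monomers are
#' only meaningful in a common frame of reference. The classic iterative
#' scheme is used: fit all frames to the current mean, recompute the mean,
#' repeat until the mean moves less than `tol` (RMSD, Angstrom).
#'
#' @param traj a [trajectory].
#' @param sel atom indices to fit on (default: all atoms).
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the mean shift, Angstrom.
#' @return list with `trajectory` (aligned; all atoms transformed) and
#'   `mean` (converged mean of the selected atoms).
#' @export
superpose_to_mean <- function(traj, sel = NULL, max_iter = 10, tol = 1e-4) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$n_frames < 2) stop("need at least 2 frames to superpose")
  if (is.null(sel)) sel <- seq_len(traj$n_atoms)
  if (length(sel) < 3) stop("superposition under-determined: fewer than 3 atoms selected")
  coords <- traj$coords
  ref <- traj_frame(traj, 1)[sel, , drop = FALSE]
  for (it in seq_len(max_iter)) {
    for (f in seq_len(traj$n_frames)) {
      frm <- coords[f, , , drop = FALSE]; dim(frm) <- dim(coords)[2:3]
      fit <- kabsch_superpose(frm[sel, , drop = FALSE], ref)
      moved <- sweep(frm, 2, fit$center_mobile) %*% fit$rotation
      moved <- sweep(moved, 2, fit$center_reference, "+")
      coords[f, , ] <- moved
    }
    new_mean <- apply(coords[, sel, , drop = FALSE], c(2, 3), mean)
    shift <- sqrt(mean(rowSums((new_mean - ref)^2)))
    ref <- new_mean
    if (shift < tol) break
  }
  list(trajectory = trajectory(coords, traj$times), mean = ref,
       iterations = it)
}

#' Compute the dynamic cross-correlation matrix (DCCM)
#'
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` with
#' `dr_i = r_i - <r_i>`, over the frames of an aligned trajectory.
#' Residues whose positional variance is (numerically) zero get NaN rows
#' and columns and a warning; a fully static trajectory is an error.
#'
#' @param traj an aligned [trajectory].
#' @param top the matching [topology].
#' @param sel atom indices of the residue markers (default: all Calpha).
#' @return Object of class `dccm_matrix`: list with `C` (symmetric matrix,
#'   labelled `chain:resno`) and `residues` (data.frame `chain`, `resno`).
#' @export
compute_dccm <- function(traj, top, sel = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(top, "topology"))
  if (traj$n_frames < 2) stop("need at least 2 frames")
  if (is.null(sel)) sel <- select_atoms(top, name = "CA")
  n <- traj$n_frames
  labels <- paste0(top$atoms$chain[sel], ":", top$atoms$resno[sel])
  # covariance of displacement vectors: sum the per-component covariances
  Dsum <- 0
  for (d in 1:3) {
    X <- traj$coords[, sel, d, drop = FALSE]
    dim(X) <- c(n, length(sel))
    X <- sweep(X, 2, colMeans(X))
    Dsum <- Dsum + crossprod(X) / n
  }
  v <- diag(Dsum)
  zero <- v < 1e-12
  if (all(zero)) stop("degenerate trajectory: every residue has zero variance")
  if (any(zero))
    warning("zero-variance residue(s) set to NaN: ",
            paste(labels[zero], collapse = ", "))
  s <- sqrt(v)
  s[zero] <- NaN
  C <- Dsum / tcrossprod(s)
  C <- (C + t(C)) / 2
  diag(C)[!zero] <- 1
  dimnames(C) <- list(labels, labels)
  structure(list(C = C,
                 residues = data.frame(chain = top$atoms$chain[sel],
                                       resno = top$atoms$resno[sel],
                                       stringsAsFactors = FALSE)),
            class = "dccm_matrix")
}

#' @export
print.dccm_matrix <- function(x, ...) {
  cat("<dccm_matrix> ", nrow(x$C), " residues, range [",
      sprintf("%.3f", min(x$C, na.rm = TRUE)), ", ",
      sprintf("%.3f", max(x$C, na.rm = TRUE)), "]\n", sep = "")
  invisible(x)
}

# residue-label indices of one region on one chain, with error reporting
region_matrix_indices <- function(cm, scheme, region, chain) {
  idx <- which(cm$residues$chain == chain &
                 cm$residues$resno %in% region_residues(scheme, region))
  if (length(idx) == 0)
    stop("region ", region, " on chain ", chain,
         " resolves to no residues in the correlation matrix")
  idx
}

#' Aggregate a DCCM into a region-by-region score map
#'
#' `S(A, B) = sum_{i in A, j in B} C_ij * 1[C_ij >= tau or C_ij <= -tau]`;
#' the threshold is inclusive. Self pairs (i = j) are excluded on diagonal
#' blocks, and NaN entries (zero-variance residues) contribute nothing.
#' In `per_pair_mean` mode (the default used for region-map displays) the
#' sum is divided by `|A| * |B|`.
#'
#' @param cm a `dccm_matrix` from [compute_dccm()].
#' @param scheme a [region_scheme].
#' @param chain_a,chain_b which monomer block to aggregate (defaults: the
#'   first chain in the matrix, against itself).
#' @param threshold coefficient threshold `tau` (>= 0), default 0.6.
#' @param normalization `"per_pair_mean"` or `"raw_sum"`.
#' @return Object of class `region_score_map`: the score matrix in `S`
#'   plus the parameters used.
#' @export
aggregate_region_scores <- function(cm, scheme = default_region_scheme(),
                                    chain_a = NULL, chain_b = NULL,
                                    threshold = 0.6,
                                    normalization = c("per_pair_mean",
                                                      "raw_sum")) {
  stopifnot(inherits(cm, "dccm_matrix"))
  normalization <- match.arg(normalization)
  if (threshold < 0) stop("threshold must be >= 0")
  if (is.null(chain_a)) chain_a <- cm$residues$chain[1]
  if (is.null(chain_b)) chain_b <- chain_a
  rn <- scheme$regions$region
  S <- matrix(0, length(rn), length(rn), dimnames = list(rn, rn))
  for (a in seq_along(rn)) {
    ia <- region_matrix_indices(cm, scheme, rn[a], chain_a)
    for (b in seq_along(rn)) {
      ib <- region_matrix_indices(cm, scheme, rn[b], chain_b)
      blk <- cm$C[ia, ib, drop = FALSE]
      if (chain_a == chain_b && a == b) {
        # exclude self pairs i = j
        diag(blk) <- NA
      }
      keep <- !is.na(blk) & abs(blk) >= threshold
      s <- sum(blk[keep])
      if (normalization == "per_pair_mean") s <- s / (length(ia) * length(ib))
      S[a, b] <- s
    }
  }
  structure(list(S = S, threshold = threshold, normalization = normalization,
                 chain_a = chain_a, chain_b = chain_b),
            class = "region_score_map")
}

#' @export
print.region_score_map <- function(x, ...) {
  cat("<region_score_map> chains ", x$chain_a, "x", x$chain_b,
      ", tau = ", x$threshold, ", ", x$normalization, "\n", sep = "")
  print(round(x$S, 3))
  invisible(x)
}

#' Per-residue helix-12 correlation profile
#'
#' For each H12 residue `i` and each other region `R`,
#' `s_i(R) = sum_{j in R} C_ij * 1[|C_ij| >= tau]` (raw sum, no
#' normalization -- the activation reference value of 4 is defined on this
#' scale). Region totals are the sums of the per-residue entries.
#'
#' @param cm a `dccm_matrix`.
#' @param scheme a [region_scheme].
#' @param chain monomer to profile (default: first chain in the matrix).
#' @param threshold coefficient threshold, default 0.6.
#' @param h12 name of the mobile-helix region in the scheme.
#' @return Object of class `h12_profile`: `per_residue` (residues x
#'   regions matrix) and `totals` (named numeric, one per target region).
#' @export
h12_profile <- function(cm, scheme = default_region_scheme(), chain = NULL,
                        threshold = 0.6, h12 = "H12") {
  stopifnot(inherits(cm, "dccm_matrix"))
  if (threshold < 0) stop("threshold must be >= 0")
  if (is.null(chain)) chain <- cm$residues$chain[1]
  ih <- region_matrix_indices(cm, scheme, h12, chain)
  targets <- setdiff(scheme$regions$region, h12)
  P <- matrix(0, length(ih), length(targets),
              dimnames = list(rownames(cm$C)[ih], targets))
  for (b in seq_along(targets)) {
    ib <- region_matrix_indices(cm, scheme, targets[b], chain)
    blk <- cm$C[ih, ib, drop = FALSE]
    keep <- !is.na(blk) & abs(blk) >= threshold
    P[, b] <- rowSums(blk * keep, na.rm = TRUE)
  }
  structure(list(per_residue = P, totals = colSums(P), chain = chain,
                 threshold = threshold),
            class = "h12_profile")
}

#' @export
print.h12_profile <- function(x, ...) {
  cat("<h12_profile> chain ", x$chain, ", tau = ", x$threshold, "\n",
      sep = "")
  tot <- sort(x$totals, decreasing = TRUE)
  print(round(tot[tot != 0], 3))
  invisible(x)
}

#' Classify receptor activation and drug efficacy from H12 profiles
#'
#' Per monomer, the activation score is `max(H12-H3, H12-H5)` region
#' total. Scores at or above the activation threshold (default 4, the
#' reference value observed for the estrogen-bound wild type) classify as
#' `high` (agonist-like active state); scores in the intermediate band
#' (default `[2, 4)`) as `intermediate`; below as `low`. A bound
#' antagonist is judged effective iff *both* monomers score below the
#' activation threshold.
#'
#' @param profiles named list of [h12_profile] objects, one per monomer.
#' @param activation_threshold score at/above which a monomer is active.
#' @param intermediate_lower lower edge of the intermediate band.
#' @return Object of class `activation_verdict`: data.frame with one row
#'   per monomer (`monomer`, `score_h3`, `score_h5`, `score`, `tier`) and
#'   attribute `effective`.
#' @export
classify_activation <- function(profiles, activation_threshold = 4,
                                intermediate_lower = 2) {
  if (activation_threshold <= 0) stop("activation threshold must be > 0")
  if (inherits(profiles, "h12_profile")) profiles <- list(profiles)
  if (length(profiles) == 0) stop("no profiles supplied")
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    stopifnot(inherits(p, "h12_profile"))
    if (!all(c("H3", "H5") %in% names(p$totals)))
      stop("profile for monomer ", p$chain, " lacks H3/H5 scores")
    s3 <- unname(p$totals["H3"]); s5 <- unname(p$totals["H5"])
    s <- max(s3, s5)
    tier <- if (s >= activation_threshold) "high"
            else if (s >= intermediate_lower) "intermediate" else "low"
    data.frame(monomer = p$chain, score_h3 = s3, score_h5 = s5,
               score = s, tier = tier, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "effective") <- all(out$score < activation_threshold)
  attr(out, "activation_threshold") <- activation_threshold
  class(out) <- c("activation_verdict", "data.frame")
  out
}

#' @export
print.activation_verdict <- function(x, ...) {
  print.data.frame(x)
  cat("drug effective (all monomers below ",
      attr(x, "activation_threshold"), "): ",
      attr(x, "effective"), "\n", sep = "")
  invisible(x)
}
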