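# Independent oracle implementations used to validate the package's fast
# paths. These deliberately use naive double loops and an alternative
# (quaternion) superposition formulation, and must stay independent of
# the code in R/.

# brute-force DCCM: explicit double loop over residue pairs and frames
oracle_dccm <- function(coords) {
  n <- dim(coords)[1]; na <- dim(coords)[2]
  mu <- apply(coords, c(2, 3), mean)
  cov_dot <- matrix(0, na, na)
  for (i in seq_len(na)) {
    for (j in seq_len(na)) {
      s <- 0
      for (f in seq_len(n)) {
        di <- coords[f, i, ] - mu[i, ]
        dj <- coords[f, j, ] - mu[j, ]
        s <- s + sum(di * dj)
      }
      cov_dot[i, j] <- s / n
    }
  }
  v <- diag(cov_dot)
  cov_dot / sqrt(outer(v, v))
}

# quaternion-method optimal superposition RMSD (Kearsley's formulation):
# smallest eigenvalue of the 4x4 key matrix gives the residual
oracle_quaternion_rmsd <- function(mobile, reference) {
  m <- sweep(mobile, 2, colMeans(mobile))
  r <- sweep(reference, 2, colMeans(reference))
  xm <- r[, 1] - m[, 1]; ym <- r[, 2] - m[, 2]; zm <- r[, 3] - m[, 3]
  xp <- r[, 1] + m[, 1]; yp <- r[, 2] + m[, 2]; zp <- r[, 3] + m[, 3]
  K <- matrix(0, 4, 4)
  K[1, 1] <- sum(xm^2 + ym^2 + zm^2)
  K[2, 2] <- sum(xm^2 + yp^2 + zp^2)
  K[3, 3] <- sum(xp^2 + ym^2 + zp^2)
  K[4, 4] <- sum(xp^2 + yp^2 + zm^2)
  K[1, 2] <- K[2, 1] <- sum(yp * zm - ym * zp)
  K[1, 3] <- K[3, 1] <- sum(xm * zp - xp * zm)
  K[1, 4] <- K[4, 1] <- sum(xp * ym - xm * yp)
  K[2, 3] <- K[3, 2] <- sum(xm * ym - xp * yp)
  K[2, 4] <- K[4, 2] <- sum(xm * zm - xp * zp)
  K[3, 4] <- K[4, 3] <- sum(ym * zm - yp * zp)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(0, min(ev) / nrow(mobile)))
}

# exhaustive Daura clustering: recount neighbours from scratch each round
oracle_daura <- function(D, cutoff) {
  n <- nrow(D)
  remaining <- seq_len(n)
  assignment <- integer(n)
  centers <- integer(0); sizes <- integer(0)
  k <- 0L
  while (length(remaining) > 0) {
    best_count <- -1L; best <- NA_integer_
    for (cand in remaining) {
      cnt <- sum(D[cand, remaining] <= cutoff)
      if (cnt > best_count) { best_count <- cnt; best <- cand }
    }
    members <- remaining[D[best, remaining] <= cutoff]
    k <- k + 1L
    assignment[members] <- k
    centers[k] <- best
    sizes[k] <- length(members)
    remaining <- setdiff(remaining, members)
  }
  ord <- order(-sizes, seq_along(sizes))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  list(assignment = relabel[assignment], centers = centers[ord],
       populations = 100 * sizes[ord] / n)
}

# random rotation matrix from a seeded QR decomposition
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# small non-collinear toy topology/trajectory builders ----------------

toy_topology <- function(n_res = 5, chain = "A", first = 1,
                         names = "CA") {
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i)
    data.frame(name = names, element = substr(names, 1, 1),
               resno = first + i - 1, resname = "ALA", chain = chain,
               stringsAsFactors = FALSE)))
  topology(atoms, chains = unique(chain))
}

# frames of gaussian jitter around a fixed non-collinear base structure
toy_trajectory <- function(n_frames, n_atoms, sd = 0.5, dt = 0.1) {
  base <- cbind(3.8 * seq_len(n_atoms),
                2 * sin(seq_len(n_atoms)),
                2 * cos(seq_len(n_atoms) / 2))
  arr <- array(0, c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames))
    arr[f, , ] <- base + matrix(rnorm(n_atoms * 3, sd = sd), n_atoms, 3)
  trajectory(arr, times = (seq_len(n_frames) - 1) * dt)
}

# a dccm_matrix-shaped object with prescribed entries, for score tests
constructed_dccm <- function(C, chain, resno) {
  dimnames(C) <- list(paste0(chain, ":", resno), paste0(chain, ":", resno))
  structure(list(C = C, residues = data.frame(chain = chain, resno = resno,
                                              stringsAsFactors = FALSE)),
            class = "dccm_matrix")
}

# dccm with every H12 x target-region correlation equal to rho, zero
# elsewhere (single monomer spanning 303:552)
planted_profile_dccm <- function(entries, chain = "A") {
  resno <- 303:552
  C <- diag(length(resno))
  rn <- function(r) match(r, resno)
  for (e in entries) C[rn(e[1]), rn(e[2])] <- C[rn(e[2]), rn(e[1])] <- e[3]
  constructed_dccm(C, chain, resno)
}
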