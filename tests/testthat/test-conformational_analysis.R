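test_that("Kabsch superposition recovers rigid transforms exactly", {
  set.seed(50)
  base <- cbind(3.8 * (1:10), 2 * sin(1:10), 2 * cos((1:10) / 2))
  fit0 <- kabsch_superpose(base, base)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  R <- random_rotation()
  moved <- sweep(base %*% R, 2, c(10, -4, 2), "+")
  fit <- kabsch_superpose(moved, base)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # symmetry of the post-fit RMSD and invariance to pre-rotation
  set.seed(51)
  a <- base + matrix(rnorm(30, sd = 0.4), 10, 3)
  expect_equal(kabsch_superpose(a, base)$rmsd,
               kabsch_superpose(base, a)$rmsd, tolerance = 1e-9)
  expect_equal(kabsch_superpose(a %*% random_rotation(), base)$rmsd,
               kabsch_superpose(a, base)$rmsd, tolerance = 1e-9)
  expect_error(kabsch_superpose(cbind(1:5, 0, 0), cbind(1:5, 0, 0)),
               "collinear")
  expect_error(kabsch_superpose(base[1:2, ], base[1:2, ]), ">= 3 atoms")
})

test_that("Kabsch RMSD agrees with an independent quaternion oracle", {
  set.seed(52)
  for (i in 1:10) {
    n <- sample(4:40, 1)
    a <- matrix(rnorm(3 * n, sd = 3), n, 3)
    b <- a + matrix(rnorm(3 * n, sd = runif(1, 0.1, 2)), n, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, oracle_quaternion_rmsd(a, b),
                 tolerance = 1e-9)
  }
  # 4-atom toy set: displacing one atom by 1 A along a direction the fit
  # cannot absorb leaves rmsd = 0.5 (quaternion oracle confirms)
  sq <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  moved <- sq; moved[1, 3] <- 1  # displace out of plane
  r_or <- oracle_quaternion_rmsd(moved, sq)
  expect_equal(kabsch_superpose(moved, sq)$rmsd, r_or, tolerance = 1e-9)
})

test_that("RMSD series is zero for static input and rotation-invariant", {
  set.seed(53)
  base <- cbind(3.8 * (1:12), 2 * sin(1:12), 2 * cos((1:12) / 2))
  static <- trajectory(array(rep(base, each = 5), c(5, 12, 3)), (0:4) * 0.1)
  expect_equal(rmsd_series(static), rep(0, 5), tolerance = 1e-9)
  tr <- toy_trajectory(6, 12)
  s1 <- rmsd_series(tr)
  arr <- tr$coords
  for (f in 1:6) arr[f, , ] <- arr[f, , ] %*% random_rotation()
  s2 <- rmsd_series(trajectory(arr, tr$times))
  expect_lt(max(abs(s1 - s2)), 1e-5)
})

test_that("equilibration detection finds plateaus and flags drift", {
  times <- (0:99) * 5   # 500 ns at 5 ns/frame
  flat <- rep(2, 100)
  expect_equal(detect_equilibration(flat, times), 0)
  step <- c(rep(0, 40), rep(5, 60))   # steps at 40% of the frames
  expect_equal(detect_equilibration(step, times), times[41])
  rising <- seq(0, 10, length.out = 100)
  expect_true(is.na(detect_equilibration(rising, times)))
  # drift then plateau, as in a convergence trace
  set.seed(54)
  drift <- c(seq(0, 3, length.out = 40), rep(3, 60)) +
    rnorm(100, sd = 0.05)
  t0 <- detect_equilibration(drift, times, tol = 0.5)
  expect_true(!is.na(t0) && t0 <= times[45])
  expect_error(detect_equilibration(rep(1, 5), (0:4) * 1), "at least 10")
})

test_that("RMSF recovers the closed-form sigma*sqrt(3) and scales linearly", {
  set.seed(55)
  tr <- toy_trajectory(5000, 10, sd = 0.5)
  r <- rmsf(tr)
  expect_equal(mean(r), 0.5 * sqrt(3), tolerance = 0.02)
  tr2 <- toy_trajectory(5000, 10, sd = 1.0)
  expect_equal(mean(rmsf(tr2)) / mean(r), 2, tolerance = 0.05)
  expect_error(rmsf(tr, window = 3), "at least 2")
  static <- trajectory(array(rep(cbind(1:4, (1:4)^2, 0), each = 3),
                             c(3, 4, 3)), (0:2) * 0.1)
  expect_equal(rmsf(static), rep(0, 4), tolerance = 1e-12)
})

test_that("Daura clustering equals the exhaustive oracle on random instances", {
  set.seed(56)
  for (rep_i in 1:6) {
    n <- sample(10:60, 1)
    # mixture of 1-3 conformers with noise, some near the cutoff scale
    k <- sample(1:3, 1)
    base <- cbind(3.8 * (1:15), 2 * sin(1:15), 2 * cos((1:15) / 2))
    centers <- lapply(1:k, function(i) base + rnorm(45, sd = 2 * (i - 1)))
    arr <- array(0, c(n, 15, 3))
    for (f in 1:n)
      arr[f, , ] <- centers[[sample(k, 1)]] +
        matrix(rnorm(45, sd = runif(1, 0.2, 2)), 15, 3)
    tr <- trajectory(arr, (1:n) * 0.1)
    cutoff <- runif(1, 1, 4)
    res <- daura_cluster(tr, rmsd_cutoff = cutoff)
    D <- h12assay:::pairwise_rmsd(tr)
    orc <- oracle_daura(D, cutoff)
    expect_identical(res$assignment, orc$assignment)
    expect_identical(res$centers, orc$centers)
    expect_equal(res$populations, orc$populations, tolerance = 1e-12)
  }
})

test_that("cluster invariants: identical frames, population sums, cutoffs", {
  base <- cbind(3.8 * (1:8), 2 * sin(1:8), 2 * cos((1:8) / 2))
  same <- trajectory(array(rep(base, each = 10), c(10, 8, 3)), (0:9) * 0.1)
  res <- daura_cluster(same, rmsd_cutoff = 2.75)
  expect_length(res$populations, 1)
  expect_equal(res$populations, 100)
  expect_equal(res$centers, 1)   # ties break to the lowest frame index
  set.seed(57)
  tr <- toy_trajectory(40, 8, sd = 1.5)
  n_clusters <- sapply(c(0.5, 1.5, 3, 6), function(cut)
    length(daura_cluster(tr, rmsd_cutoff = cut)$populations))
  expect_true(all(diff(n_clusters) <= 0))
  res2 <- daura_cluster(tr, rmsd_cutoff = 1.5)
  expect_equal(sum(res2$populations), 100, tolerance = 1e-9)
  expect_true(all(table(res2$assignment)[as.character(
    seq_along(res2$populations))] == res2$populations * 0.4))
  # a single frame forms one singleton cluster
  one <- subset_frames(tr, 1)
  res1 <- daura_cluster(one, rmsd_cutoff = 2.75)
  expect_equal(res1$populations, 100)
})

test_that("planted conformer mixtures are recovered at the Daura cutoff", {
  spec <- synthetic_spec(seed = 58, n_frames = 500, sigma = 0.3,
                         atoms = "calpha",
                         cluster_mixture = list(weights = c(0.8, 0.2),
                                                separation_rmsd = 8))
  g <- generate_trajectory(spec)
  mono <- split_monomers(g$topology, g$trajectory)
  res <- daura_cluster(mono$A$trajectory, mono$A$topology,
                       rmsd_cutoff = 2.75)
  expect_length(res$populations, 2)
  truth_pct <- 100 * mean(g$truth$frames$conformer == 1)
  expect_equal(res$populations[1], truth_pct, tolerance = 3 / truth_pct)
  expect_equal(res$populations[1], 80, tolerance = 3 / 80)
  expect_equal(res$populations[2], 20, tolerance = 3 / 20)
  # the representative of the top cluster carries the majority label
  expect_equal(g$truth$frames$conformer[representative_structure(res, 1)], 1L)
  expect_equal(g$truth$frames$conformer[representative_structure(res, 2)], 2L)
  expect_error(representative_structure(res, 6), "out of range")
})

test_that("helix assignment: ideal helix 100%, extended 0%", {
  n <- 14
  for (conf in c("helical", "extended")) {
    seg <- h12assay:::helix_segment_coords(n, conformation = conf)
    atoms <- do.call(rbind, lapply(1:n, function(i)
      data.frame(name = c("N", "CA", "C", "O", "H"),
                 element = c("N", "C", "C", "O", "H"),
                 resno = i, resname = "ALA", chain = "A",
                 stringsAsFactors = FALSE)))
    top <- topology(atoms)
    frame <- matrix(0, n * 5, 3)
    for (i in 1:n) {
      frame[(i - 1) * 5 + 1, ] <- seg$N[i, ]
      frame[(i - 1) * 5 + 2, ] <- seg$CA[i, ]
      frame[(i - 1) * 5 + 3, ] <- seg$C[i, ]
      frame[(i - 1) * 5 + 4, ] <- seg$O[i, ]
      frame[(i - 1) * 5 + 5, ] <- seg$H[i, ]
    }
    arr <- array(rep(frame, each = 2), c(2, n * 5, 3))
    ha <- assign_helix(trajectory(arr, c(0, 0.1)), top)
    interior <- ha$residues$resno >= 2 & ha$residues$resno <= n - 1
    if (conf == "helical") {
      expect_equal(unname(ha$content[interior]),
                   rep(100, sum(interior)))
    } else {
      expect_equal(unname(ha$content), rep(0, n))
    }
  }
})

test_that("planted helical fraction is recovered exactly from geometry", {
  spec <- synthetic_spec(seed = 59, n_frames = 1000, sigma = 0.4,
                         helicity_plants = list(list(
                           chain = "A", first = 527, last = 540,
                           fraction = 0.6)))
  g <- generate_trajectory(spec)
  ha <- assign_helix(g$trajectory, g$topology, chains = "A")
  truth_pct <- 100 * mean(g$truth$frames$helical_A_527_540)
  seg <- segment_helicity(ha, "A", 527, 540)
  expect_equal(seg, truth_pct)
  ci <- 100 * (0.6 + c(-1, 1) * qnorm(0.995) * sqrt(0.6 * 0.4 / 1000))
  expect_gt(seg, ci[1]); expect_lt(seg, ci[2])
  # outside the planted segment the reference geometry is non-helical
  expect_equal(segment_helicity(ha, "A", 400, 430), 0)
  expect_error(segment_helicity(ha, "B", 527, 540), "no residues")
})

test_that("missing backbone atoms are reported per residue", {
  top <- toy_topology(n_res = 12)  # Calpha only
  tr <- toy_trajectory(3, 12)
  expect_error(assign_helix(tr, top), "missing backbone")
})
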