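test_that("hydrogen-bond rule evaluates distance and angle cutoffs", {
  top <- hb_toy(); spec <- hb_spec(); p <- hbond_params()
  expect_true(detect_hbond_frame(hb_frame(2.9, 175), top, spec, p))
  expect_false(detect_hbond_frame(hb_frame(3.4, 180), top, spec, p))
  expect_false(detect_hbond_frame(hb_frame(3.0, 140), top, spec, p))
  expect_true(detect_hbond_frame(hb_frame(3.3, 145), top, spec, p))  # inclusive
  expect_false(detect_hbond_frame(hb_frame(3.0, 144.9), top, spec, p))
})

test_that("hydrogen-bond rule is invariant under rigid motion", {
  top <- hb_toy(); spec <- hb_spec(); p <- hbond_params()
  set.seed(20)
  for (i in 1:5) {
    for (case in list(c(2.9, 175), c(3.4, 180), c(3.0, 140))) {
      frm <- hb_frame(case[1], case[2])
      R <- random_rotation()
      moved <- sweep(frm %*% R, 2, rnorm(3, sd = 20), "+")
      expect_identical(detect_hbond_frame(moved, top, spec, p),
                       detect_hbond_frame(frm, top, spec, p))
    }
  }
})

test_that("missing hydrogens error with a pointer to heavy-atom mode", {
  atoms <- data.frame(name = c("NE2", "OE1"), element = c("N", "O"),
                      resno = c(1, 2), resname = c("HIS", "GLU"),
                      chain = "A", stringsAsFactors = FALSE)
  top <- topology(atoms)
  spec <- interaction_spec("hbond", "noH",
                           a = list(resno = 1, name = "NE2"),
                           h = list(resno = 1, name = "HE2"),
                           b = list(resno = 2, name = "OE1"))
  expect_error(
    detect_hbond_frame(rbind(c(0, 0, 0), c(3, 0, 0)), top, spec),
    "heavy_only")
  # distance-only fallback detects and flags
  tr <- trajectory(array(rbind(c(0, 0, 0), c(3, 0, 0)), c(1, 2, 3)), 0)
  # build 2 frames to satisfy trajectory shape expectations
  arr <- array(0, c(2, 2, 3)); arr[1, , ] <- rbind(c(0, 0, 0), c(3, 0, 0))
  arr[2, , ] <- rbind(c(0, 0, 0), c(5, 0, 0))
  ser <- persistence(trajectory(arr, c(0, 0.1)), top, spec,
                     params = hbond_params(heavy_only = TRUE))
  expect_equal(ser$persistence, 50)
  expect_true("distance_only" %in% ser$flags)
})

test_that("planted occupancy is recovered within the binomial interval", {
  spec <- synthetic_spec(seed = 41, n_frames = 1000, sigma = 0.5,
                         hbond_plants = list(list(
                           label = "E380-H377",
                           donor = list(chain = "A", resno = 377,
                                        name = "NE2"),
                           hydrogen = list(chain = "A", resno = 377,
                                           name = "HE2"),
                           acceptor = list(chain = "A", resno = 380,
                                           name = "OE1"),
                           occupancy = 0.7)))
  g <- generate_trajectory(spec)
  isp <- interaction_spec("hbond", "E380-H377",
                          a = list(chain = "A", resno = 377,
                                   name = c("ND1", "NE2")),
                          h = list(chain = "A", resno = 377,
                                   name = c("HD1", "HE2")),
                          b = list(chain = "A", resno = 380,
                                   name = c("OE1", "OE2")))
  ser <- persistence(g$trajectory, g$topology, isp)
  truth_pct <- 100 * mean(g$truth$frames$hbond_E380.H377)
  expect_equal(ser$persistence, truth_pct)   # detector matches ground truth
  ci <- 100 * (0.7 + c(-1, 1) * qnorm(0.995) * sqrt(0.7 * 0.3 / 1000))
  expect_gt(ser$persistence, ci[1])
  expect_lt(ser$persistence, ci[2])
})

test_that("persistence is additive over disjoint windows", {
  set.seed(42)
  spec <- synthetic_spec(seed = 43, n_frames = 200, sigma = 0.5,
                         hbond_plants = list(list(
                           label = "hb",
                           donor = list(chain = "A", resno = 377,
                                        name = "NE2"),
                           hydrogen = list(chain = "A", resno = 377,
                                           name = "HE2"),
                           acceptor = list(chain = "A", resno = 380,
                                           name = "OE1"),
                           occupancy = 0.4)))
  g <- generate_trajectory(spec)
  isp <- interaction_spec("hbond", "hb",
                          a = list(chain = "A", resno = 377, name = "NE2"),
                          h = list(chain = "A", resno = 377, name = "HE2"),
                          b = list(chain = "A", resno = 380, name = "OE1"))
  w1 <- 1:80; w2 <- 81:200
  p1 <- persistence(g$trajectory, g$topology, isp, window = w1)$persistence
  p2 <- persistence(g$trajectory, g$topology, isp, window = w2)$persistence
  pall <- persistence(g$trajectory, g$topology, isp)$persistence
  expect_equal(pall, (80 * p1 + 120 * p2) / 200, tolerance = 1e-12)
  expect_error(persistence(g$trajectory, g$topology, isp, window = integer(0)),
               "empty")
})

test_that("tightening the cutoffs never increases persistence", {
  spec <- synthetic_spec(seed = 44, n_frames = 150, sigma = 1,
                         hbond_plants = list(list(
                           label = "hb",
                           donor = list(chain = "A", resno = 377,
                                        name = "NE2"),
                           hydrogen = list(chain = "A", resno = 377,
                                           name = "HE2"),
                           acceptor = list(chain = "A", resno = 380,
                                           name = "OE1"),
                           occupancy = 0.6)))
  g <- generate_trajectory(spec)
  isp <- interaction_spec("hbond", "hb",
                          a = list(chain = "A", resno = 377, name = "NE2"),
                          h = list(chain = "A", resno = 377, name = "HE2"),
                          b = list(chain = "A", resno = 380, name = "OE1"))
  pers <- sapply(c(4.0, 3.3, 3.0, 2.9), function(dm)
    persistence(g$trajectory, g$topology, isp,
                params = hbond_params(d_max = dm))$persistence)
  expect_true(all(diff(pers) <= 0))
})

test_that("contact detection thresholds the minimum cross-group distance", {
  atoms <- data.frame(name = c("CD1", "CD2", "CZ2", "CH2"),
                      element = "C", resno = c(1, 1, 2, 2),
                      resname = c("LEU", "LEU", "TRP", "TRP"),
                      chain = "A", stringsAsFactors = FALSE)
  top <- topology(atoms)
  arr <- array(0, c(2, 4, 3))
  arr[1, , ] <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(4.5, 0, 0), c(9, 0, 0))
  arr[2, , ] <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(11.5, 0, 0), c(13, 0, 0))
  tr <- trajectory(arr, c(0, 0.1))
  ser <- contact_persistence(tr, top, list(resno = 1), list(resno = 2),
                             cutoff = 4.5)
  expect_equal(ser$present, c(TRUE, FALSE))  # 3.0 A apart vs 10 A apart
  expect_equal(ser$persistence, 50)
  expect_error(contact_persistence(tr, top, list(resno = 1),
                                   list(resno = 3)), "no atoms")
})

test_that("pi-stacking requires both centroid distance and plane angle", {
  hex <- function(center, tilt_deg = 0) {
    ang <- seq(0, 2 * pi, length.out = 7)[-7]
    ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
    t <- tilt_deg * pi / 180
    R <- rbind(c(1, 0, 0), c(0, cos(t), -sin(t)), c(0, sin(t), cos(t)))
    sweep(ring %*% R, 2, center, "+")
  }
  atoms <- data.frame(name = paste0("C", 1:12), element = "C",
                      resno = rep(1:2, each = 6),
                      resname = "TYR", chain = "A", stringsAsFactors = FALSE)
  top <- topology(atoms)
  mk_traj <- function(center2, tilt) {
    arr <- array(0, c(1, 12, 3))
    arr[1, , ] <- rbind(hex(c(0, 0, 0)), hex(center2, tilt))
    # pad to 2 frames (times must be strictly increasing)
    arr2 <- array(arr[1, , ], c(1, 12, 3))
    trajectory(abind_frames(arr, arr2), c(0, 0.1))
  }
  abind_frames <- function(a, b) {
    out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], 3))
    out[seq_len(dim(a)[1]), , ] <- a
    out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
    out
  }
  ra <- list(resno = 1); rb <- list(resno = 2)
  expect_equal(pi_stacking(mk_traj(c(0, 0, 3.8), 0), top, ra, rb)$persistence,
               100)   # coplanar parallel rings 3.8 A apart
  expect_equal(pi_stacking(mk_traj(c(0, 0, 4.0), 90), top, ra, rb)$persistence,
               0)     # perpendicular rings
  expect_equal(pi_stacking(mk_traj(c(0, 0, 4.9), 25), top, ra, rb)$persistence,
               100)   # 4.9 A, 25 deg: inside both cutoffs
  expect_equal(pi_stacking(mk_traj(c(0, 0, 5.1), 25), top, ra, rb)$persistence,
               0)     # 5.1 A: centroid distance fails
  # collinear "ring" atoms have no plane
  line <- array(rep(cbind(1:12, 0, 0), each = 2), c(2, 12, 3))
  expect_error(pi_stacking(trajectory(line, c(0, 0.1)), top, ra, rb),
               "collinear")
})

test_that("signature panel recovers plants and marks absent chemistry n/a", {
  spec <- synthetic_spec(seed = 45, n_frames = 300, sigma = 0.4,
                         isoform = "WT",
                         hbond_plants = list(list(
                           label = "E380-H377",
                           donor = list(chain = "A", resno = 377,
                                        name = "NE2"),
                           hydrogen = list(chain = "A", resno = 377,
                                           name = "HE2"),
                           acceptor = list(chain = "A", resno = 380,
                                           name = "OE1"),
                           occupancy = 0.9)))
  g <- generate_trajectory(spec)
  pan <- signature_panel(g$topology, g$trajectory, isoform = "WT")
  rowA <- pan[pan$monomer == "A" & pan$label == "E380-H377", ]
  expect_equal(rowA$persistence, 100 * mean(g$truth$frames$hbond_E380.H377))
  expect_gt(rowA$persistence, 85)
  # serine-537 signature is not applicable in the wild type
  s537 <- pan[pan$monomer == "A" & pan$label == "D351-S537(OG)", ]
  expect_false(s537$applicable)
  expect_true(is.na(s537$persistence))
  # unplanted H-bond rows stay at 0
  rowB <- pan[pan$monomer == "B" & pan$label == "E380-H377", ]
  expect_equal(rowB$persistence, 0)
})

test_that("the 537 variants switch the applicable signature rows", {
  spec <- synthetic_spec(seed = 46, n_frames = 5, sigma = 0.3,
                         isoform = "Y537S")
  g <- generate_trajectory(spec)
  pan <- signature_panel(g$topology, g$trajectory, isoform = "Y537S")
  s537 <- pan[pan$monomer == "A" & pan$label == "D351-S537(OG)", ]
  expect_true(s537$applicable)
  # no tyrosine ring: the stacking row becomes n/a
  stack <- pan[pan$monomer == "A" & pan$label == "Y537-H377", ]
  expect_false(stack$applicable)
})
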