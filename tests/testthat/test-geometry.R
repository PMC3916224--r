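test_that("superposition recovers constructed rigid motions", {
  set.seed(1)
  a <- matrix(rnorm(30), 10, 3)
  s0 <- superpose(a, a)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-8)

  r25 <- rotation_about_axis(c(0, 0, 1), 25)
  b <- sweep(a %*% r25, 2, c(3, -1, 2), "+")
  s <- superpose(a, b)
  expect_equal(rotation_angle(s$rotation), 25, tolerance = 1e-8)
  expect_lt(s$rmsd, 1e-10)
  expect_equal(det(s$rotation), 1, tolerance = 1e-10)
})

test_that("superposition RMSD matches a brute-force rotation-grid search", {
  set.seed(9)
  mob <- matrix(rnorm(15), 5, 3)
  ref <- mob %*% rotation_about_axis(c(1, 2, 3), 30) +
    matrix(rnorm(15, sd = 0.3), 5, 3)
  kab <- superpose(mob, ref)$rmsd
  grid <- grid_min_rmsd(mob, ref)
  expect_gte(grid, kab - 1e-9)      # Kabsch is the true minimiser
  expect_lt(grid - kab, 5e-3)       # and the grid search agrees closely
})

test_that("superposition rejects mismatched or degenerate input", {
  expect_error(superpose(matrix(0, 4, 3), matrix(0, 5, 3)), "identical")
  expect_error(superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose(line, line + 1), "collinear")
})

test_that("superposition is invariant to rigid motion of the mobile set", {
  set.seed(4)
  for (i in 1:10) {
    mob <- matrix(rnorm(24), 8, 3)
    ref <- mob + matrix(rnorm(24, sd = 0.5), 8, 3)
    base <- superpose(mob, ref)$rmsd
    g <- rotation_about_axis(rnorm(3), runif(1, 0, 180))
    moved <- sweep(mob %*% g, 2, rnorm(3, sd = 10), "+")
    expect_equal(superpose(moved, ref)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("plane fitting matches exact and brute-force oracles", {
  set.seed(11)
  flat <- cbind(runif(12, -5, 5), runif(12, -5, 5), 0)
  fp <- fit_plane(flat)
  expect_equal(abs(fp$normal[3]), 1, tolerance = 1e-10)
  expect_lt(fp$residual, 1e-10)

  jittered_cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1))) +
    matrix(rnorm(24, sd = 0.2), 8, 3)
  fp2 <- fit_plane(jittered_cube)
  expect_equal(fp2$residual, grid_min_plane_resid(jittered_cube),
               tolerance = 1e-3)

  expect_error(fit_plane(matrix(rnorm(6), 2, 3)), "at least 3")
  expect_error(fit_plane(cbind(1:6, 1:6, 1:6)), "collinear")
})

test_that("SASA reproduces closed-form sphere geometry", {
  # isolated atom: full expanded sphere
  one <- sasa(matrix(0, 1, 3), 1.7, probe_radius = 1.2)
  expect_equal(as.numeric(one), 4 * pi * 2.9^2, tolerance = 1e-9)
  # two distant atoms: exactly additive
  two <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), c(1.7, 1.7), 1.2)
  expect_equal(as.numeric(two), 2 * as.numeric(one), tolerance = 1e-9)
  # partial overlap: spherical-cap closed form at several separations
  for (d in c(2.0, 3.5, 5.0)) {
    s <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), c(1.7, 1.7), 1.2, 960L)
    expect_equal(as.numeric(s), cap_sasa(1.7, 1.7, d, 1.2),
                 tolerance = 0.01)
  }
  expect_error(sasa(matrix(0, 1, 3), -1), "positive")
})

test_that("SASA converges under point-density doubling", {
  set.seed(21)
  xyz <- matrix(rnorm(30, sd = 2), 10, 3)
  r <- runif(10, 1.4, 1.9)
  a1 <- as.numeric(sasa(xyz, r, n_points = 960L))
  a2 <- as.numeric(sasa(xyz, r, n_points = 1920L))
  expect_lt(abs(a2 - a1) / a1, 0.01)
})

test_that("buried surface area follows the two-term SASA difference", {
  # far-apart pseudo-subunits bury nothing
  far <- structure_model(data.frame(
    elety = "CA", elesy = "C", resid = "GLY",
    chain = rep(c("A", "B"), each = 3), resno = rep(1:3, 2),
    x = c(0, 2, 4, 100, 102, 104), y = 0, z = 0))
  dim_far <- list(structure = far, alpha = "A", beta = "B")
  class(dim_far) <- "tubulin_dimer"
  expect_equal(buried_surface_area(dim_far), 0, tolerance = 1e-9)

  # two overlapping one-atom subunits: BSA = sum of buried cap areas
  d <- 3.0
  pair <- structure_model(data.frame(
    elety = "C", elesy = "C", resid = "LIG", chain = c("A", "B"),
    resno = 1L, x = c(0, d), y = 0, z = 0))
  dim_pair <- list(structure = pair, alpha = "A", beta = "B")
  class(dim_pair) <- "tubulin_dimer"
  R <- 1.7 + 1.2
  h <- R - d / 2
  expect_equal(buried_surface_area(dim_pair), 2 * 2 * pi * R * h,
               tolerance = 0.02 * 2 * 2 * pi * R * h)
})

test_that("BSA is non-negative for random two-cluster geometries", {
  set.seed(33)
  for (i in 1:100) {
    gap <- runif(1, 0, 8)
    at <- data.frame(
      elety = "C", elesy = "C", resid = "GLY",
      chain = rep(c("A", "B"), each = 5), resno = rep(1:5, 2),
      x = c(rnorm(5, 0, 2), rnorm(5, gap, 2)),
      y = rnorm(10, 0, 2), z = rnorm(10, 0, 2))
    dm <- list(structure = structure_model(at), alpha = "A", beta = "B")
    class(dm) <- "tubulin_dimer"
    expect_gte(buried_surface_area(dm, n_points = 240L), -1e-9)
  }
})

test_that("clash detection equals brute-force pair enumeration", {
  set.seed(5)
  xyz <- matrix(rnorm(150, sd = 3), 50, 3)
  el <- sample(c("C", "N", "O", "S"), 50, replace = TRUE)
  got <- steric_clashes(xyz, xyz, elements_a = el)
  ref <- bf_clashes(xyz, el, xyz, el, same = TRUE)
  expect_equal(nrow(got), nrow(ref))
  o1 <- order(got$i, got$j); o2 <- order(ref[, 1], ref[, 2])
  expect_equal(got$i[o1], as.integer(ref[o2, 1]))
  expect_equal(got$j[o1], as.integer(ref[o2, 2]))
  expect_close(got$distance[o1], ref[o2, 3], 1e-10)

  # distinct sets: all cross pairs
  xb <- matrix(rnorm(60, sd = 3), 20, 3)
  eb <- sample(c("C", "O"), 20, replace = TRUE)
  got2 <- steric_clashes(xyz, xb, elements_a = el, elements_b = eb)
  ref2 <- bf_clashes(xyz, el, xb, eb, same = FALSE)
  expect_equal(nrow(got2), nrow(ref2))

  # 75 percent rule arithmetic
  cc <- matrix(c(0, 0, 0, 3.4, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(nrow(steric_clashes(cc, cc, elements_a = c("C", "C"))), 0L)
  cc[2, 1] <- 2.0
  hit <- steric_clashes(cc, cc, elements_a = c("C", "C"))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$threshold, 0.75 * 3.4)
  expect_error(steric_clashes(cc, cc, elements_a = c("C", "Xx")),
               "Xx")
})

test_that("intradimer angle is zero for self-comparison and recovers rotations", {
  syn <- make_synthetic_dimer(0, seed = 2)
  self <- intradimer_angle(syn$straight_dimer, syn$straight_dimer)
  expect_equal(self$mean, 0, tolerance = 1e-8)
  expect_equal(self$sd, 0, tolerance = 1e-8)

  syn7 <- make_synthetic_dimer(7.5, seed = 3)
  res <- intradimer_angle(syn7$bent_dimer, syn7$straight_dimer)
  # closed-form oracle: the combined-plane normal simply rotates with the
  # beta subunit, so the plane-intersection angle is angle(n, R n)
  n <- h7_plane_normal(syn7$straight_dimer)
  r <- rotation_about_axis(syn7$axis, 7.5)
  oracle <- plane_angle(n, as.numeric(n %*% r))
  expect_equal(oracle, 7.5, tolerance = 1e-3)
  expect_equal(res$mean, oracle, tolerance = 0.15)
  expect_true(res$mean >= min(res$variants) - 1e-12 &&
                res$mean <= max(res$variants) + 1e-12)
})

test_that("intradimer angle is invariant to global rigid motion of either input", {
  syn <- make_synthetic_dimer(9, seed = 6)
  base <- intradimer_angle(syn$bent_dimer, syn$straight_dimer)$mean
  moved <- syn$bent
  g <- rotation_about_axis(c(2, -1, 5), 73)
  moved$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(moved$atoms[, c("x", "y", "z")]) %*% g, 2,
          c(20, -5, 11), "+")
  moved_dimer <- annotate_dimer(moved, list(alpha = "A", beta = "B"),
                                syn$domains, quiet = TRUE)
  expect_equal(intradimer_angle(moved_dimer, syn$straight_dimer)$mean,
               base, tolerance = 1e-6)
})

test_that("intramonomer rotation recovers a constructed domain rotation", {
  syn <- make_synthetic_dimer(0, seed = 7)
  expect_equal(
    intramonomer_rotation(syn$straight_dimer, syn$straight_dimer,
                          "beta")$mean, 0, tolerance = 1e-8)

  # rotate only the intermediate domain of chain B by 9 degrees about a
  # random axis through its centroid; N-terminal frame stays fixed
  set.seed(8)
  bent <- syn$straight
  sel <- bent$atoms$chain == "B" & bent$atoms$resno >= 20 &
    bent$atoms$resno <= 34
  xyz <- as.matrix(bent$atoms[sel, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  r9 <- rotation_about_axis(rnorm(3), 9)
  bent$atoms[sel, c("x", "y", "z")] <-
    sweep(sweep(xyz, 2, ctr) %*% r9, 2, ctr, "+")
  bd <- annotate_dimer(bent, list(alpha = "A", beta = "B"), syn$domains,
                       quiet = TRUE)
  got <- intramonomer_rotation(bd, syn$straight_dimer, "beta")
  expect_equal(got$mean, 9, tolerance = 0.1)
  # whole-subunit rigid rotation is not an intramonomer rearrangement
  syn12 <- make_synthetic_dimer(12, seed = 9)
  expect_equal(
    intramonomer_rotation(syn12$bent_dimer, syn12$straight_dimer,
                          "beta")$mean, 0, tolerance = 1e-4)
})

test_that("domain-center bending angle matches constructed rotations", {
  syn <- make_synthetic_dimer(0, seed = 10)
  # acos() near 1 amplifies float rounding; 1e-4 deg is numerically zero
  expect_equal(voth_bending_angle(syn$straight_dimer), 0, tolerance = 1e-4)
  syn10 <- make_synthetic_dimer(10, seed = 10)
  expect_equal(voth_bending_angle(syn10$bent_dimer) -
                 voth_bending_angle(syn10$straight_dimer), 10,
               tolerance = 0.5)

  # spec-style fixture: subunit centre lines along x, beta rotated about z
  line_blobs <- function(chain, xs) do.call(rbind, Map(function(resno, x0)
    data.frame(elety = "CA", elesy = "C", resid = "GLY", chain = chain,
               resno = resno, x = x0 + c(0.5, -0.5, 0, 0, 0, 0),
               y = c(0, 0, 0.4, -0.4, 0, 0), z = c(0, 0, 0, 0, 0.4, -0.4)),
    list(1:6, 20:25, 40:45), xs))
  at <- rbind(line_blobs("A", c(-60, -40, -20)),
              line_blobs("B", c(20, 40, 60)))
  dom <- domain_config(n_terminal = c(1, 6), intermediate = c(20, 25),
                       c_terminal = c(40, 45), h7_alpha = c(1, 6),
                       h7_beta = c(1, 6))
  straight <- structure_model(at)
  bsel <- at$chain == "B"
  at_b <- at
  at_b[bsel, c("x", "y", "z")] <-
    as.matrix(at[bsel, c("x", "y", "z")]) %*% rotation_about_axis(c(0, 0, 1), 10)
  d0 <- annotate_dimer(straight, list(alpha = "A", beta = "B"), dom,
                       quiet = TRUE)
  d1 <- annotate_dimer(structure_model(at_b), list(alpha = "A", beta = "B"),
                       dom, quiet = TRUE)
  expect_equal(voth_bending_angle(d0), 0, tolerance = 1e-4)
  expect_equal(voth_bending_angle(d1), 10, tolerance = 1e-6)

  # degenerate: coincident centers
  coll <- at
  coll[coll$chain == "B", c("x", "y", "z")] <-
    matrix(rep(c(30, 0, 0), each = sum(bsel)), ncol = 3)
  expect_error(voth_bending_angle(
    annotate_dimer(structure_model(coll), list(alpha = "A", beta = "B"),
                   dom, quiet = TRUE)), "degenerate|collinear")
})

test_that("angle recovery holds across 0-20 degrees on synthetic dimers", {
  for (a in c(0, 2.5, 7.5, 12, 16, 20)) {
    syn <- make_synthetic_dimer(a, seed = 2)
    expect_equal(intradimer_angle(syn$bent_dimer, syn$straight_dimer)$mean,
                 a, tolerance = 0.5)
  }
})

test_that("the two curvature metrics agree with slope near one along a morph", {
  syn <- make_synthetic_dimer(12, seed = 4)
  path <- linear_morph(syn$straight, syn$bent, 13)
  v0 <- voth_bending_angle(syn$straight_dimer)
  ang <- vapply(1:15, function(k) {
    d <- annotate_dimer(path_frame_structure(path, k),
                        list(alpha = "A", beta = "B"), syn$domains,
                        quiet = TRUE)
    c(intradimer_angle(d, syn$straight_dimer)$mean,
      voth_bending_angle(d) - v0)
  }, numeric(2))
  slope <- stats::coef(stats::lm(ang[2, ] ~ ang[1, ]))[[2]]
  expect_gt(slope, 0.85)
  expect_lt(slope, 1.15)
})
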