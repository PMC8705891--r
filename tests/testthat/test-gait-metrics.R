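test_that("time normalisation interpolates linearly with exact endpoints", {
  t <- seq(0, 1, by = 0.01)
  expect_equal(time_normalise(rep(5, length(t)), t, 0.1, 0.9, 51), rep(5, 51))
  ramp <- 2 * t + 1
  out <- time_normalise(ramp, t, 0.1, 0.9, 41)
  expect_equal(out, 2 * seq(0.1, 0.9, length.out = 41) + 1, tolerance = 1e-12)
  expect_error(time_normalise(ramp, t, -0.5, 0.9), "outside")
  expect_error(time_normalise(ramp, t, 0.9, 0.1), "exceed")
})

test_that("a 200 Hz sine normalises to within 1e-3 of the closed form", {
  t <- seq(0, 1, by = 1 / 200)
  x <- sin(2 * pi * t)
  out <- time_normalise(x, t, 0, 1, 101)
  expect_lt(max(abs(out - sin(2 * pi * seq(0, 1, length.out = 101)))), 1e-3)
})

test_that("trial averaging is the elementwise mean", {
  set.seed(31)
  w1 <- random_waveforms()
  expect_equal(average_trials(list(w1))$values, w1$values)
  # two sets symmetric about a template average to the template
  tmpl <- random_waveforms()
  d <- matrix(stats::rnorm(101 * 9), 101, 9)
  wp <- gait_cycle_waveforms(tmpl$values + d, side = "left")
  wm <- gait_cycle_waveforms(tmpl$values - d, side = "left")
  expect_equal(average_trials(list(wp, wm))$values, tmpl$values,
               tolerance = 1e-12)
  # k random sets vs brute-force elementwise average
  k <- 5
  sets <- replicate(k, random_waveforms(), simplify = FALSE)
  brute <- sets[[1]]$values * 0
  for (s in sets) for (i in seq_len(101)) for (j in 1:9)
    brute[i, j] <- brute[i, j] + s$values[i, j] / k
  expect_equal(average_trials(sets)$values, brute, tolerance = 1e-12)
  expect_error(average_trials(list(w1, random_waveforms(T = 51))), "grids")
  expect_error(average_trials(list(w1, random_waveforms(side = "right"))),
               "sides")
})

test_that("gait variable scores follow the RMS-deviation formula", {
  set.seed(32)
  ref <- ref_from_matrix(random_waveforms()$values)
  w_same <- gait_cycle_waveforms(ref$values, side = "left")
  expect_equal(unname(gvs(w_same, ref)), rep(0, 9))
  # constant 3-degree offset on one variable scores exactly 3 there
  v <- ref$values
  v[, "hip_rotation"] <- v[, "hip_rotation"] + 3
  sc <- gvs(gait_cycle_waveforms(v, side = "left"), ref)
  expect_equal(unname(sc["hip_rotation"]), 3, tolerance = 1e-12)
  expect_equal(unname(sc[setdiff(names(sc), "hip_rotation")]), rep(0, 8))
})

test_that("gvs and gps match brute-force evaluation on random pairs", {
  set.seed(33)
  for (rep in 1:25) {
    w <- random_waveforms()
    ref <- ref_from_matrix(random_waveforms()$values)
    sc <- gvs(w, ref)
    # independent direct-summation oracle
    brute <- numeric(9)
    for (j in 1:9) {
      acc <- 0
      for (i in 1:101) acc <- acc + (w$values[i, j] - ref$values[i, j])^2
      brute[j] <- sqrt(acc / 101)
    }
    expect_equal(unname(sc), brute, tolerance = 1e-12)
    expect_equal(gps(sc), sqrt(sum(brute^2) / 9), tolerance = 1e-12)
  }
})

test_that("gps of equal scores is that score, and is permutation invariant", {
  for (g in c(3, 2.5, 0.125, 7)) {
    expect_identical(gps(rep(g, 9)), g)
  }
  expect_equal(gps(c(3, 4)), sqrt(12.5), tolerance = 1e-15)
  set.seed(34)
  v <- abs(stats::rnorm(9))
  expect_equal(gps(v), gps(sample(v)))
  expect_error(gps(numeric()), "non-empty")
})

test_that("gps properties: zero iff equal, monotone, and scale-equivariant", {
  set.seed(35)
  w <- random_waveforms()
  ref <- ref_from_matrix(random_waveforms()$values)
  expect_identical(gps(gvs(gait_cycle_waveforms(ref$values, side = "left"),
                           ref)), 0)
  expect_gt(gps(gvs(w, ref)), 0)
  sc <- gvs(w, ref)
  sc2 <- sc
  sc2[4] <- sc2[4] + 1
  expect_gt(gps(sc2), gps(sc))
  # multiplying all deviations by c scales every GVS and the GPS by c
  for (c_ in c(0, 0.5, 2)) {
    wc <- gait_cycle_waveforms(ref$values + c_ * (w$values - ref$values),
                               side = "left")
    expect_equal(unname(gvs(wc, ref)), c_ * unname(sc), tolerance = 1e-12)
    expect_equal(gps(gvs(wc, ref)), c_ * gps(sc), tolerance = 1e-12)
  }
})

test_that("foot progression angle follows its construction", {
  t <- seq(0, 1, by = 0.01)
  nf <- length(t)
  pelvis <- cbind(t * 1.2, 0, 0.9)  # walking along +X
  ank_r <- cbind(t * 1.2, -0.1, 0.05)
  # foot parallel to progression -> all zeros
  toe <- ank_r + rep(c(0.15, 0, -0.02), each = nf)
  expect_equal(foot_progression_angle(pelvis, ank_r, toe, t, 0, 1, 101,
                                      side = "right"),
               rep(0, 101), tolerance = 1e-12)
  # +10 degrees internal (right foot toward the midline) -> constant +10
  th <- 10 * pi / 180
  toe10 <- ank_r + rep(0.15 * c(cos(th), sin(th), 0) + c(0, 0, -0.02),
                       each = nf)
  expect_equal(foot_progression_angle(pelvis, ank_r, toe10, t, 0, 1, 101,
                                      side = "right"),
               rep(10, 101), tolerance = 1e-9)
  # left foot: internal rotation is toward -Y
  toe10l <- ank_r + rep(0.15 * c(cos(th), -sin(th), 0) + c(0, 0, -0.02),
                        each = nf)
  expect_equal(foot_progression_angle(pelvis, ank_r, toe10l, t, 0, 1, 101,
                                      side = "left"),
               rep(10, 101), tolerance = 1e-9)
  # vertical components never matter (transverse projection)
  pelvis_z <- pelvis; pelvis_z[, 3] <- stats::runif(nf)
  toe_z <- toe10; toe_z[, 3] <- toe_z[, 3] + stats::rnorm(nf, sd = 0.3)
  expect_equal(foot_progression_angle(pelvis_z, ank_r, toe_z, t, 0, 1, 101,
                                      side = "right"),
               rep(10, 101), tolerance = 1e-9)
  # no net progression -> degenerate error
  expect_error(foot_progression_angle(pelvis * 0, ank_r, toe, t, 0, 1, 101),
               "degenerate")
})

test_that("symmetry index is Robinson's normalised difference", {
  expect_equal(symmetry_index(5, 5), 0)
  expect_equal(symmetry_index(6, 4), 40)
  expect_equal(symmetry_index(4, 6), -40)
  expect_error(symmetry_index(0, 0), "undefined")
})

test_that("reference profiles are per-group means with correct assignment", {
  set.seed(36)
  # one subject per group: the reference equals that subject's waveform
  wfs <- list(random_waveforms(), random_waveforms(), random_waveforms())
  refs <- build_reference(wfs, ages = c(7, 12, 20))
  expect_equal(refs$children$values, wfs[[1]]$values)
  expect_equal(refs$teenagers$values, wfs[[2]]$values)
  expect_equal(refs$young_adults$values, wfs[[3]]$values)
  expect_error(build_reference(wfs[1:2], ages = c(7, 12)), "young_adults")
  # cohort symmetric about a template averages to the template
  tmpl <- random_waveforms()
  d <- matrix(stats::rnorm(101 * 9), 101, 9)
  wp <- gait_cycle_waveforms(tmpl$values + d, side = "left")
  wm <- gait_cycle_waveforms(tmpl$values - d, side = "right")
  refs2 <- build_reference(list(wp, wm, wfs[[2]], wfs[[3]]),
                           ages = c(8, 8, 12, 20))
  expect_equal(refs2$children$values, tmpl$values, tolerance = 1e-12)
})

test_that("group mean squared GPS equals the pooled within-group variance", {
  # variance-decomposition oracle, computed by brute force: with the
  # reference equal to the group mean, mean_j GPS_j^2 equals the average
  # over variables and time of the per-point population variance
  set.seed(37)
  k <- 6
  wfs <- replicate(k, random_waveforms(T = 31), simplify = FALSE)
  acc <- Reduce(`+`, lapply(wfs, `[[`, "values")) / k
  ref <- ref_from_matrix(acc, n = k)
  gps2 <- vapply(wfs, function(w) gps(gvs(w, ref))^2, numeric(1))
  expect_true(all(vapply(wfs, function(w) gps(gvs(w, ref)), numeric(1)) >= 0))
  brute_var <- 0
  for (j in 1:9) for (i in 1:31) {
    xs <- vapply(wfs, function(w) w$values[i, j], numeric(1))
    brute_var <- brute_var + mean((xs - mean(xs))^2)
  }
  brute_var <- brute_var / (9 * 31)
  expect_equal(mean(gps2), brute_var, tolerance = 1e-12)
})
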