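test_that("responder classification respects the inclusive MCID boundary", {
  expect_equal(classify_responder(-1.6), "responder")
  expect_equal(classify_responder(-1.59), "non-responder")
  expect_equal(classify_responder(5), "non-responder")
  expect_error(classify_responder(NaN), "finite")
  # monotone: decreasing delta never flips responder -> non-responder
  deltas <- seq(2, -5, by = -0.1)
  cls <- classify_responder(deltas)
  flips <- which(cls[-1] == "non-responder" & cls[-length(cls)] == "responder")
  expect_length(flips, 0)
})

test_that("waveform RMSD matches direct evaluation", {
  set.seed(41)
  a <- random_waveforms()
  expect_equal(unname(waveform_rmsd(a, a)), rep(0, 9))
  b5 <- gait_cycle_waveforms(a$values + 5, side = "left")
  expect_equal(unname(waveform_rmsd(a, b5)), rep(5, 9), tolerance = 1e-12)
  b <- random_waveforms()
  brute <- vapply(1:9, function(j)
    sqrt(sum((a$values[, j] - b$values[, j])^2) / 101), numeric(1))
  expect_equal(unname(waveform_rmsd(a, b)), brute, tolerance = 1e-12)
})

test_that("waveform R2 is the linear-fit coefficient of determination", {
  set.seed(42)
  a <- random_waveforms()
  b <- gait_cycle_waveforms(2 * a$values + 3, side = "left")
  expect_equal(unname(waveform_r2(a, b)), rep(1, 9), tolerance = 1e-12)
  expect_equal(unname(waveform_r2(a, a)), rep(1, 9), tolerance = 1e-12)
  # normal-equations oracle on a random pair
  bb <- random_waveforms()
  r2 <- waveform_r2(a, bb)
  for (j in c(1, 5, 9)) {
    x <- bb$values[, j]; y <- a$values[, j]
    beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    alpha <- mean(y) - beta * mean(x)
    oracle <- 1 - sum((y - alpha - beta * x)^2) / sum((y - mean(y))^2)
    expect_equal(unname(r2[j]), oracle, tolerance = 1e-12)
  }
  const <- gait_cycle_waveforms(matrix(2, 101, 9,
                                       dimnames = list(NULL, gait_variables())),
                                side = "left")
  expect_error(waveform_r2(a, const), "constant")
})

test_that("Bland-Altman limits follow the stated formulas", {
  ba <- bland_altman(c(2, 3, 4), c(1, 1, 1))  # differences 1, 2, 3
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd, 1)
  expect_equal(ba$loa_low, 0.04, tolerance = 1e-12)
  expect_equal(ba$loa_high, 3.96, tolerance = 1e-12)
  x <- c(1.2, 3.4, 5.6, 2.2)
  ba0 <- bland_altman(x, x)
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  # swapping arguments negates the bias and reflects the limits
  set.seed(43)
  y <- x + stats::rnorm(4)
  f <- bland_altman(x, y); r <- bland_altman(y, x)
  expect_equal(r$bias, -f$bias)
  expect_equal(r$loa_low, -f$loa_high)
  expect_equal(r$loa_high, -f$loa_low)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("paired tests wrap the standard statistics correctly", {
  x <- c(3.1, 4.2, 5.9, 2.6, 7.4, 6.1)
  expect_equal(paired_tests(x, x + 0, "spearman")$statistic, 1)
  # strictly monotone transform: Spearman stays 1, Pearson drops below 1
  y <- exp(x)
  expect_equal(paired_tests(x, y, "spearman")$statistic, 1)
  expect_lt(paired_tests(x, y, "pearson")$statistic, 1)
  # hand-enumerated ranks for a small vector
  a <- c(10, 20, 30, 40, 50)
  b <- c(12, 18, 35, 30, 60)  # ranks of b: 1 2 4 3 5 -> rho = 1 - 6*2/(5*24)
  expect_equal(paired_tests(a, b, "spearman")$statistic, 1 - 12 / 120,
               tolerance = 1e-12)
  tt <- paired_tests(a, b, "paired_t")
  d <- a - b
  expect_equal(tt$statistic, mean(d) / (stats::sd(d) / sqrt(5)),
               tolerance = 1e-12)
  expect_error(paired_tests(1:5, 1:4), "lengths differ")
})

test_that("identical paired waveform sets produce an empty significance mask", {
  set.seed(44)
  a <- replicate(8, random_waveforms(T = 51), simplify = FALSE)
  res <- pointwise_waveform_test(a, a, n_permutations = 200)
  expect_equal(res$alpha_per_test, 0.05 / 9, tolerance = 1e-12)
  expect_equal(round(res$alpha_per_test, 4), 0.0056)
  for (v in gait_variables()) {
    expect_false(res$variables[[v]]$significant)
    expect_false(any(res$variables[[v]]$mask))
  }
})

test_that("a localised shift is detected in the shifted half of the cycle", {
  set.seed(45)
  Tn <- 51
  n <- 10
  make <- function(shift) {
    v <- matrix(stats::rnorm(Tn * 9, sd = 0.5), Tn, 9)
    colnames(v) <- gait_variables()
    if (shift) v[1:25, "hip_rotation"] <- v[1:25, "hip_rotation"] + 5
    gait_cycle_waveforms(v, side = "left")
  }
  a <- replicate(n, make(TRUE), simplify = FALSE)
  b <- replicate(n, make(FALSE), simplify = FALSE)
  res <- pointwise_waveform_test(a, b)
  hv <- res$variables$hip_rotation
  expect_true(hv$significant)
  expect_gt(mean(hv$mask[1:25]), 0.5)     # detected region overlaps the shift
  expect_lt(mean(hv$mask[26:51]), 0.2)    # and not the untouched half
})

test_that("insufficient permutations for the requested alpha raise an error", {
  set.seed(46)
  a <- replicate(20, random_waveforms(T = 11), simplify = FALSE)
  expect_error(pointwise_waveform_test(a, a, n_permutations = 100,
                                       exhaustive_limit = 4),
               "insufficient permutations")
})

test_that("Kruskal-Wallis + Dunn behave at the extremes", {
  set.seed(47)
  base <- stats::rnorm(12)
  same <- list(a = base, b = base, c = stats::rnorm(12))
  res <- group_axis_comparison(same)
  pw <- res$pairwise
  expect_equal(pw$z[pw$group1 == "a" & pw$group2 == "b"], 0, tolerance = 1e-12)
  far <- list(td = stats::rnorm(15), cp = stats::rnorm(15) + 100)
  expect_lt(group_axis_comparison(far)$omnibus$p_value, 1e-3)
  expect_error(group_axis_comparison(list(a = 1:5)), "2 groups")
})

test_that("omnibus p-values are uniform under the null", {
  # null-calibration oracle: identically distributed groups across seeds
  set.seed(48)
  ps <- replicate(200, {
    g <- list(a = stats::rnorm(8), b = stats::rnorm(8), c = stats::rnorm(8))
    group_axis_comparison(g)$omnibus$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))  # ranks tie occasionally
  expect_gt(ks$p.value, 0.01)
})

test_that("agreement tabulation counts matches and lists discordant limbs", {
  rec <- data.frame(
    subject = c("A", "A", "B"), side = c("left", "right", "left"),
    operated = TRUE,
    clinical_label = c("responder", "responder", "non-responder"),
    responder_dk = c("responder", "responder", "non-responder"),
    responder_ik = c("non-responder", "responder", "non-responder"),
    delta_gps_dk = c(-1.7, -3.0, 0.5),
    delta_gps_ik = c(-1.5, -3.2, 0.6),
    stringsAsFactors = FALSE)
  out <- tabulate_agreement(rec)
  expect_equal(out$n_limbs, 3)
  expect_equal(unname(out$clinical_agreement["dk"]), 3L)
  expect_equal(unname(out$clinical_agreement["ik"]), 2L)
  expect_equal(out$engine_concordance, 2L)
  expect_equal(out$discordant$delta_diff, 0.2, tolerance = 1e-12)
  # all labels identical: full agreement, empty discordance list
  rec2 <- rec
  rec2$responder_ik <- rec2$responder_dk
  out2 <- tabulate_agreement(rec2)
  expect_equal(out2$engine_concordance, 3L)
  expect_equal(nrow(out2$discordant), 0)
  rec3 <- rec
  rec3$clinical_label[2] <- NA
  expect_error(tabulate_agreement(rec3), "missing clinical label.*A")
})

test_that("the Bonferroni per-test alpha is 0.05/9", {
  expect_equal(round(per_test_alpha(), 4), 0.0056)
})
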