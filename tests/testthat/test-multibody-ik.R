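test_that("the exact pose is a fixed point of the solver", {
  m <- fixture_model()
  set.seed(61)
  b <- coordinate_bounds(m)
  q_star <- stats::setNames(stats::runif(18, pmax(b[, 1], -0.4),
                                         pmin(b[, 2], 0.4)),
                            coordinate_names(m))
  obs <- forward_kinematics(m, q_star)$markers
  sol <- solve_frame(m, obs, q0 = q_star)
  expect_lte(sol$iterations, 2)
  expect_lt(max(sol$residuals), 1e-10)
  expect_equal(unname(sol$q), unname(q_star), tolerance = 1e-10)
})

test_that("the generating pose is recovered from a perturbed start", {
  m <- fixture_model()
  set.seed(62)
  b <- coordinate_bounds(m)
  for (i in 1:5) {
    q_star <- stats::setNames(stats::runif(18, pmax(b[, 1], -0.4),
                                           pmin(b[, 2], 0.4)),
                              coordinate_names(m))
    obs <- forward_kinematics(m, q_star)$markers
    q0 <- q_star + stats::runif(18, -5, 5) * pi / 180
    q0 <- clamp(q0, b[, 1], b[, 2])
    sol <- solve_frame(m, obs, q0 = q0)
    rot <- !grepl("_t[xyz]$", names(sol$q))
    expect_lt(max(abs(sol$q[rot] - q_star[rot])) * 180 / pi, 1e-3)
  }
})

test_that("uniform weight scaling leaves the minimiser unchanged", {
  m <- fixture_model()
  x <- fixture_clean_trial()
  obs <- gaitprofile:::trial_frame(x$trial, 30)
  obs <- obs + matrix(stats::rnorm(length(obs), sd = 0.003), nrow(obs))
  s1 <- solve_frame(m, obs, cfg = ik_config())
  s2 <- solve_frame(m, obs, cfg = ik_config(
    marker_weights = c(RTHI = 1, LTHI = 1, RTIB = 1, LTIB = 1),
    default_weight = 2))
  expect_equal(unname(s1$q), unname(s2$q), tolerance = 1e-5)
  expect_equal(s2$objective, 2 * s1$objective, tolerance = 1e-6)
})

test_that("the analytic Jacobian matches finite differences", {
  m <- apply_knee_axis_correction(fixture_model(), "right", 14)
  set.seed(63)
  b <- coordinate_bounds(m)
  q <- stats::setNames(stats::runif(18, pmax(b[, 1], -0.3),
                                    pmin(b[, 2], 0.3)),
                       coordinate_names(m))
  labels <- pig_lower_limb_markers()
  fk <- gaitprofile:::.fk_core(m, q, marker_labels = labels, dof_info = TRUE)
  ancestry <- gaitprofile:::.segment_ancestral_dofs(m)
  h <- 1e-7
  for (lab in c("RTOE", "LKNE", "RTHI", "SACR")) {
    xm <- fk$markers[lab, ]
    seg <- fk$marker_segment[[lab]]
    for (dn in ancestry[[seg]]) {
      di <- fk$dof_info[[dn]]
      analytic <- if (di$type == "translation") di$w else
        gaitprofile:::cross3(di$w, xm - di$p)
      qp <- q; qp[dn] <- qp[dn] + h
      fd <- (gaitprofile:::.fk_core(m, qp, marker_labels = lab)$markers[lab, ] - xm) / h
      expect_equal(analytic, fd, tolerance = 1e-5)
    }
  }
})

test_that("under-determined frames are refused", {
  m <- fixture_model()
  obs <- forward_kinematics(m, rep(0, 18))$markers
  expect_error(solve_frame(m, obs[1:2, ]), "fewer than 3")
  # collinear observations
  obs3 <- rbind(LASI = c(0, 1, 0), RASI = c(0, 2, 0), SACR = c(0, 3, 0))
  expect_error(solve_frame(m, obs3), "collinear")
})

test_that("trial solve matches the generating coordinates on clean data", {
  x <- fixture_clean_trial()
  sub <- x$trial
  keep <- 1:60
  sub$time <- sub$time[keep]
  sub$markers <- lapply(sub$markers, function(mm) mm[keep, , drop = FALSE])
  ik <- solve_trial(x$model, sub)
  expect_true(all(ik$converged))
  rot <- !grepl("_t[xyz]$", colnames(ik$q_trajectory))
  err <- (ik$q_trajectory[, rot] - x$q[keep, rot]) * 180 / pi
  expect_lt(max(sqrt(colMeans(err^2))), 0.1)
  # objective at the solution is no worse than at the cold start
  obs <- gaitprofile:::trial_frame(sub, 10)
  cold <- gaitprofile:::.cold_start_ci(gaitprofile:::.free_coord_info(x$model), obs)
  pred0 <- forward_kinematics(x$model, cold, check = FALSE)$markers
  w <- gaitprofile:::.ik_weights(rownames(obs), ik_config())
  obj0 <- sum(w * rowSums((obs - pred0[rownames(obs), ])^2))
  sol <- solve_frame(x$model, obs)
  expect_lte(sol$objective, obj0)
})

test_that("warm and cold starts find the same minimiser on clean data", {
  x <- fixture_clean_trial()
  sub <- x$trial
  keep <- 1:25
  sub$time <- sub$time[keep]
  sub$markers <- lapply(sub$markers, function(mm) mm[keep, , drop = FALSE])
  warm <- solve_trial(x$model, sub, ik_config(warm_start = TRUE))
  cold <- solve_trial(x$model, sub, ik_config(warm_start = FALSE))
  expect_lt(max(abs(warm$q_trajectory - cold$q_trajectory)), 1e-4)
})

test_that("per-marker RMS errors reflect the configured artefact ordering", {
  m <- fixture_model()
  pat <- gait_pattern()
  sta <- sta_model(amplitude = 0.004,
                   marker_amplitudes = c(RTHI = 0.02, LTHI = 0.02,
                                         RTIB = 0.006, LTIB = 0.006))
  tr <- generate_trial(m, pat, n_cycles = 2, sta = sta, seed = 8)
  ik <- solve_trial(m, tr)
  expect_gt(ik$marker_rms[["RTHI"]], ik$marker_rms[["RTIB"]])
  expect_gt(ik$marker_rms[["LTHI"]], ik$marker_rms[["LTIB"]])
  qc <- marker_error_qc(ik)
  expect_true(all(c("marker", "rms_m", "within_limit") %in% names(qc)))
})

test_that("body kinematics reproduces pure translations and static poses", {
  m <- fixture_model()
  nf <- 10
  q <- matrix(0, nf, 18, dimnames = list(NULL, coordinate_names(m)))
  q[, "pelvis_tx"] <- seq(0, 0.9, length.out = nf)
  bk <- body_kinematics(m, q, time = seq(0, 0.09, by = 0.01))
  expect_equal(bk$pelvis_origin[, 1], seq(0, 0.9, length.out = nf),
               tolerance = 1e-12)
  expect_equal(diff(bk$jc$ankle_r[, 1]), diff(bk$pelvis_origin[, 1]),
               tolerance = 1e-12)
  q0 <- matrix(0, 3, 18, dimnames = list(NULL, coordinate_names(m)))
  bk0 <- body_kinematics(m, q0, time = 1:3)
  expect_equal(bk0$R$femur_r[, , 1], bk0$R$femur_r[, , 3])
  # frames equal the forward-kinematics oracle
  set.seed(64)
  b <- coordinate_bounds(m)
  qr <- matrix(stats::runif(2 * 18, pmax(b[, 1], -0.3), pmin(b[, 2], 0.3)),
               2, 18, byrow = TRUE, dimnames = list(NULL, coordinate_names(m)))
  bkr <- body_kinematics(m, qr, time = 1:2)
  for (f in 1:2) {
    fk <- forward_kinematics(m, qr[f, ])
    expect_equal(bkr$R$tibia_l[, , f], fk$frames$tibia_l$R, tolerance = 1e-10)
    expect_equal(bkr$jc$knee_r[f, ], fk$frames$tibia_r$origin,
                 tolerance = 1e-10)
  }
})
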