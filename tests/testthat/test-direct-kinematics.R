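test_that("chord construction satisfies its two metric conditions", {
  prox <- c(0, 0, 0.4); lat <- c(0.05, 0, 0); wand <- c(0.05, 0.1, 0.2)
  jc <- chord_joint_centre(prox, lat, wand, 0.05)
  # distance condition
  expect_equal(sqrt(sum((jc - lat)^2)), 0.05, tolerance = 1e-9)
  # perpendicularity condition
  expect_equal(sum((prox - jc) * (jc - lat)), 0, tolerance = 1e-9)
  # in-plane condition
  n <- gaitprofile:::cross3(lat - prox, wand - prox)
  expect_equal(sum(n * (jc - prox)) / sqrt(sum(n^2)), 0, tolerance = 1e-9)
})

test_that("chord construction fails when no perpendicular solution exists", {
  prox <- c(0, 0, 0.4); lat <- c(0.05, 0, 0); wand <- c(0.05, 0.1, 0.2)
  h <- sqrt(sum((prox - lat)^2))
  expect_error(chord_joint_centre(prox, lat, wand, h), "no perpendicular")
  expect_error(chord_joint_centre(prox, lat, prox + (lat - prox) * 0.5, 0.05),
               "collinear")
})

test_that("chord construction commutes with rigid transforms", {
  set.seed(21)
  prox <- c(0, 0, 0.4); lat <- c(0.05, 0, 0); wand <- c(0.05, 0.1, 0.2)
  jc <- chord_joint_centre(prox, lat, wand, 0.05)
  for (i in 1:10) {
    R <- random_rotation()
    t <- stats::rnorm(3)
    jc_t <- chord_joint_centre(as.numeric(R %*% prox + t),
                               as.numeric(R %*% lat + t),
                               as.numeric(R %*% wand + t), 0.05)
    expect_equal(jc_t, as.numeric(R %*% jc + t), tolerance = 1e-9)
  }
})

test_that("pelvis frame reproduces a known rigid pelvis motion", {
  m <- fixture_model()
  a <- fixture_anthro()
  # synthesise markers from a rigid rotation + translation of the pelvis
  nf <- 20
  time <- seq(0, 0.19, by = 0.01)
  ang <- seq(0, 0.3, length.out = nf)
  fk0 <- forward_kinematics(m, rep(0, 18))$markers
  labs <- pig_lower_limb_markers()
  markers <- lapply(labs, function(l) matrix(NA_real_, nf, 3))
  names(markers) <- labs
  Rs <- list()
  for (f in seq_len(nf)) {
    R <- compose_cardan(c(ang[f] * 57.29578, 5, -8),
                        clinical_axes("pelvis", "right"))
    Rs[[f]] <- R
    for (l in labs) {
      markers[[l]][f, ] <- as.numeric(R %*% fk0[l, ]) + c(0.01 * f, 0, 0)
    }
  }
  tr <- marker_trial(time, markers)
  fr <- build_pig_frames(tr, a)
  for (f in c(1, 10, 20)) {
    expect_equal(fr$R$pelvis[, , f], Rs[[f]], tolerance = 1e-9)
  }
})

test_that("thigh offset moves the knee centre but not the hip centre", {
  x <- fixture_clean_trial()
  f0 <- build_pig_frames(x$trial, fixture_anthro(),
                         thigh_offset_deg = c(left = 0, right = 0))
  f10 <- build_pig_frames(x$trial, fixture_anthro(),
                          thigh_offset_deg = c(left = 0, right = 10))
  expect_identical(f0$jc$hip_r, f10$jc$hip_r)
  expect_gt(max(abs(f0$jc$knee_r - f10$jc$knee_r)), 1e-4)
  expect_equal(f0$jc$knee_l, f10$jc$knee_l, tolerance = 1e-12)
})

test_that("marker gaps raise an error naming the frame and label", {
  x <- fixture_clean_trial()
  tr <- x$trial
  tr$markers$RKNE[5, 2] <- NA
  expect_error(build_pig_frames(tr, fixture_anthro()), "RKNE.*frame 5")
})

test_that("segment frames are orthonormal with determinant +1", {
  x <- fixture_clean_trial()
  fr <- build_pig_frames(x$trial, fixture_anthro())
  sub <- fr
  sub$R <- lapply(fr$R, function(a) a[, , seq(1, dim(a)[3], by = 37)])
  expect_silent(gaitprofile:::validate_segment_frames(sub))
})

test_that("a trial with three cycles yields three waveform sets per side", {
  x <- fixture_clean_trial()
  wfs <- extract_waveforms_dk(x$trial, fixture_anthro())
  expect_equal(sum(vapply(wfs, function(w) w$side == "left", logical(1))), 3)
  # right limb's first heel strike is at mid-cycle, so one fewer full cycle
  expect_equal(sum(vapply(wfs, function(w) w$side == "right", logical(1))), 2)
})

test_that("noiseless waveforms match the generating templates", {
  x <- fixture_clean_trial()
  wfs <- extract_waveforms_dk(x$trial, fixture_anthro())
  w <- wf_pick(wfs, "left", 2)
  phi <- seq(0, 1, length.out = 101)
  for (v in c("hip_flexion", "knee_flexion", "ankle_dorsiflexion",
              "pelvic_tilt", "hip_rotation", "hip_abduction")) {
    rms <- sqrt(mean((w$values[, v] - pattern_value(x$pattern, v, phi))^2))
    expect_lt(rms, 0.5)
  }
})

test_that("mirror-symmetric input gives equal left and right waveforms", {
  m <- fixture_model()
  # symmetric pattern: zero out the antisymmetric pelvis variables
  four <- gaitprofile:::.normative_fourier()
  four$pelvic_obliquity <- list(c0 = 0, a = c(0, 0, 0), b = c(0, 0, 0))
  four$pelvic_rotation <- list(c0 = 0, a = c(0, 0, 0), b = c(0, 0, 0))
  # cadence 120 puts cycle boundaries exactly on the frame grid, so both
  # limbs are sampled at identical phases
  pat <- gait_pattern(fourier = four, cadence = 120)
  tr <- generate_trial(m, pat, n_cycles = 3, sta = sta_none(), seed = 3)
  wfs <- extract_waveforms_dk(tr, fixture_anthro())
  wl <- wf_pick(wfs, "left", 2)$values
  wr <- wf_pick(wfs, "right", 1)$values  # right cycles start half a cycle in
  expect_equal(wl, wr, tolerance = 1e-6)
})

test_that("no complete cycle produces an empty result with a warning", {
  x <- fixture_clean_trial()
  tr <- x$trial
  tr$events$left$heel_strike <- tr$events$left$heel_strike[1]
  expect_warning(out <- extract_waveforms_dk(tr, fixture_anthro(),
                                             sides = "left"),
                 "no complete gait cycle")
  expect_length(out, 0)
})
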