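test_that("coordinate bookkeeping matches the joint structure", {
  m <- fixture_model()
  expect_equal(n_coordinates(m), 18)  # 6 + 2 x (3 + 1 + 1 + 1)
  m16 <- build_generic_model(subtalar_locked = TRUE)
  expect_equal(n_coordinates(m16), 16)
  co <- model_coordinates(m)
  expect_true(all(co$locked[grepl("^mtp_", co$name)]))  # MTP always locked
  expect_error(build_generic_model(marker_set_spec = c("LASI", "RASI")),
               "SACR")
})

test_that("zero pose is mirror-symmetric about the sagittal plane", {
  m <- fixture_model()
  fk <- forward_kinematics(m, rep(0, 18))
  mk <- fk$markers
  for (lab in c("THI", "KNE", "TIB", "ANK", "HEE", "TOE")) {
    r <- mk[paste0("R", lab), ]
    l <- mk[paste0("L", lab), ]
    expect_equal(r * c(1, -1, 1), l, tolerance = 1e-12)
  }
  expect_equal(mk["LASI", ] * c(1, -1, 1), mk["RASI", ], tolerance = 1e-12)
})

test_that("forward kinematics translates rigidly with the pelvis", {
  m <- fixture_model()
  q0 <- rep(0, 18)
  q1 <- q0
  names(q1) <- coordinate_names(m)
  q1["pelvis_tx"] <- 1
  a <- forward_kinematics(m, q0)$markers
  b <- forward_kinematics(m, q1)$markers
  expect_equal(b, a + rep(c(1, 0, 0), each = nrow(a)), tolerance = 1e-12)
})

test_that("forward kinematics agrees with an independent homogeneous-transform chain", {
  m <- fixture_model()
  set.seed(7)
  # independent oracle: 4x4 homogeneous transforms composed per segment
  hom_fk <- function(model, qv) {
    qv <- stats::setNames(qv, coordinate_names(model))
    Ts <- list()
    out <- NULL
    for (seg in model$segments) {
      Tl <- diag(4)
      Tl[1:3, 4] <- seg$origin
      for (d in seg$dofs) {
        val <- if (d$locked) d$value else qv[[d$name]]
        Td <- diag(4)
        if (d$type == "translation") {
          Td[1:3, 4] <- d$axis * val
        } else {
          Td[1:3, 1:3] <- gaitprofile:::rot_axis_angle(d$axis, val)
        }
        Tl <- Tl %*% Td
      }
      Tg <- if (is.na(seg$parent)) Tl else Ts[[seg$parent]] %*% Tl
      Ts[[seg$name]] <- Tg
      for (l in names(seg$markers)) {
        p <- Tg %*% c(seg$markers[[l]], 1)
        out <- rbind(out, stats::setNames(p[1:3], NULL))
        rownames(out)[nrow(out)] <- l
      }
    }
    out
  }
  b <- coordinate_bounds(m)
  for (i in 1:5) {
    q <- stats::runif(18, pmax(b[, 1], -0.5), pmin(b[, 2], 0.5))
    fk <- forward_kinematics(m, q)$markers
    oracle <- hom_fk(m, q)
    expect_equal(fk[rownames(oracle), ], oracle, tolerance = 1e-10)
  }
})

test_that("same-segment marker distances are invariant under any pose", {
  m <- fixture_model()
  set.seed(8)
  b <- coordinate_bounds(m)
  pairs <- list(c("RTHI", "RKNE"), c("RTIB", "RANK"), c("RHEE", "RTOE"),
                c("LASI", "SACR"))
  d0 <- NULL
  for (i in 1:10) {
    q <- stats::runif(18, pmax(b[, 1], -0.6), pmin(b[, 2], 0.6))
    mk <- forward_kinematics(m, q)$markers
    d <- vapply(pairs, function(p) sqrt(sum((mk[p[1], ] - mk[p[2], ])^2)),
                numeric(1))
    if (is.null(d0)) d0 <- d else expect_equal(d, d0, tolerance = 1e-12)
  }
})

test_that("coordinate vector length and bounds are enforced", {
  m <- fixture_model()
  expect_error(forward_kinematics(m, rep(0, 5)), "18")
  qbad <- rep(0, 18)
  names(qbad) <- coordinate_names(m)
  qbad["hip_flexion_r"] <- 10  # radians, far out of bounds
  expect_error(forward_kinematics(m, qbad), "out of bounds")
})

test_that("knee axis correction rotates only the knee hinge, reversibly", {
  m <- fixture_model()
  ax0 <- m$segments$tibia_r$dofs[[1]]$axis
  m1 <- apply_knee_axis_correction(m, "right", 15)
  m2 <- apply_knee_axis_correction(m1, "right", -15)
  expect_equal(m2$segments$tibia_r$dofs[[1]]$axis, ax0, tolerance = 1e-12)
  expect_equal(apply_knee_axis_correction(m, "right", 0), m)
  # unit norm preserved; hip and ankle axes untouched bit-for-bit
  expect_equal(sqrt(sum(m1$segments$tibia_r$dofs[[1]]$axis^2)), 1,
               tolerance = 1e-12)
  expect_identical(m1$segments$femur_r$dofs, m$segments$femur_r$dofs)
  expect_identical(m1$segments$talus_r$dofs, m$segments$talus_r$dofs)
  expect_identical(m1$segments$tibia_l$dofs, m$segments$tibia_l$dofs)
  expect_error(apply_knee_axis_correction(m, "right", 95), "90")
})

test_that("knee axis correction projects to the stated transverse-plane angle", {
  # oracle: explicit rotation-matrix construction and arccos of the
  # projected dot product
  m <- fixture_model()
  for (side in c("left", "right")) {
    seg <- paste0("tibia_", substr(side, 1, 1))
    old <- m$segments[[seg]]$dofs[[1]]$axis
    new <- apply_knee_axis_correction(m, side, 20)$segments[[seg]]$dofs[[1]]$axis
    po <- old[1:2] / sqrt(sum(old[1:2]^2))
    pn <- new[1:2] / sqrt(sum(new[1:2]^2))
    expect_equal(acos(sum(po * pn)) * 180 / pi, 20, tolerance = 1e-9)
  }
})

test_that("self-scaling returns unit factors", {
  m <- fixture_model()
  st <- generate_static_trial(m)
  sc <- scale_model(m, st, fixture_anthro())
  expect_equal(unname(sc$scale_set$pelvis_factors), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(sc$scale_set$femur_factor), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(sc$scale_set$tibia_factor), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(sc$scale_set$foot_factor), c(1, 1), tolerance = 1e-9)
})

test_that("a uniformly enlarged subject yields the enlargement as scale factor", {
  a <- fixture_anthro()
  big <- generic_anthropometry(
    leg_length = 1.2 * a$leg_length, ASIS_breadth = 1.2 * a$ASIS_breadth,
    knee_width = 1.2 * a$knee_width, ankle_width = 1.2 * a$ankle_width,
    height = 1.2 * a$height)
  m_big <- build_generic_model(anthropometry = big)
  st <- generate_static_trial(m_big)
  sc <- scale_model(fixture_model(), st, big)
  expect_equal(unname(sc$scale_set$femur_factor), c(1.2, 1.2), tolerance = 1e-6)
  expect_equal(unname(sc$scale_set$tibia_factor), c(1.2, 1.2), tolerance = 1e-6)
})

test_that("scaling is idempotent against the subject's own static pose", {
  a <- generic_anthropometry(leg_length = 0.7, height = 1.3,
                             ASIS_breadth = 0.2)
  subj <- build_generic_model(anthropometry = a)
  st <- generate_static_trial(subj)
  s1 <- scale_model(fixture_model(), st, a)
  s2 <- scale_model(s1$model, st, a)
  expect_equal(unname(s2$scale_set$femur_factor), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(s2$scale_set$pelvis_factors), rep(1, 3), tolerance = 1e-9)
})

test_that("degenerate static geometry raises an error", {
  m <- fixture_model()
  st <- generate_static_trial(m)
  st$markers$LASI <- st$markers$RASI  # zero ASIS breadth
  expect_error(scale_model(m, st, fixture_anthro()), "ASIS")
})

test_that("model YAML serialization round-trips loss-free", {
  m <- apply_knee_axis_correction(fixture_model(), "right", 12.5)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(m, p)
  m2 <- read_model_yaml(p)
  expect_equal(m2$segments, m$segments, tolerance = 1e-12)
  expect_equal(m2$knee_axis_correction_deg, m$knee_axis_correction_deg)
  q <- seq(-0.2, 0.2, length.out = 18)
  expect_equal(forward_kinematics(m2, q)$markers,
               forward_kinematics(m, q)$markers, tolerance = 1e-12)
})
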