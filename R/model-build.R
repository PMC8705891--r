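# Construction of the generic constrained lower-limb model.
#
# The kinematic structure follows the classic lower-limb multibody layout:
# a 6-DoF pelvis root, per leg a 3-DoF ball hip, a 1-DoF knee hinge, a 1-DoF
# tibiotalar hinge and a 1-DoF subtalar hinge (lockable); the
# metatarsophalangeal joint is permanently locked. Geometry (segment lengths
# and surface-marker placements) is a documented parametric constants table
# driven by anthropometry, not a mesh.
#
# Laboratory frame convention used throughout the package:
#   X = direction of walking progression, Y = left, Z = up (right-handed).
# All internal lengths are metres and all internal angles radians; degrees
# appear only at the user/file boundary.

#' Plug-in-Gait lower-limb marker labels
#'
#' The mandatory marker set: pelvis (LASI, RASI, SACR) plus, per side, thigh
#' wand (THI), lateral knee (KNE), shank wand (TIB), lateral malleolus (ANK),
#' heel (HEE) and toe (TOE).
#'
#' @return character vector of 15 marker labels.
#' @export
pig_lower_limb_markers <- function() {
  c("LASI", "RASI", "SACR",
    paste0("R", c("THI", "KNE", "TIB", "ANK", "HEE", "TOE")),
    paste0("L", c("THI", "KNE", "TIB", "ANK", "HEE", "TOE")))
}

#' Default anthropometry matching the generic model
#'
#' Measurements (metres, kg, years) for which [build_generic_model()] returns
#' its reference geometry. Used as the default subject and as the basis of
#' self-consistent scaling tests.
#'
#' @param ... named overrides of individual fields.
#' @return an object of class `anthropometry`.
#' @export
generic_anthropometry <- function(...) {
  a <- list(leg_length = 0.86, ASIS_breadth = 0.24, knee_width = 0.10,
            ankle_width = 0.07, mass = 45, height = 1.55, age = 14)
  dots <- list(...)
  a[names(dots)] <- dots
  validate_anthropometry(a)
}

validate_anthropometry <- function(a) {
  need <- c("leg_length", "ASIS_breadth", "knee_width", "ankle_width",
            "mass", "height", "age")
  miss <- setdiff(need, names(a))
  assert_that(length(miss) == 0, "anthropometry missing field(s): %s",
              paste(miss, collapse = ", "))
  for (f in need) {
    assert_that(is_scalar_number(a[[f]]) && a[[f]] > 0,
                "anthropometry field `%s` must be a strictly positive number", f)
  }
  structure(a, class = "anthropometry")
}

# Fixed geometric ratios of the parametric generic geometry (documented
# constants; see the methods vignette for provenance and rationale).
.geom_const <- list(
  pelvis_depth_ratio = 0.625,   # ASIS-midpoint-to-SACR depth / ASIS breadth
  femur_ratio  = 0.46,          # hip-to-knee centre length / leg length
  tibia_ratio  = 0.42,          # knee-to-ankle centre length / leg length
  ankle_height_ratio = 0.05,    # ankle centre to subtalar/foot origin
  foot_ratio   = 0.25,          # foot length / leg length
  marker_radius = 0.005,        # marker-centre offset beyond the half-width
  thigh_wand_extra = 0.025,     # wand lateral stand-off beyond knee half-width
  shank_wand_extra = 0.020,
  thigh_wand_height = -0.45,    # along femur, fraction of femur length
  shank_wand_height = -0.40
)

#' Hip joint centre location from pelvic dimensions
#'
#' Regression of Harrington et al. (J Biomech 2007) mapping pelvic width
#' (inter-ASIS distance) and pelvic depth (ASIS midpoint to sacrum) to the
#' hip joint centre in the pelvis frame, re-expressed in this package's
#' frame convention (X anterior, Y left, Z up; origin at the ASIS midpoint).
#'
#' @param pelvic_width,pelvic_depth metres.
#' @param side `"left"` or `"right"`.
#' @return numeric length-3 hip joint centre in the pelvis frame (metres).
#' @export
hip_joint_centre_regression <- function(pelvic_width, pelvic_depth, side) {
  check_side(side)
  # Harrington 2007 (mm): x = -0.24 PD - 9.9; y = -0.30 PW - 10.9 (vertical,
  # down negative); z = 0.33 PW + 7.3 (lateral).
  x_ant <- -0.24 * pelvic_depth - 0.0099
  y_up  <- -0.30 * pelvic_width - 0.0109
  z_lat <-  0.33 * pelvic_width + 0.0073
  lat <- if (side == "right") -z_lat else z_lat  # lateral: right = -Y
  c(x_ant, lat, y_up)
}

.make_dof <- function(name, type, axis, bounds, locked = FALSE) {
  list(name = name, type = type, axis = unitize(axis),
       bounds = bounds, locked = locked, value = 0)
}

.make_segment <- function(name, parent, origin, dofs, markers = list()) {
  list(name = name, parent = parent, origin = origin,
       dofs = dofs, markers = markers)
}

#' Build the generic constrained lower-limb model
#'
#' Constructs the kinematic chain (pelvis root with 3 translations + 3
#' rotations; per leg a 3-DoF hip, knee hinge, tibiotalar hinge, subtalar
#' hinge; metatarsophalangeal joint permanently locked) with parametric
#' geometry driven by `anthropometry`. Hip joint centres are placed by
#' [hip_joint_centre_regression()], so the direct-kinematics hip-centre
#' estimate and the model agree exactly for noise-free data.
#'
#' At the zero pose the model stands in the laboratory frame with the ASIS
#' midpoint at the origin and left/right markers mirror-symmetric about the
#' sagittal (XZ) plane.
#'
#' @param marker_set_spec character vector of marker labels that must be
#'   covered; must include the mandatory Plug-in-Gait lower-limb labels.
#' @param anthropometry an [generic_anthropometry()] object.
#' @param subtalar_locked lock both subtalar hinges at 0 (default `FALSE`).
#' @return an object of class `skeletal_model`.
#' @export
#' @examples
#' m <- build_generic_model()
#' n_coordinates(m)  # 18
build_generic_model <- function(marker_set_spec = pig_lower_limb_markers(),
                                anthropometry = generic_anthropometry(),
                                subtalar_locked = FALSE) {
  a <- validate_anthropometry(anthropometry)
  miss <- setdiff(pig_lower_limb_markers(), marker_set_spec)
  assert_that(length(miss) == 0,
              "marker set specification is missing mandatory label(s): %s",
              paste(miss, collapse = ", "))
  g <- .geom_const
  PW <- a$ASIS_breadth
  PD <- g$pelvis_depth_ratio * PW
  LL <- a$leg_length
  L_f <- g$femur_ratio * LL
  L_t <- g$tibia_ratio * LL
  h_a <- g$ankle_height_ratio * LL
  flen <- g$foot_ratio * LL
  d_knee  <- a$knee_width / 2 + g$marker_radius
  d_ankle <- a$ankle_width / 2 + g$marker_radius

  big <- c(-10, 10)  # translation bounds (m)
  r45 <- deg2rad(c(-45, 45))

  pelvis <- .make_segment(
    "pelvis", NA_character_, c(0, 0, 0),
    dofs = list(
      .make_dof("pelvis_tx", "translation", c(1, 0, 0), big),
      .make_dof("pelvis_ty", "translation", c(0, 1, 0), big),
      .make_dof("pelvis_tz", "translation", c(0, 0, 1), big),
      .make_dof("pelvis_tilt",      "rotation", c(0, 1, 0), r45),
      .make_dof("pelvis_obliquity", "rotation", c(1, 0, 0), r45),
      .make_dof("pelvis_rotation",  "rotation", c(0, 0, 1), r45)
    ),
    markers = list(LASI = c(0,  PW / 2, 0),
                   RASI = c(0, -PW / 2, 0),
                   SACR = c(-PD, 0, 0))
  )

  leg <- function(side) {
    s <- if (side == "right") -1 else 1      # lateral direction sign (+Y left)
    ss <- if (side == "right") 1 else -1     # axis mirroring sign
    P <- if (side == "right") "R" else "L"
    hjc <- hip_joint_centre_regression(PW, PD, side)
    sub_axis <- unitize(c(0.787, ss * -0.120, 0.605))
    list(
      femur = .make_segment(
        paste0("femur_", substr(side, 1, 1)), "pelvis", hjc,
        dofs = list(
          .make_dof(paste0("hip_flexion_", substr(side, 1, 1)), "rotation",
                    c(0, -1, 0), deg2rad(c(-40, 130))),
          .make_dof(paste0("hip_adduction_", substr(side, 1, 1)), "rotation",
                    c(ss, 0, 0), deg2rad(c(-60, 60))),
          .make_dof(paste0("hip_rotation_", substr(side, 1, 1)), "rotation",
                    c(0, 0, ss), deg2rad(c(-60, 60)))
        ),
        markers = stats::setNames(list(
          c(0, s * (a$knee_width / 2 + g$thigh_wand_extra), g$thigh_wand_height * L_f),
          c(0, s * d_knee, -L_f)
        ), paste0(P, c("THI", "KNE")))
      ),
      tibia = .make_segment(
        paste0("tibia_", substr(side, 1, 1)), paste0("femur_", substr(side, 1, 1)),
        c(0, 0, -L_f),
        dofs = list(
          .make_dof(paste0("knee_flexion_", substr(side, 1, 1)), "rotation",
                    c(0, 1, 0), deg2rad(c(-10, 140)))
        ),
        markers = stats::setNames(list(
          c(0, s * (a$ankle_width / 2 + g$shank_wand_extra), g$shank_wand_height * L_t),
          c(0, s * d_ankle, -L_t)
        ), paste0(P, c("TIB", "ANK")))
      ),
      talus = .make_segment(
        paste0("talus_", substr(side, 1, 1)), paste0("tibia_", substr(side, 1, 1)),
        c(0, 0, -L_t),
        dofs = list(
          .make_dof(paste0("ankle_flexion_", substr(side, 1, 1)), "rotation",
                    c(0, -1, 0), deg2rad(c(-50, 50)))
        )
      ),
      foot = .make_segment(
        paste0("foot_", substr(side, 1, 1)), paste0("talus_", substr(side, 1, 1)),
        c(0, 0, -h_a),
        dofs = list(
          .make_dof(paste0("subtalar_", substr(side, 1, 1)), "rotation",
                    sub_axis, deg2rad(c(-30, 30)), locked = subtalar_locked)
        ),
        # heel and toe markers sit on the foot midline (calcaneus / second
        # metatarsal head) at equal height, so the foot long axis they span
        # is yaw-stable under transverse-plane projection
        markers = stats::setNames(list(
          c(-0.3 * flen, 0, 0.01),
          c(0.6 * flen, 0, 0.01)
        ), paste0(P, c("HEE", "TOE")))
      ),
      toes = .make_segment(
        paste0("toes_", substr(side, 1, 1)), paste0("foot_", substr(side, 1, 1)),
        c(0.4 * flen, s * 0.01, 0),
        dofs = list(
          # metatarsophalangeal joint: present, permanently locked
          .make_dof(paste0("mtp_", substr(side, 1, 1)), "rotation",
                    c(0, 1, 0), deg2rad(c(-30, 60)), locked = TRUE)
        )
      )
    )
  }

  rl <- leg("right"); ll <- leg("left")
  segments <- c(list(pelvis = pelvis),
                stats::setNames(rl, vapply(rl, `[[`, "", "name")),
                stats::setNames(ll, vapply(ll, `[[`, "", "name")))

  model <- structure(list(
    segments = segments,
    anthropometry = a,
    knee_axis_correction_deg = c(left = 0, right = 0),
    marker_radius = g$marker_radius,
    geometry = list(femur_length = c(left = L_f, right = L_f),
                    tibia_length = c(left = L_t, right = L_t),
                    ankle_height = c(left = h_a, right = h_a),
                    foot_length = c(left = flen, right = flen),
                    pelvic_width = PW, pelvic_depth = PD)
  ), class = "skeletal_model")
  validate_model(model)
}

#' @export
print.skeletal_model <- function(x, ...) {
  cat("<skeletal_model>\n")
  cat("  segments:", length(x$segments),
      " free coordinates:", n_coordinates(x), "\n")
  cat("  markers:", length(model_marker_labels(x)), "\n")
  cat("  knee axis correction (deg): left",
      x$knee_axis_correction_deg[["left"]], ", right",
      x$knee_axis_correction_deg[["right"]], "\n")
  invisible(x)
}

#' Coordinate bookkeeping
#'
#' `model_coordinates()` returns a data frame describing every degree of
#' freedom (including locked ones); `n_coordinates()` counts the free
#' (unlocked) coordinates; `coordinate_names()` lists them in order.
#'
#' @param model a `skeletal_model`.
#' @return see description.
#' @export
model_coordinates <- function(model) {
  rows <- list()
  for (seg in model$segments) {
    for (d in seg$dofs) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = d$name, segment = seg$name, type = d$type,
        locked = d$locked, lower = d$bounds[1], upper = d$bounds[2],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Flat free-coordinate info without data.frame overhead (hot path).
.free_coord_info <- function(model) {
  nm <- character(); lo <- numeric(); hi <- numeric()
  for (seg in model$segments) {
    for (d in seg$dofs) {
      if (!d$locked) {
        nm <- c(nm, d$name); lo <- c(lo, d$bounds[1]); hi <- c(hi, d$bounds[2])
      }
    }
  }
  list(names = nm, lower = lo, upper = hi)
}

#' @rdname model_coordinates
#' @export
n_coordinates <- function(model) length(.free_coord_info(model)$names)

#' @rdname model_coordinates
#' @export
coordinate_names <- function(model) .free_coord_info(model)$names

#' @rdname model_coordinates
#' @export
coordinate_bounds <- function(model) {
  ci <- .free_coord_info(model)
  cbind(lower = ci$lower, upper = ci$upper)
}

model_marker_labels <- function(model) {
  unlist(lapply(model$segments, function(s) names(s$markers)), use.names = FALSE)
}

validate_model <- function(model) {
  assert_that(inherits(model, "skeletal_model"), "not a skeletal_model")
  segs <- model$segments
  assert_that(identical(segs[[1]]$name, "pelvis") && is.na(segs[[1]]$parent),
              "pelvis must be the root segment")
  seen <- character()
  for (seg in segs) {
    if (!is.na(seg$parent)) {
      assert_that(seg$parent %in% seen,
                  "segments must be topologically sorted; `%s` precedes its parent `%s`",
                  seg$name, seg$parent)
    }
    seen <- c(seen, seg$name)
    for (d in seg$dofs) {
      assert_that(abs(vnorm(d$axis) - 1) < 1e-9,
                  "axis of dof `%s` is not unit length", d$name)
      assert_that(d$bounds[1] < d$bounds[2], "bad bounds for dof `%s`", d$name)
    }
  }
  lab <- model_marker_labels(model)
  assert_that(!anyDuplicated(lab), "duplicate marker labels in model")
  invisible(model)
}

#' Lock or unlock the subtalar joints
#'
#' @param model a `skeletal_model`.
#' @param locked logical.
#' @return the modified model.
#' @export
set_subtalar_locked <- function(model, locked = TRUE) {
  for (nm in c("foot_r", "foot_l")) {
    for (i in seq_along(model$segments[[nm]]$dofs)) {
      model$segments[[nm]]$dofs[[i]]$locked <- locked
    }
  }
  model
}

#' Rotate a knee flexion axis in the transverse plane
#'
#' Applies the knee-alignment-device (KAD) derived correction: the knee hinge
#' axis of the given side is rotated about the femur's longitudinal (vertical)
#' axis by `kad_axis_angle_deg`. Positive angles rotate the axis into internal
#' (medial) rotation for that side. All other axes are untouched and the
#' applied angle is accumulated in `knee_axis_correction_deg`.
#'
#' @param model a `skeletal_model`.
#' @param side `"left"` or `"right"`.
#' @param kad_axis_angle_deg signed angle in degrees, |angle| < 90.
#' @return the modified model.
#' @export
apply_knee_axis_correction <- function(model, side, kad_axis_angle_deg) {
  check_side(side)
  assert_that(is_scalar_number(kad_axis_angle_deg) &&
                abs(kad_axis_angle_deg) < 90,
              "kad_axis_angle_deg must be a finite angle with |angle| < 90")
  ss <- if (side == "right") 1 else -1  # internal rotation axis sign
  seg <- paste0("tibia_", substr(side, 1, 1))
  R <- rot_axis_angle(c(0, 0, ss), deg2rad(kad_axis_angle_deg))
  i <- which(vapply(model$segments[[seg]]$dofs, function(d)
    startsWith(d$name, "knee_flexion"), logical(1)))
  old <- model$segments[[seg]]$dofs[[i]]$axis
  model$segments[[seg]]$dofs[[i]]$axis <- as.numeric(R %*% old)
  model$knee_axis_correction_deg[[side]] <-
    model$knee_axis_correction_deg[[side]] + kad_axis_angle_deg
  model
}
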