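# Direct (conventional gait model) kinematics engine: segment frames are
# built per frame straight from surface markers, joint centres come from the
# chord construction and a hip-centre regression, and joint angles are Cardan
# decompositions of relative frame rotations.

#' Chord construction for a joint centre
#'
#' The conventional-gait-model primitive: given an already-known proximal
#' joint centre, a lateral surface marker and a wand marker, the joint centre
#' is the point lying in the plane of the three inputs, at distance `offset`
#' from the lateral marker, such that the segment from the proximal centre to
#' the result is perpendicular to the segment from the result to the lateral
#' marker.
#'
#' Two points in the plane satisfy these conditions; the anatomically correct
#' one is selected as the candidate for which the lateral and wand markers
#' lie on the same side (maximal agreement of the directions result->lateral
#' and result->wand).
#'
#' @param proximal_jc,lateral_marker,wand_marker numeric length-3 points (m).
#' @param offset distance from the lateral marker to the joint centre
#'   (half joint width + marker radius), metres, > 0.
#' @return numeric length-3 joint centre.
#' @export
chord_joint_centre <- function(proximal_jc, lateral_marker, wand_marker, offset) {
  assert_that(is_scalar_number(offset) && offset > 0, "offset must be > 0")
  v <- proximal_jc - lateral_marker
  h <- vnorm(v)
  w <- wand_marker - lateral_marker
  nrm <- cross3(v, w)
  assert_that(vnorm(nrm) > 1e-10 * h * vnorm(w),
              "chord construction: the three input points are collinear")
  assert_that(offset < h * (1 - 1e-9),
              "chord construction: offset >= proximal-to-lateral distance, no perpendicular solution")
  e1 <- v / h
  n <- unitize(nrm)
  e2 <- cross3(n, e1)
  ct <- offset / h
  st <- sqrt(1 - ct^2)
  cand <- list(lateral_marker + offset * (ct * e1 + st * e2),
               lateral_marker + offset * (ct * e1 - st * e2))
  score <- vapply(cand, function(r)
    sum(unitize(lateral_marker - r) * unitize(wand_marker - r)), numeric(1))
  cand[[which.max(score)]]
}

# Vectorised chord over F frames (all inputs F x 3). Same selection rule.
.chord_rows <- function(prox, lat, wand, offset) {
  v <- prox - lat
  h <- row_norms(v)
  if (any(offset >= h * (1 - 1e-9))) {
    stopf("chord construction: offset >= proximal-to-lateral distance at frame %d",
          which(offset >= h * (1 - 1e-9))[1])
  }
  w <- wand - lat
  nr <- row_cross(v, w)
  if (any(row_norms(nr) < 1e-10 * h * row_norms(w))) {
    stopf("chord construction: collinear markers at frame %d",
          which(row_norms(nr) < 1e-10 * h * row_norms(w))[1])
  }
  e1 <- v / h
  n <- row_unit(nr)
  e2 <- row_cross(n, e1)
  ct <- offset / h
  st <- sqrt(pmax(0, 1 - ct^2))
  r1 <- lat + offset * (ct * e1 + st * e2)
  r2 <- lat + offset * (ct * e1 - st * e2)
  s1 <- rowSums(row_unit(lat - r1) * row_unit(wand - r1))
  s2 <- rowSums(row_unit(lat - r2) * row_unit(wand - r2))
  pick1 <- s1 >= s2
  r1[!pick1, ] <- r2[!pick1, ]
  r1
}

.require_markers <- function(trial, labels) {
  miss <- setdiff(labels, names(trial$markers))
  assert_that(length(miss) == 0, "trial is missing mandatory marker(s): %s",
              paste(miss, collapse = ", "))
  for (l in labels) {
    bad <- which(!stats::complete.cases(trial$markers[[l]]))
    if (length(bad)) {
      stopf("marker gap: label %s has missing samples starting at frame %d (no interpolation by default)",
            l, bad[1])
    }
  }
  invisible(TRUE)
}

#' Build segment frames from Plug-in-Gait-style markers
#'
#' Constructs per-frame pelvis, femur, tibia and foot frames. The pelvis
#' frame comes from LASI/RASI/SACR; hip joint centres from
#' [hip_joint_centre_regression()] applied in the pelvis frame; knee and
#' ankle centres from [chord_joint_centre()] with the subject's knee/ankle
#' widths; the foot frame from heel/toe markers and the ankle construction.
#' `thigh_offset_deg` rotates the thigh wand about the hip-centre-to-knee-
#' marker axis (right-hand rule about that downward axis) before the knee
#' chord construction, the usual post-hoc knee-axis alignment adjustment.
#'
#' @param trial a [marker_trial()] containing the mandatory lower-limb set.
#' @param anthropometry an [generic_anthropometry()] object for the subject.
#' @param thigh_offset_deg named numeric `c(left=, right=)` wand rotation
#'   offsets in degrees.
#' @param marker_radius marker-centre stand-off added to half-widths (m).
#' @return an object of class `segment_frames`: per-segment rotation arrays
#'   (3x3xF) and origins, joint-centre trajectories, the pelvis origin
#'   trajectory, and foot landmark trajectories.
#' @export
build_pig_frames <- function(trial, anthropometry,
                             thigh_offset_deg = c(left = 0, right = 0),
                             marker_radius = 0.005) {
  a <- validate_anthropometry(anthropometry)
  .require_markers(trial, pig_lower_limb_markers())
  mk <- trial$markers
  nf <- n_frames(trial)

  lasi <- mk$LASI; rasi <- mk$RASI; sacr <- mk$SACR
  mid <- (lasi + rasi) / 2
  Yp <- lasi - rasi
  if (any(row_norms(Yp) < 1e-9)) stopf("degenerate pelvis geometry: zero ASIS breadth")
  Yp <- row_unit(Yp)
  vv <- mid - sacr
  Xp <- vv - rowSums(vv * Yp) * Yp
  if (any(row_norms(Xp) < 1e-9)) stopf("degenerate pelvis geometry: collinear pelvis markers")
  Xp <- row_unit(Xp)
  Zp <- row_cross(Xp, Yp)

  PW <- mean(row_norms(lasi - rasi))
  PD <- mean(row_norms(mid - sacr))

  R <- list(); O <- list(); jc <- list(); pts <- list()
  R$pelvis <- .frames_from_axes(Xp, Yp, Zp)
  O$pelvis <- mid

  d_knee <- a$knee_width / 2 + marker_radius
  d_ankle <- a$ankle_width / 2 + marker_radius

  for (side in c("left", "right")) {
    P <- if (side == "right") "R" else "L"
    sfx <- substr(side, 1, 1)
    hjc_loc <- hip_joint_centre_regression(PW, PD, side)
    hipc <- mid + hjc_loc[1] * Xp + hjc_loc[2] * Yp + hjc_loc[3] * Zp

    kne <- mk[[paste0(P, "KNE")]]
    thi <- mk[[paste0(P, "THI")]]
    off <- thigh_offset_deg[[side]] %||% 0
    if (off != 0) thi <- .rotate_about_line(thi, hipc, kne, deg2rad(off))
    kneec <- .chord_rows(hipc, kne, thi, d_knee)

    ank <- mk[[paste0(P, "ANK")]]
    tib <- mk[[paste0(P, "TIB")]]
    anklec <- .chord_rows(kneec, ank, tib, d_ankle)

    ml_knee <- if (side == "right") kneec - kne else kne - kneec
    Zf <- row_unit(hipc - kneec)
    Xf <- row_unit(row_cross(ml_knee, Zf))
    Yf <- row_cross(Zf, Xf)
    R[[paste0("femur_", sfx)]] <- .frames_from_axes(Xf, Yf, Zf)
    O[[paste0("femur_", sfx)]] <- hipc

    ml_ank <- if (side == "right") anklec - ank else ank - anklec
    Zt <- row_unit(kneec - anklec)
    Xt <- row_unit(row_cross(ml_ank, Zt))
    Yt <- row_cross(Zt, Xt)
    R[[paste0("tibia_", sfx)]] <- .frames_from_axes(Xt, Yt, Zt)
    O[[paste0("tibia_", sfx)]] <- kneec

    hee <- mk[[paste0(P, "HEE")]]
    toe <- mk[[paste0(P, "TOE")]]
    Xo <- row_unit(toe - hee)
    Zo <- row_unit(row_cross(Xo, ml_ank))
    Yo <- row_cross(Zo, Xo)
    R[[paste0("foot_", sfx)]] <- .frames_from_axes(Xo, Yo, Zo)
    O[[paste0("foot_", sfx)]] <- anklec

    jc[[paste0("hip_", sfx)]] <- hipc
    jc[[paste0("knee_", sfx)]] <- kneec
    jc[[paste0("ankle_", sfx)]] <- anklec
    pts[[paste0("TOE_", sfx)]] <- toe
    pts[[paste0("HEE_", sfx)]] <- hee
  }

  structure(list(time = trial$time, R = R, origin = O, jc = jc,
                 pelvis_origin = mid, points = pts, source = "direct"),
            class = "segment_frames")
}

# Stack per-frame axis rows into a 3x3xF rotation array with columns X,Y,Z.
.frames_from_axes <- function(X, Y, Z) {
  nf <- nrow(X)
  arr <- array(0, c(3, 3, nf))
  arr[, 1, ] <- t(X); arr[, 2, ] <- t(Y); arr[, 3, ] <- t(Z)
  arr
}

# Rotate points (F x 3) about the per-frame line a->b by angle (radians).
.rotate_about_line <- function(p, a, b, angle) {
  axis <- row_unit(b - a)
  rel <- p - a
  ca <- cos(angle); sa <- sin(angle)
  dot <- rowSums(axis * rel)
  rel_rot <- ca * rel + sa * row_cross(axis, rel) + (1 - ca) * dot * axis
  a + rel_rot
}

#' @export
print.segment_frames <- function(x, ...) {
  cat("<segment_frames>", length(x$time), "frames,",
      length(x$R), "segments, source:", x$source, "\n")
  invisible(x)
}

validate_segment_frames <- function(frames, tol = 1e-9) {
  for (s in names(frames$R)) {
    arr <- frames$R[[s]]
    for (f in seq_len(dim(arr)[3])) {
      Rf <- arr[, , f]
      assert_that(max(abs(crossprod(Rf) - diag(3))) < tol,
                  "frame %d of segment %s not orthonormal", f, s)
      assert_that(abs(det(Rf) - 1) < tol,
                  "frame %d of segment %s has determinant != +1", f, s)
    }
  }
  invisible(TRUE)
}

# Per-frame Cardan angle series (degrees) between two rotation arrays.
.angle_series <- function(Rp_arr, Rc_arr, axes) {
  nf <- dim(Rc_arr)[3]
  out <- matrix(NA_real_, nf, 3)
  for (f in seq_len(nf)) {
    Rp <- if (is.null(Rp_arr)) diag(3) else Rp_arr[, , f]
    out[f, ] <- .cardan_from_rel(crossprod(Rp, Rc_arr[, , f]), axes)
  }
  out
}

# All nine variable series (degrees, per frame) for one side, from a
# segment_frames object. Foot progression is handled per cycle, not here.
.joint_angle_series <- function(frames, side) {
  sfx <- substr(side, 1, 1)
  pel <- .angle_series(NULL, frames$R$pelvis, clinical_axes("pelvis", side))
  hip <- .angle_series(frames$R$pelvis, frames$R[[paste0("femur_", sfx)]],
                       clinical_axes("hip", side))
  kne <- .angle_series(frames$R[[paste0("femur_", sfx)]],
                       frames$R[[paste0("tibia_", sfx)]],
                       clinical_axes("knee", side))
  ank <- .angle_series(frames$R[[paste0("tibia_", sfx)]],
                       frames$R[[paste0("foot_", sfx)]],
                       clinical_axes("ankle", side))
  cbind(pelvic_tilt = pel[, 1], pelvic_obliquity = pel[, 2],
        pelvic_rotation = pel[, 3],
        hip_flexion = hip[, 1], hip_abduction = hip[, 2],
        hip_rotation = hip[, 3],
        knee_flexion = kne[, 1], ankle_dorsiflexion = ank[, 1])
}

#' Extract per-cycle time-normalised waveforms from segment frames
#'
#' Produces one [gait_cycle_waveforms()] object per complete gait cycle and
#' side: the eight pelvis/joint angles plus the foot progression angle, each
#' time-normalised to `T` points over the cycle.
#'
#' Sign conventions (documented, clinical): flexion +, adduction +
#' (the `hip_abduction` variable follows the conventional gait chart and is
#' adduction-positive), internal rotation +, dorsiflexion +, anterior pelvic
#' tilt +; pelvic obliquity/rotation and foot progression are mirrored for
#' the left side so that left and right waveforms are directly comparable.
#'
#' @param frames a `segment_frames` object (from [build_pig_frames()] or
#'   [body_kinematics()]).
#' @param events the `events` element of the source trial.
#' @param sides sides to extract.
#' @param T number of normalised time points (default 101, 0-100% inclusive).
#' @param meta metadata list copied onto each waveform set.
#' @return list of `gait_cycle_waveforms`.
#' @export
extract_waveforms <- function(frames, events, sides = c("left", "right"),
                              T = 101, meta = list()) {
  out <- list()
  for (side in sides) {
    hs <- events[[side]]$heel_strike
    if (is.null(hs) || length(hs) < 2) {
      warning("no complete gait cycle for side ", side)
      next
    }
    series <- .joint_angle_series(frames, side)
    sfx <- substr(side, 1, 1)
    for (ci in seq_len(length(hs) - 1)) {
      t0 <- hs[ci]; t1 <- hs[ci + 1]
      vals <- matrix(NA_real_, T, length(gait_variables()))
      colnames(vals) <- gait_variables()
      for (v in colnames(series)) {
        vals[, v] <- time_normalise(series[, v], frames$time, t0, t1, T)
      }
      vals[, "foot_progression"] <- foot_progression_angle(
        frames$pelvis_origin,
        frames$jc[[paste0("ankle_", sfx)]],
        frames$points[[paste0("TOE_", sfx)]],
        frames$time, t0, t1, T, side = side)
      out[[length(out) + 1L]] <- gait_cycle_waveforms(
        vals, side = side, cycle = ci, meta = meta)
    }
  }
  out
}

#' Direct-kinematics waveforms for a trial
#'
#' Convenience wrapper: builds Plug-in-Gait-style frames and extracts
#' per-cycle waveforms.
#'
#' @inheritParams build_pig_frames
#' @inheritParams extract_waveforms
#' @return list of `gait_cycle_waveforms`.
#' @export
extract_waveforms_dk <- function(trial, anthropometry,
                                 thigh_offset_deg = c(left = 0, right = 0),
                                 sides = c("left", "right"), T = 101) {
  frames <- build_pig_frames(trial, anthropometry, thigh_offset_deg)
  extract_waveforms(frames, trial$events, sides = sides, T = T,
                    meta = c(trial$meta, list(engine = "dk")))
}
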