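# Gait Variable Score / Gait Profile Score metrics, time normalisation,
# trial averaging, foot progression angle, symmetry index and reference
# profile construction.

#' The nine kinematic variables of the gait profile
#'
#' Canonical order used everywhere in the package: pelvic tilt, pelvic
#' obliquity, pelvic rotation, hip flexion, hip ab/adduction (adduction
#' positive, conventional gait-chart sign), hip rotation, knee flexion,
#' ankle dorsiflexion, foot progression angle.
#'
#' @return character vector of length 9.
#' @export
gait_variables <- function() {
  c("pelvic_tilt", "pelvic_obliquity", "pelvic_rotation",
    "hip_flexion", "hip_abduction", "hip_rotation",
    "knee_flexion", "ankle_dorsiflexion", "foot_progression")
}

#' Time-normalised waveforms for one gait cycle
#'
#' @param values `T x 9` numeric matrix (degrees), columns named and ordered
#'   as [gait_variables()], rows spanning 0-100% of the gait cycle.
#' @param side `"left"` or `"right"`.
#' @param cycle cycle index within the source trial.
#' @param meta metadata list (subject, session, trial, engine, ...).
#' @return an object of class `gait_cycle_waveforms`.
#' @export
gait_cycle_waveforms <- function(values, side, cycle = 1L, meta = list()) {
  assert_that(is.matrix(values) && nrow(values) >= 2,
              "values must be a matrix with T >= 2 rows")
  assert_that(identical(colnames(values), gait_variables()),
              "waveform columns must be exactly the nine canonical variables, in order")
  assert_that(all(is.finite(values)), "waveforms contain non-finite values")
  structure(list(values = values, side = check_side(side),
                 cycle = as.integer(cycle), meta = meta),
            class = "gait_cycle_waveforms")
}

#' @export
print.gait_cycle_waveforms <- function(x, ...) {
  cat("<gait_cycle_waveforms>", x$side, "side, cycle", x$cycle,
      ",", nrow(x$values), "time points\n")
  invisible(x)
}

#' Time-normalise a signal to a percent-gait-cycle grid
#'
#' Linearly interpolates the per-frame values onto `T` evenly spaced points
#' spanning the cycle from `cycle_start` to `cycle_end` inclusive (0-100% of
#' the gait cycle); the endpoints are the interpolated values at the event
#' times themselves.
#'
#' @param raw numeric per-frame values.
#' @param time numeric frame times (seconds), same length as `raw`.
#' @param cycle_start,cycle_end event times bounding the cycle (seconds).
#' @param T number of output points (default 101).
#' @return numeric vector of length `T`.
#' @export
time_normalise <- function(raw, time, cycle_start, cycle_end, T = 101) {
  assert_that(length(raw) == length(time), "raw and time lengths differ")
  assert_that(cycle_end > cycle_start, "cycle_end must exceed cycle_start")
  assert_that(cycle_start >= time[1] - 1e-9 &&
                cycle_end <= time[length(time)] + 1e-9,
              "cycle events lie outside the trial time range")
  inside <- sum(time >= cycle_start - 1e-9 & time <= cycle_end + 1e-9)
  assert_that(inside >= 2, "fewer than 2 samples inside the cycle")
  grid <- seq(cycle_start, cycle_end, length.out = T)
  stats::approx(time, raw, xout = grid, rule = 2)$y
}

#' Pointwise mean of waveform sets for one limb
#'
#' @param waveform_sets non-empty list of [gait_cycle_waveforms()] with
#'   identical grids (same T) for one limb.
#' @return a single `gait_cycle_waveforms` holding the pointwise mean.
#' @export
average_trials <- function(waveform_sets) {
  assert_that(is.list(waveform_sets) && length(waveform_sets) >= 1,
              "need at least one waveform set")
  T0 <- nrow(waveform_sets[[1]]$values)
  side <- waveform_sets[[1]]$side
  for (w in waveform_sets) {
    assert_that(inherits(w, "gait_cycle_waveforms"), "elements must be gait_cycle_waveforms")
    assert_that(nrow(w$values) == T0, "mismatched normalised-time grids")
    assert_that(identical(w$side, side), "cannot average waveforms across sides")
  }
  acc <- Reduce(`+`, lapply(waveform_sets, `[[`, "values")) / length(waveform_sets)
  gait_cycle_waveforms(acc, side = side, cycle = 1L,
                       meta = c(waveform_sets[[1]]$meta,
                                list(n_averaged = length(waveform_sets))))
}

#' Reference profile: mean waveforms of a non-pathological group
#'
#' @param values `T x 9` matrix of group-mean waveforms (degrees).
#' @param n_subjects number of limbs/subjects averaged.
#' @param age_group label of the age group.
#' @return object of class `reference_profile`.
#' @export
reference_profile <- function(values, n_subjects, age_group = "all") {
  assert_that(is.matrix(values) && identical(colnames(values), gait_variables()),
              "reference values must be a T x 9 matrix in canonical variable order")
  structure(list(values = values, n_subjects = n_subjects,
                 age_group = age_group), class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat("<reference_profile>", x$age_group, "group,", x$n_subjects,
      "limbs,", nrow(x$values), "time points\n")
  invisible(x)
}

#' Gait Variable Scores
#'
#' For each of the nine variables, the root-mean-square deviation over the
#' normalised gait cycle between the subject's waveform and the reference
#' mean waveform:
#' `GVS_i = sqrt( (1/T) * sum_t (x_{i,t} - x_ref_{i,t})^2 )` (degrees).
#'
#' @param waveforms a [gait_cycle_waveforms()] (typically a limb's mean
#'   waveform over trials).
#' @param reference a [reference_profile()] on the same grid.
#' @return named numeric vector of nine non-negative scores (degrees).
#' @export
gvs <- function(waveforms, reference) {
  assert_that(inherits(waveforms, "gait_cycle_waveforms"), "waveforms must be gait_cycle_waveforms")
  assert_that(inherits(reference, "reference_profile"), "reference must be a reference_profile")
  assert_that(nrow(waveforms$values) == nrow(reference$values),
              "waveform and reference grids differ")
  d <- waveforms$values - reference$values
  sqrt(colMeans(d^2))
}

#' Gait Profile Score
#'
#' Root-mean-square of the N Gait Variable Scores:
#' `GPS = sqrt( (1/N) * sum_i GVS_i^2 )` (degrees). A single index of
#' overall gait deviation from the reference population.
#'
#' @param gvs_vector numeric vector of N >= 1 non-negative GVS values.
#' @return scalar GPS in degrees.
#' @export
gps <- function(gvs_vector) {
  assert_that(is.numeric(gvs_vector) && length(gvs_vector) >= 1,
              "gvs_vector must be a non-empty numeric vector")
  assert_that(all(is.finite(gvs_vector)) && all(gvs_vector >= 0),
              "GVS values must be finite and non-negative")
  sqrt(sum(gvs_vector^2) / length(gvs_vector))
}

#' Foot progression angle over one gait cycle
#'
#' The direction of progression is the transverse-plane vector from the
#' pelvis centre position at initial heel strike to its position at the end
#' of the cycle; the foot vector is the line from the ankle joint centre to
#' the toe marker. The FPA is the signed transverse-plane angle between
#' them, time-normalised to `T` points. Sign convention: internal rotation
#' (in-toeing) positive for both sides.
#'
#' @param pelvis_centre_trajectory,ankle_jc_trajectory,toe_trajectory
#'   `F x 3` matrices covering the cycle (metres).
#' @param time frame times (seconds).
#' @param cycle_start,cycle_end heel-strike times bounding the cycle.
#' @param T output grid size.
#' @param side `"left"` or `"right"` (flips the sign so in-toeing is
#'   positive on both sides).
#' @return numeric length-`T` FPA in degrees.
#' @export
foot_progression_angle <- function(pelvis_centre_trajectory,
                                   ankle_jc_trajectory, toe_trajectory,
                                   time, cycle_start, cycle_end, T = 101,
                                   side = "right") {
  check_side(side)
  p0 <- vapply(1:2, function(j) stats::approx(time, pelvis_centre_trajectory[, j],
                                              cycle_start, rule = 2)$y, numeric(1))
  p1 <- vapply(1:2, function(j) stats::approx(time, pelvis_centre_trajectory[, j],
                                              cycle_end, rule = 2)$y, numeric(1))
  v <- p1 - p0  # transverse-plane progression vector
  assert_that(vnorm(v) > 1e-9,
              "degenerate input: no net pelvis displacement over the cycle")
  fvec <- toe_trajectory - ankle_jc_trajectory
  s <- if (side == "right") 1 else -1
  ang <- rad2deg(atan2(v[1] * fvec[, 2] - v[2] * fvec[, 1],
                       v[1] * fvec[, 1] + v[2] * fvec[, 2])) * s
  time_normalise(ang, time, cycle_start, cycle_end, T)
}

#' Symmetry Index of left/right scores
#'
#' Robinson's form: `SI = 100 * (left - right) / (0.5 * (left + right))`
#' percent. Zero means perfect symmetry; swapping limbs negates the result.
#'
#' @param gps_left,gps_right scalar limb scores (same session).
#' @return SI in percent.
#' @export
symmetry_index <- function(gps_left, gps_right) {
  assert_that(is_scalar_number(gps_left) && is_scalar_number(gps_right),
              "inputs must be scalar scores")
  m <- (gps_left + gps_right) / 2
  assert_that(m > 0, "symmetry index undefined: both scores are zero")
  100 * (gps_left - gps_right) / m
}

.age_group_label <- function(age, boundaries = c(10, 16)) {
  ifelse(age < boundaries[1], "children",
         ifelse(age < boundaries[2], "teenagers", "young_adults"))
}

#' Build age-group reference profiles from typically-developing waveforms
#'
#' Pools limb-level mean waveforms of the typically-developing cohort and
#' returns, per age group (children < 10 y, teenagers < 16 y, young adults
#' >= 16 y by default), the pointwise mean as a [reference_profile()].
#'
#' @param td_waveforms list of [gait_cycle_waveforms()] (one mean waveform
#'   per TD limb).
#' @param ages numeric vector of subject ages (years), one per waveform.
#' @param age_groups numeric boundaries `c(children_upper, teenagers_upper)`.
#' @return named list of `reference_profile`, one per age group.
#' @export
build_reference <- function(td_waveforms, ages, age_groups = c(10, 16)) {
  assert_that(length(td_waveforms) == length(ages),
              "need one age per waveform set")
  labels <- .age_group_label(ages, age_groups)
  out <- list()
  for (g in c("children", "teenagers", "young_adults")) {
    idx <- which(labels == g)
    assert_that(length(idx) > 0,
                "reference configuration error: age group `%s` is empty", g)
    acc <- Reduce(`+`, lapply(td_waveforms[idx], `[[`, "values")) / length(idx)
    out[[g]] <- reference_profile(acc, n_subjects = length(idx), age_group = g)
  }
  out
}
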