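# Synthetic marker-trajectory generation: a gait pattern drives the model's
# coordinates, forward kinematics produces rigid marker trajectories, and a
# soft-tissue artefact (STA) model displaces each skin marker.

#' Soft-tissue artefact model
#'
#' Each marker's displacement from its rigid (bone-fixed) position is the sum
#' of a gait-cycle-locked sinusoid (systematic artefact) and a smooth
#' Ornstein-Uhlenbeck random walk (random artefact). `amplitude` is the
#' target root-mean-square of the total 3-D displacement; the random
#' component is scaled so the combination realises it.
#'
#' The default thigh-wand amplitude (0.019 m) is the largest, reflecting the
#' roughly 1.9 cm tracking RMS error typical of thigh markers.
#'
#' @param amplitude default per-marker RMS displacement (metres).
#' @param marker_amplitudes named overrides per marker label.
#' @param correlation_time temporal correlation length of the random
#'   component (seconds).
#' @param harmonic_fraction gait-locked sinusoid amplitude as a fraction of
#'   `amplitude` (its RMS contribution is `amplitude*fraction/sqrt(2)`).
#' @param harmonic_seed optional integer: when set, the gait-locked
#'   component's direction and phase per marker are drawn deterministically
#'   from this seed instead of the trial's random stream. The systematic
#'   artefact of a subject is anatomy-driven and repeats across that
#'   subject's sessions, so cohort generation sets a per-subject seed here.
#' @return object of class `sta_model`.
#' @export
sta_model <- function(amplitude = 0.008,
                      marker_amplitudes = c(RTHI = 0.019, LTHI = 0.019,
                                            RTIB = 0.012, LTIB = 0.012),
                      correlation_time = 0.12, harmonic_fraction = 0.5,
                      harmonic_seed = NULL) {
  assert_that(amplitude >= 0 && all(marker_amplitudes >= 0),
              "STA amplitudes must be >= 0")
  assert_that(correlation_time > 0, "correlation_time must be > 0")
  assert_that(harmonic_fraction >= 0 && harmonic_fraction <= 1,
              "harmonic_fraction must lie in [0, 1]")
  structure(list(amplitude = amplitude, marker_amplitudes = marker_amplitudes,
                 correlation_time = correlation_time,
                 harmonic_fraction = harmonic_fraction,
                 harmonic_seed = harmonic_seed),
            class = "sta_model")
}

#' Zero soft-tissue artefact (rigid markers)
#' @return an [sta_model()] with all amplitudes 0.
#' @export
sta_none <- function() sta_model(amplitude = 0, marker_amplitudes = numeric())

sta_amplitude_for <- function(sta, label) {
  if (label %in% names(sta$marker_amplitudes)) sta$marker_amplitudes[[label]]
  else sta$amplitude
}

#' Simulate the artefact displacement series for one marker
#'
#' Exposed so the artefact component can be inspected and calibrated
#' directly (its realised RMS approximates the configured amplitude).
#'
#' @param sta an [sta_model()].
#' @param label marker label (selects the amplitude).
#' @param time frame times (seconds).
#' @param phase gait-cycle phase per frame (for the gait-locked component).
#' @return `F x 3` displacement matrix (metres).
#' @export
sta_displacement <- function(sta, label, time, phase) {
  amp <- sta_amplitude_for(sta, label)
  nf <- length(time)
  if (amp <= 0) return(matrix(0, nf, 3))
  h_amp <- sta$harmonic_fraction * amp
  # random-component per-axis stationary sd so that total RMS ~= amp
  var_rand <- max(amp^2 - h_amp^2 / 2, 0)
  sd_ax <- sqrt(var_rand / 3)
  dt <- diff(time)[1]
  rho <- exp(-dt / sta$correlation_time)
  innov_sd <- sd_ax * sqrt(1 - rho^2)
  disp <- matrix(0, nf, 3)
  for (j in 1:3) {
    x <- numeric(nf)
    x[1] <- stats::rnorm(1, 0, sd_ax)
    eps <- stats::rnorm(nf - 1, 0, innov_sd)
    for (f in 2:nf) x[f] <- rho * x[f - 1] + eps[f - 1]
    disp[, j] <- x
  }
  if (h_amp > 0) {
    if (!is.null(sta$harmonic_seed)) {
      # subject-stable systematic component: direction/phase drawn from a
      # dedicated stream keyed on subject seed + marker label, leaving the
      # trial's random stream untouched
      keep <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      set.seed(sta$harmonic_seed + sum(utf8ToInt(label)))
      u <- unitize(stats::rnorm(3))
      ph <- stats::runif(1, 0, 2 * pi)
      if (!is.null(keep)) assign(".Random.seed", keep, globalenv())
    } else {
      u <- unitize(stats::rnorm(3))
      ph <- stats::runif(1, 0, 2 * pi)
    }
    disp <- disp + outer(h_amp * sin(2 * pi * phase + ph), u)
  }
  disp
}

# Map pattern variables onto model coordinates for one frame set.
# phi_l / phi_r: per-frame phase of the left / right limb cycle.
.pattern_to_coordinates <- function(model, pattern, time, phi_l, phi_r,
                                    pelvis_height = 0) {
  free <- coordinate_names(model)
  q <- matrix(0, length(time), length(free), dimnames = list(NULL, free))
  speed <- pattern$stride_length / cycle_duration(pattern)
  q[, "pelvis_tx"] <- speed * time
  q[, "pelvis_tz"] <- pelvis_height
  pv <- function(v, phi) deg2rad(pattern_value(pattern, v, phi))
  # pelvis coordinates are laboratory-referenced; the left limb's cycle is
  # the reference phase
  q[, "pelvis_tilt"] <- pv("pelvic_tilt", phi_l)
  q[, "pelvis_obliquity"] <- -pv("pelvic_obliquity", phi_l)
  q[, "pelvis_rotation"] <- -pv("pelvic_rotation", phi_l)
  for (side in c("left", "right")) {
    sfx <- substr(side, 1, 1)
    phi <- if (side == "left") phi_l else phi_r
    q[, paste0("hip_flexion_", sfx)] <- pv("hip_flexion", phi)
    q[, paste0("hip_adduction_", sfx)] <- pv("hip_abduction", phi)
    # transverse-plane deviations (hip internal rotation and foot
    # progression) are both realised through the hip rotation coordinate:
    # the chain has no tibial-torsion degree of freedom
    fp_dev <- pattern$deviation_offsets$foot_progression
    q[, paste0("hip_rotation_", sfx)] <-
      pv("hip_rotation", phi) +
      deg2rad(fp_dev$constant + fp_dev$amp1 * sin(2 * pi * phi + fp_dev$phase1))
    q[, paste0("knee_flexion_", sfx)] <- pv("knee_flexion", phi)
    q[, paste0("ankle_flexion_", sfx)] <- pv("ankle_dorsiflexion", phi)
  }
  q
}

#' Generate a synthetic walking trial
#'
#' Converts a gait pattern into a coordinate trajectory (pelvis advancing
#' along the progression axis at the pattern's cadence and stride length,
#' right limb phase-shifted by half a cycle), runs forward kinematics, adds
#' per-marker soft-tissue artefact displacement, and emits heel-strike
#' events at the exact cycle boundaries.
#'
#' @param model a `skeletal_model`.
#' @param pattern a [gait_pattern()].
#' @param n_cycles number of complete gait cycles (>= 1).
#' @param sta an [sta_model()]; use [sta_none()] for rigid markers.
#' @param seed integer seed; the trial is bit-reproducible given the seed.
#' @param rate sampling rate in Hz.
#' @param meta metadata list stored on the trial.
#' @return a [marker_trial()].
#' @export
generate_trial <- function(model, pattern, n_cycles = 3, sta = sta_model(),
                           seed = 1L, rate = 100, meta = list()) {
  assert_that(inherits(pattern, "gait_pattern"), "pattern must be a gait_pattern")
  assert_that(n_cycles >= 1, "n_cycles must be >= 1")
  dur <- cycle_duration(pattern)
  time <- seq(0, by = 1 / rate,
              length.out = ceiling(n_cycles * dur * rate) + 1L)
  phi_l <- (time / dur) %% 1
  phi_r <- (time / dur + 0.5) %% 1
  q <- .pattern_to_coordinates(model, pattern, time, phi_l, phi_r)
  b <- coordinate_bounds(model)
  q <- sweep(sweep(q, 2, b[, "lower"], pmax), 2, b[, "upper"], pmin)
  fk <- .fk_trajectory(model, q)
  markers <- fk$markers
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  for (l in names(markers)) {
    markers[[l]] <- markers[[l]] + sta_displacement(sta, l, time, phi_l)
  }
  hs_l <- seq(0, n_cycles) * dur
  hs_r <- (seq(0, n_cycles - 1) + 0.5) * dur
  to_l <- (seq(0, n_cycles - 1) + 0.62) * dur
  to_r <- (seq(0, n_cycles - 1) + 0.12) * dur
  marker_trial(time, markers,
               events = list(left = list(heel_strike = hs_l, toe_off = to_l),
                             right = list(heel_strike = hs_r, toe_off = to_r)),
               meta = c(meta, list(seed = seed, n_cycles = n_cycles,
                                   cadence = pattern$cadence)),
               rate = rate)
}

#' Generate a quasi-static calibration trial
#'
#' The subject standing in the neutral pose for a short capture; used for
#' model scaling.
#'
#' @inheritParams generate_trial
#' @param duration seconds of standing.
#' @param sta artefact model (default none: a calm standing pose).
#' @return a [marker_trial()].
#' @export
generate_static_trial <- function(model, duration = 0.5, sta = sta_none(),
                                  seed = 1L, rate = 100, meta = list()) {
  time <- seq(0, duration, by = 1 / rate)
  q <- matrix(0, length(time), n_coordinates(model),
              dimnames = list(NULL, coordinate_names(model)))
  fk <- .fk_trajectory(model, q)
  markers <- fk$markers
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  for (l in names(markers)) {
    markers[[l]] <- markers[[l]] + sta_displacement(sta, l, time, rep(0, length(time)))
  }
  marker_trial(time, markers, events = list(),
               meta = c(meta, list(static = TRUE, seed = seed)), rate = rate)
}
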