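# Gait pattern templates: the nine kinematic waveforms as truncated Fourier
# series over the gait cycle. Built-in normative curves are stylised
# constants chosen for physiological plausibility (amplitudes and timing of
# typical paediatric walking), not digitised from any published figure; they
# are documented in the methods vignette.

# Fourier coefficients per variable: value(phi) = c0 + sum_k a_k cos(2 pi k
# phi) + b_k sin(2 pi k phi), phi in [0, 1), angles in degrees.
.normative_fourier <- function() {
  list(
    pelvic_tilt        = list(c0 = 10, a = c(0, 1.5, 0), b = c(0, 0, 0)),
    pelvic_obliquity   = list(c0 = 0,  a = c(0, 0, 0),   b = c(4, 0, 0)),
    pelvic_rotation    = list(c0 = 0,  a = c(0, 0, 0),   b = c(6, 0, 0)),
    hip_flexion        = list(c0 = 13, a = c(25, 0, 0), b = c(-8, 0, 0)),
    hip_abduction      = list(c0 = 0,  a = c(3, -2, 0),  b = c(-2, 0, 0)),
    hip_rotation       = list(c0 = 2,  a = c(-2, 0, 0),  b = c(3, 0, 0)),
    knee_flexion       = list(c0 = 25, a = c(-5, -12, 3), b = c(-18, 3, 4)),
    ankle_dorsiflexion = list(c0 = 2,  a = c(-3, -5, 0), b = c(6, -3, 0)),
    foot_progression   = list(c0 = -8, a = c(0, 0, 0),   b = c(2, 0, 0))
  )
}

.eval_fourier <- function(cf, phi) {
  out <- rep(cf$c0, length(phi))
  for (k in seq_along(cf$a)) {
    out <- out + cf$a[k] * cos(2 * pi * k * phi) + cf$b[k] * sin(2 * pi * k * phi)
  }
  out
}

#' Gait pattern: waveform templates plus deviation offsets
#'
#' A gait pattern holds, for each of the nine kinematic variables, a
#' periodic template (degrees as a function of percent gait cycle) plus a
#' per-variable deviation: a constant offset and a first-harmonic
#' perturbation. Deviations model a subject's departure from the normative
#' curve (e.g. elevated hip internal rotation in cerebral palsy).
#'
#' @param deviation_offsets named list; for each variable either a single
#'   constant (degrees) or a list with `constant`, `amp1` (first-harmonic
#'   amplitude, degrees) and `phase1` (radians). Variables not mentioned
#'   deviate by 0.
#' @param cadence steps per minute (two steps per gait cycle).
#' @param stride_length metres advanced per gait cycle.
#' @param fourier template coefficients (advanced use); defaults to the
#'   built-in normative set.
#' @return object of class `gait_pattern`.
#' @export
gait_pattern <- function(deviation_offsets = list(), cadence = 110,
                         stride_length = 1.1, fourier = .normative_fourier()) {
  assert_that(setequal(names(fourier), gait_variables()),
              "templates must cover exactly the nine canonical variables")
  assert_that(is_scalar_number(cadence) && cadence > 0, "cadence must be > 0")
  assert_that(is_scalar_number(stride_length) && stride_length > 0,
              "stride_length must be > 0")
  dev <- stats::setNames(vector("list", 9), gait_variables())
  for (v in gait_variables()) {
    d <- deviation_offsets[[v]]
    if (is.null(d)) d <- list(constant = 0, amp1 = 0, phase1 = 0)
    if (is.numeric(d) && length(d) == 1) d <- list(constant = d, amp1 = 0, phase1 = 0)
    d$constant <- d$constant %||% 0
    d$amp1 <- d$amp1 %||% 0
    d$phase1 <- d$phase1 %||% 0
    dev[[v]] <- d
  }
  extra <- setdiff(names(deviation_offsets), gait_variables())
  assert_that(length(extra) == 0, "unknown deviation variable(s): %s",
              paste(extra, collapse = ", "))
  structure(list(fourier = fourier, deviation_offsets = dev,
                 cadence = cadence, stride_length = stride_length),
            class = "gait_pattern")
}

#' Evaluate a pattern's waveform (template + deviations)
#'
#' @param pattern a [gait_pattern()].
#' @param variable one of [gait_variables()].
#' @param phi gait-cycle phase in [0, 1] (0 = heel strike).
#' @return numeric vector of angles (degrees).
#' @export
pattern_value <- function(pattern, variable, phi) {
  assert_that(variable %in% gait_variables(), "unknown variable `%s`", variable)
  d <- pattern$deviation_offsets[[variable]]
  .eval_fourier(pattern$fourier[[variable]], phi) +
    d$constant + d$amp1 * sin(2 * pi * phi + d$phase1)
}

#' @export
print.gait_pattern <- function(x, ...) {
  cat("<gait_pattern> cadence", x$cadence, "steps/min, stride",
      x$stride_length, "m\n")
  devs <- vapply(gait_variables(), function(v) {
    d <- x$deviation_offsets[[v]]
    d$constant != 0 || d$amp1 != 0
  }, logical(1))
  if (any(devs)) cat("  deviations on:", paste(gait_variables()[devs],
                                               collapse = ", "), "\n")
  invisible(x)
}

# Seconds per full gait cycle (two steps).
cycle_duration <- function(pattern) 120 / pattern$cadence
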