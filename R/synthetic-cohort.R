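# Synthetic cohort generation: a typically-developing (TD) reference cohort
# in three age subgroups and a cerebral-palsy (CP) cohort with paired
# pre/post-surgery sessions, programmable transverse-plane deviations,
# programmable surgical corrections, and ground-truth + simulated clinical
# responder labels.

#' Cohort specification
#'
#' @param n_td integer length-3: TD subjects per age subgroup (children
#'   < 10 y, teenagers < 16 y, young adults >= 16 y).
#' @param n_cp number of CP subjects (each contributes paired pre/post
#'   sessions; surgery is bilateral, so each subject contributes two
#'   operated limbs).
#' @param responder_fraction fraction of operated limbs programmed as true
#'   responders (0..1).
#' @param responder_correction_fraction fraction of a responding limb's
#'   pathological transverse-plane deviation removed by the surgery (a
#'   derotation osteotomy corrects the measured deviation, so the programmed
#'   correction scales with it; 0.9 by default).
#' @param surgical_effect named list of additional per-variable constant
#'   corrections (degrees) added to a responding limb's deviations after
#'   surgery, on top of the proportional correction (default none).
#' @param non_responder_effect same, for non-responding limbs (default
#'   none: their pathological deviation persists).
#' @param clinical_disagreement probability that a limb's simulated clinical
#'   label disagrees with the ground truth (independent per limb).
#' @param td_offset_sd named numeric: SD (degrees) of the zero-mean constant
#'   deviation offsets drawn for TD limbs.
#' @param cp_hip_rotation_mean,cp_hip_rotation_sd distribution (degrees) of
#'   the elevated hip internal-rotation deviation of CP limbs pre-surgery.
#' @param cp_fpa_mean,cp_fpa_sd distribution (degrees) of the in-toeing
#'   foot-progression deviation of CP limbs pre-surgery.
#' @param n_trials walking trials per session.
#' @param n_cycles gait cycles per trial.
#' @param rate sampling rate (Hz).
#' @param sta an [sta_model()].
#' @param seed integer master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_td = c(children = 12, teenagers = 10, young_adults = 12),
                        n_cp = 13,
                        responder_fraction = 0.6,
                        responder_correction_fraction = 0.9,
                        surgical_effect = list(),
                        non_responder_effect = list(),
                        clinical_disagreement = 0.3,
                        td_offset_sd = c(pelvic_tilt = 2, pelvic_obliquity = 1,
                                         pelvic_rotation = 2, hip_flexion = 4,
                                         hip_abduction = 2, hip_rotation = 5,
                                         knee_flexion = 3, ankle_dorsiflexion = 2,
                                         foot_progression = 3),
                        cp_hip_rotation_mean = 18, cp_hip_rotation_sd = 6,
                        cp_fpa_mean = 10, cp_fpa_sd = 4,
                        n_trials = 3, n_cycles = 2, rate = 100,
                        sta = sta_model(), seed = 20260921L) {
  assert_that(length(n_td) == 3 && all(n_td >= 0), "n_td must have 3 subgroup counts")
  assert_that(responder_fraction >= 0 && responder_fraction <= 1,
              "responder_fraction must lie in [0, 1]")
  assert_that(clinical_disagreement >= 0 && clinical_disagreement <= 1,
              "clinical_disagreement must lie in [0, 1]")
  # the right limb strikes half a cycle in, so a complete right cycle needs
  # at least two generated cycles
  assert_that(n_cycles >= 2, "cohort trials need n_cycles >= 2")
  assert_that(responder_correction_fraction >= 0 &&
                responder_correction_fraction <= 1,
              "responder_correction_fraction must lie in [0, 1]")
  names(n_td) <- c("children", "teenagers", "young_adults")
  structure(list(n_td = n_td, n_cp = n_cp,
                 responder_fraction = responder_fraction,
                 responder_correction_fraction = responder_correction_fraction,
                 surgical_effect = surgical_effect,
                 non_responder_effect = non_responder_effect,
                 clinical_disagreement = clinical_disagreement,
                 td_offset_sd = td_offset_sd,
                 cp_hip_rotation_mean = cp_hip_rotation_mean,
                 cp_hip_rotation_sd = cp_hip_rotation_sd,
                 cp_fpa_mean = cp_fpa_mean, cp_fpa_sd = cp_fpa_sd,
                 n_trials = n_trials, n_cycles = n_cycles, rate = rate,
                 sta = sta, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Simple paediatric anthropometry as a function of age (documented stylised
# growth curves; metres / kg).
.anthro_from_age <- function(age) {
  height <- min(0.75 + 0.045 * age, 1.78)
  leg <- 0.48 * height
  generic_anthropometry(height = height, leg_length = leg,
                        ASIS_breadth = 0.155 * height,
                        knee_width = 0.0645 * height,
                        ankle_width = 0.045 * height,
                        mass = 17 * height^2, age = age)
}

.draw_td_offsets <- function(sd_map) {
  out <- list()
  for (v in gait_variables()) {
    s <- sd_map[[v]] %||% 0
    out[[v]] <- list(constant = stats::rnorm(1, 0, s),
                     amp1 = abs(stats::rnorm(1, 0, s / 2)),
                     phase1 = stats::runif(1, 0, 2 * pi))
  }
  out
}

.apply_effect <- function(offsets, effect) {
  for (v in names(effect)) {
    offsets[[v]]$constant <- offsets[[v]]$constant + effect[[v]]
  }
  offsets
}

#' Generate a synthetic gait-laboratory cohort
#'
#' Produces, per subject: a static calibration trial and `n_trials` walking
#' trials per session (TD: one session; CP: `pre` and `post`). TD limbs draw
#' zero-mean deviation offsets; CP limbs additionally draw elevated hip
#' internal-rotation and in-toeing foot-progression deviations pre-surgery.
#' Responding limbs receive `surgical_effect` post-surgery, non-responding
#' limbs `non_responder_effect`; subject-level deviations are otherwise held
#' fixed across sessions. Ground-truth responder labels and simulated
#' clinical labels (ground truth flipped with probability
#' `clinical_disagreement`) are emitted per operated limb.
#'
#' Knee-alignment-device (KAD) axis angles are drawn per limb (TD near zero;
#' CP elevated, unchanged by surgery) and applied to each subject's model.
#'
#' @param spec a [cohort_spec()].
#' @param model optional template `skeletal_model`; per-subject models are
#'   rebuilt from each subject's anthropometry, so this argument only
#'   supplies the marker set / locking configuration.
#' @return a list of class `cohort` with elements `subjects` (per subject:
#'   `model`, `anthropometry`, `static`, `sessions` of trials, `kad_deg`),
#'   `metadata` (one row per subject) and `limbs` (one row per limb with
#'   deviations, ground-truth and clinical labels).
#' @export
generate_cohort <- function(spec, model = NULL) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  set.seed(spec$seed)
  subjects <- list()
  meta_rows <- list()
  limb_rows <- list()
  subtalar_locked <- if (is.null(model)) FALSE else
    all(model_coordinates(model)$locked[grepl("^subtalar", model_coordinates(model)$name)])

  age_ranges <- list(children = c(5, 9.5), teenagers = c(10, 15.5),
                     young_adults = c(16, 25))
  sid <- 0L
  for (grp in names(spec$n_td)) {
    for (i in seq_len(spec$n_td[[grp]])) {
      sid <- sid + 1L
      id <- sprintf("TD%02d", sid)
      age <- stats::runif(1, age_ranges[[grp]][1], age_ranges[[grp]][2])
      subjects[[id]] <- .make_subject(id, "TD", age, spec, subtalar_locked,
                                      sessions = "control")
      meta_rows[[id]] <- data.frame(subject = id, group = "TD",
                                    age_group = grp, age = age,
                                    stringsAsFactors = FALSE)
      for (side in c("left", "right")) {
        limb_rows[[paste(id, side)]] <- data.frame(
          subject = id, side = side, group = "TD", operated = FALSE,
          responder_true = NA, clinical_label = NA_character_,
          kad_deg = subjects[[id]]$kad_deg[[side]],
          stringsAsFactors = FALSE)
      }
    }
  }
  for (i in seq_len(spec$n_cp)) {
    sid <- sid + 1L
    id <- sprintf("CP%02d", i)
    age <- stats::runif(1, 6, 13)
    subjects[[id]] <- .make_subject(id, "CP", age, spec, subtalar_locked,
                                    sessions = c("pre", "post"))
    meta_rows[[id]] <- data.frame(subject = id, group = "CP",
                                  age_group = .age_group_label(age), age = age,
                                  stringsAsFactors = FALSE)
    for (side in c("left", "right")) {
      s <- subjects[[id]]$limbs[[side]]
      limb_rows[[paste(id, side)]] <- data.frame(
        subject = id, side = side, group = "CP", operated = TRUE,
        responder_true = s$responder, clinical_label = s$clinical_label,
        kad_deg = subjects[[id]]$kad_deg[[side]],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(subjects = subjects,
                 metadata = do.call(rbind, c(meta_rows, list(make.row.names = FALSE))),
                 limbs = do.call(rbind, c(limb_rows, list(make.row.names = FALSE))),
                 spec = spec),
            class = "cohort")
}

# Build one subject: model (with KAD correction), deviations, labels, trials.
.make_subject <- function(id, group, age, spec, subtalar_locked, sessions) {
  anthro <- .anthro_from_age(age)
  model <- build_generic_model(anthropometry = anthro,
                               subtalar_locked = subtalar_locked)
  is_cp <- group == "CP"
  kad <- list()
  limbs <- list()
  side_offsets <- list()
  for (side in c("left", "right")) {
    off <- .draw_td_offsets(spec$td_offset_sd)
    kad[[side]] <- if (is_cp) stats::rnorm(1, 12, 6) else stats::rnorm(1, 0, 3)
    responder <- NA
    clinical <- NA_character_
    cp_dev <- list(hip_rotation = 0, foot_progression = 0)
    if (is_cp) {
      # surgical candidates carry a substantial transverse-plane deviation;
      # draws are floored accordingly
      cp_dev$hip_rotation <- max(
        stats::rnorm(1, spec$cp_hip_rotation_mean, spec$cp_hip_rotation_sd), 8)
      cp_dev$foot_progression <- max(
        stats::rnorm(1, spec$cp_fpa_mean, spec$cp_fpa_sd), 4)
      off$hip_rotation$constant <- off$hip_rotation$constant + cp_dev$hip_rotation
      off$foot_progression$constant <- off$foot_progression$constant +
        cp_dev$foot_progression
      responder <- stats::runif(1) < spec$responder_fraction
      truth_lab <- if (responder) "responder" else "non-responder"
      flip <- stats::runif(1) < spec$clinical_disagreement
      clinical <- if (flip) {
        if (responder) "non-responder" else "responder"
      } else truth_lab
    }
    limbs[[side]] <- list(offsets = off, cp_dev = cp_dev,
                          responder = responder, clinical_label = clinical)
    side_offsets[[side]] <- off
  }
  model <- apply_knee_axis_correction(model, "left", clamp(kad$left, -45, 45))
  model <- apply_knee_axis_correction(model, "right", clamp(kad$right, -45, 45))

  cadence <- stats::rnorm(1, 112, 6)
  stride <- clamp(1.25 * anthro$leg_length, 0.6, 1.5)
  sta_subj <- spec$sta
  sta_subj$harmonic_seed <- as.integer(stats::runif(1, 1, 2^30))

  static <- generate_static_trial(model, seed = stats::runif(1, 1, 2^30),
                                  rate = spec$rate,
                                  meta = list(subject = id))
  session_trials <- list()
  for (sess in sessions) {
    trials <- list()
    for (tr in seq_len(spec$n_trials)) {
      # per-limb offsets differ; the generator drives each side from its own
      # pattern by building a two-sided coordinate map below
      offs <- side_offsets
      if (is_cp && sess == "post") {
        for (side in c("left", "right")) {
          if (limbs[[side]]$responder) {
            # proportional derotation of the pathological deviation,
            # plus any configured constant effect
            f <- spec$responder_correction_fraction
            corr <- lapply(limbs[[side]]$cp_dev, function(d) -f * d)
            offs[[side]] <- .apply_effect(offs[[side]], corr)
            offs[[side]] <- .apply_effect(offs[[side]], spec$surgical_effect)
          } else {
            offs[[side]] <- .apply_effect(offs[[side]], spec$non_responder_effect)
          }
        }
      }
      trials[[tr]] <- .generate_two_sided_trial(
        model, offs, cadence, stride, spec, sta = sta_subj,
        seed = as.integer(stats::runif(1, 1, 2^30)),
        meta = list(subject = id, session = sess, trial = tr, group = group))
    }
    session_trials[[sess]] <- trials
  }
  list(id = id, group = group, age = age, anthropometry = anthro,
       model = model, kad_deg = kad, limbs = limbs,
       static = static, sessions = session_trials,
       cadence = cadence, stride = stride)
}

# A walking trial whose left and right limbs follow different deviation
# offsets (per-limb pathology); shared pelvis template.
.generate_two_sided_trial <- function(model, side_offsets, cadence, stride,
                                      spec, seed, meta, sta = spec$sta) {
  pat_l <- gait_pattern(side_offsets$left, cadence = cadence,
                        stride_length = stride)
  pat_r <- gait_pattern(side_offsets$right, cadence = cadence,
                        stride_length = stride)
  dur <- cycle_duration(pat_l)
  time <- seq(0, by = 1 / spec$rate,
              length.out = ceiling(spec$n_cycles * dur * spec$rate) + 1L)
  phi_l <- (time / dur) %% 1
  phi_r <- (time / dur + 0.5) %% 1
  q <- .pattern_to_coordinates(model, pat_l, time, phi_l, phi_r)
  qr <- .pattern_to_coordinates(model, pat_r, time, phi_l, phi_r)
  rcols <- grepl("_r$", colnames(q))
  q[, rcols] <- qr[, rcols]
  b <- coordinate_bounds(model)
  q <- sweep(sweep(q, 2, b[, "lower"], pmax), 2, b[, "upper"], pmin)
  fk <- .fk_trajectory(model, q)
  markers <- fk$markers
  set.seed(seed)
  for (l in names(markers)) {
    markers[[l]] <- markers[[l]] + sta_displacement(sta, l, time, phi_l)
  }
  hs_l <- seq(0, spec$n_cycles) * dur
  hs_r <- (seq(0, spec$n_cycles - 1) + 0.5) * dur
  marker_trial(time, markers,
               events = list(left = list(heel_strike = hs_l),
                             right = list(heel_strike = hs_r)),
               meta = c(meta, list(seed = seed)), rate = spec$rate)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", sum(x$metadata$group == "TD"), "TD +",
      sum(x$metadata$group == "CP"), "CP subjects\n")
  invisible(x)
}
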