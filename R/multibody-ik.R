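# Global-optimisation (multibody) inverse kinematics: per-frame weighted
# least-squares fit of the constrained model's coordinates to the measured
# markers, solved by a damped Gauss-Newton iteration with finite-difference
# marker Jacobians.

#' Inverse-kinematics configuration
#'
#' @param marker_weights named numeric vector of non-negative weights; any
#'   marker not listed takes `default_weight`. By default wand markers
#'   (`*THI`, `*TIB`) are down-weighted to 0.5 because they carry the largest
#'   soft-tissue artefact.
#' @param tolerance convergence threshold on the coordinate update norm
#'   (radians / metres).
#' @param max_iterations maximum Gauss-Newton iterations per frame.
#' @param warm_start start each frame from the previous frame's solution.
#' @param bounds_enforced project iterates onto the coordinate bounds.
#' @param default_weight weight for markers absent from `marker_weights`.
#' @return object of class `ik_config`.
#' @export
ik_config <- function(marker_weights = c(RTHI = 0.5, LTHI = 0.5,
                                         RTIB = 0.5, LTIB = 0.5),
                      tolerance = 1e-6, max_iterations = 100,
                      warm_start = TRUE, bounds_enforced = TRUE,
                      default_weight = 1) {
  assert_that(is_scalar_number(tolerance) && tolerance > 0, "tolerance must be > 0")
  assert_that(max_iterations >= 1, "max_iterations must be >= 1")
  assert_that(all(marker_weights >= 0), "marker weights must be non-negative")
  structure(list(marker_weights = marker_weights, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 warm_start = isTRUE(warm_start),
                 bounds_enforced = isTRUE(bounds_enforced),
                 default_weight = default_weight),
            class = "ik_config")
}

.ik_weights <- function(labels, cfg) {
  w <- rep(cfg$default_weight, length(labels))
  names(w) <- labels
  hit <- intersect(labels, names(cfg$marker_weights))
  w[hit] <- cfg$marker_weights[hit]
  w
}

# Neutral-pose cold start: zero joint angles, pelvis translation initialised
# from the observed ASIS midpoint so the optimiser starts near the data.
.cold_start_ci <- function(ci, observed) {
  q0 <- stats::setNames(rep(0, length(ci$names)), ci$names)
  if (all(c("LASI", "RASI") %in% rownames(observed))) {
    mid_obs <- (observed["LASI", ] + observed["RASI", ]) / 2
    q0[c("pelvis_tx", "pelvis_ty", "pelvis_tz")] <- mid_obs
  }
  q0
}

#' Solve one frame of marker-based inverse kinematics
#'
#' Finds a local minimiser of the weighted least-squares objective
#' `sum_m w_m * || observed_m - forward_kinematics(q)_m ||^2`
#' by damped Gauss-Newton iteration; stops when the coordinate update norm
#' drops below `cfg$tolerance` or `cfg$max_iterations` is reached (flagged).
#'
#' @param model a (scaled) `skeletal_model`.
#' @param observed matrix of observed marker positions with rownames =
#'   labels (metres); a named list of 3-vectors is also accepted.
#' @param q0 starting coordinate vector; `NULL` for the documented
#'   neutral-pose cold start.
#' @param cfg an [ik_config()].
#' @return list with `q` (named coordinate vector), `residuals` (named
#'   per-marker distances, metres), `objective`, `iterations`, `converged`.
#' @export
solve_frame <- function(model, observed, q0 = NULL, cfg = ik_config()) {
  if (is.list(observed) && !is.matrix(observed)) {
    observed <- do.call(rbind, observed)
  }
  labels <- intersect(model_marker_labels(model), rownames(observed))
  assert_that(length(labels) >= 3,
              "under-determined frame: fewer than 3 model markers observed")
  obs <- observed[labels, , drop = FALSE]
  assert_that(all(is.finite(obs)), "observed markers contain missing values")
  span <- svd(sweep(obs, 2, colMeans(obs)))$d
  assert_that(span[2] > 1e-8,
              "under-determined frame: observed markers are collinear")
  ci <- .free_coord_info(model)
  .solve_frame_core(model, obs, labels, .ik_weights(labels, cfg), q0, cfg,
                    ci, .segment_ancestral_dofs(model))
}

# The damped Gauss-Newton iteration, with all per-trial invariants
# (coordinate info, ancestry, weights) supplied by the caller.
.solve_frame_core <- function(model, obs, labels, w, q0, cfg, ci, ancestry) {
  free <- ci$names
  nq <- length(free)
  if (is.null(q0)) {
    q <- .cold_start_ci(ci, obs)
  } else {
    assert_that(length(q0) == nq, "q0 has the wrong length")
    q <- stats::setNames(as.numeric(q0), free)
  }
  if (cfg$bounds_enforced) q <- clamp(q, ci$lower, ci$upper)

  objective <- function(e) sum(w * rowSums(e^2))

  fk <- .fk_core(model, q, marker_labels = labels, dof_info = TRUE)
  p <- fk$markers[labels, , drop = FALSE]
  # which markers each dof moves, and their rows in the stacked Jacobian
  dof_mk <- lapply(free, function(dn) {
    which(vapply(labels, function(l)
      dn %in% ancestry[[fk$marker_segment[[l]]]], logical(1)))
  })
  dof_rows <- lapply(dof_mk, function(mi)
    as.vector(rbind(3 * (mi - 1) + 1, 3 * (mi - 1) + 2, 3 * mi)))
  e <- obs - p
  obj <- objective(e)
  lambda <- 1e-8  # near-pure Gauss-Newton; inflated only on step rejection
  it <- 0L
  converged <- FALSE
  while (it < cfg$max_iterations) {
    it <- it + 1L
    # analytic chain Jacobian: w x (x_m - p_joint) per rotational dof,
    # the global axis direction per translational dof
    J <- matrix(0, 3 * length(labels), nq)
    for (k in seq_len(nq)) {
      mi <- dof_mk[[k]]
      if (!length(mi)) next
      di <- fk$dof_info[[free[k]]]
      w3 <- di$w
      if (di$type == "translation") {
        J[dof_rows[[k]], k] <- rep(w3, times = length(mi))
      } else {
        d1 <- p[mi, 1] - di$p[1]
        d2 <- p[mi, 2] - di$p[2]
        d3 <- p[mi, 3] - di$p[3]
        J[dof_rows[[k]], k] <- as.vector(rbind(w3[2] * d3 - w3[3] * d2,
                                               w3[3] * d1 - w3[1] * d3,
                                               w3[1] * d2 - w3[2] * d1))
      }
    }
    ev <- as.numeric(t(e))
    wl <- rep(w, each = 3)
    g <- crossprod(J, wl * ev)
    H <- crossprod(J, wl * J)
    accepted <- FALSE
    for (try in 1:8) {
      delta <- tryCatch(solve(H + lambda * diag(nq), g),
                        error = function(err) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      qn <- q + as.numeric(delta)
      if (cfg$bounds_enforced) qn <- clamp(qn, ci$lower, ci$upper)
      fkn <- .fk_core(model, qn, marker_labels = labels, dof_info = TRUE)
      pn <- fkn$markers[labels, , drop = FALSE]
      en <- obs - pn
      on <- objective(en)
      if (on <= obj + 1e-15) {
        step <- max(abs(qn - q))
        q <- qn; p <- pn; e <- en; obj <- on; fk <- fkn
        lambda <- max(lambda / 3, 1e-10)
        accepted <- TRUE
        if (step < cfg$tolerance) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!accepted || converged) {
      if (!accepted) converged <- TRUE  # no descent direction left: at a minimum
      break
    }
  }
  res <- sqrt(rowSums(e^2))
  names(res) <- labels
  list(q = q, residuals = res, objective = obj,
       iterations = it, converged = converged)
}

#' Solve inverse kinematics over a whole trial
#'
#' Frame-sequential solve, warm-starting each frame from the previous
#' solution when enabled. Errors (rather than silently skipping) if any
#' frame fails to produce a solution.
#'
#' @param model a subject-scaled `skeletal_model`.
#' @param trial a [marker_trial()].
#' @param cfg an [ik_config()].
#' @return object of class `ik_result`: `q_trajectory` (frames x
#'   coordinates, named columns), `residuals` (frames x markers, metres),
#'   `marker_rms` (per-marker trial RMS error, metres), `converged` flags,
#'   `time`.
#' @export
solve_trial <- function(model, trial, cfg = ik_config()) {
  labels <- intersect(model_marker_labels(model), names(trial$markers))
  assert_that(length(labels) >= 3, "trial shares fewer than 3 markers with the model")
  .require_markers(trial, labels)
  nf <- n_frames(trial)
  ci <- .free_coord_info(model)
  ancestry <- .segment_ancestral_dofs(model)
  w <- .ik_weights(labels, cfg)
  free <- ci$names
  qt <- matrix(NA_real_, nf, length(free), dimnames = list(NULL, free))
  resid <- matrix(NA_real_, nf, length(labels), dimnames = list(NULL, labels))
  conv <- logical(nf)
  q_prev <- NULL
  for (f in seq_len(nf)) {
    obs <- trial_frame(trial, f, labels)
    sol <- tryCatch(
      .solve_frame_core(model, obs, labels, w,
                        q0 = if (cfg$warm_start) q_prev else NULL,
                        cfg = cfg, ci = ci, ancestry = ancestry),
      error = function(err) stopf("inverse kinematics failed at frame %d: %s",
                                  f, conditionMessage(err)))
    qt[f, ] <- sol$q
    resid[f, labels] <- sol$residuals[labels]
    conv[f] <- sol$converged
    q_prev <- sol$q
  }
  structure(list(q_trajectory = qt, residuals = resid,
                 marker_rms = sqrt(colMeans(resid^2)),
                 converged = conv, time = trial$time,
                 events = trial$events, meta = trial$meta),
            class = "ik_result")
}

#' @export
print.ik_result <- function(x, ...) {
  cat("<ik_result>", nrow(x$q_trajectory), "frames,",
      ncol(x$q_trajectory), "coordinates\n")
  cat("  worst marker RMS error:",
      sprintf("%.1f mm (%s)", 1000 * max(x$marker_rms),
              names(which.max(x$marker_rms))), "\n")
  invisible(x)
}

#' Marker error quality-control table
#'
#' Per-marker trial RMS error with a pass flag against an acceptability
#' limit (reported for QC only, never enforced).
#'
#' @param ik_result an [solve_trial()] result.
#' @param limit acceptable RMS error in metres (default 0.02, the
#'   conventional rule of thumb for tracking error).
#' @return data frame with `marker`, `rms_m`, `within_limit`.
#' @export
marker_error_qc <- function(ik_result, limit = 0.02) {
  data.frame(marker = names(ik_result$marker_rms),
             rms_m = as.numeric(ik_result$marker_rms),
             within_limit = as.numeric(ik_result$marker_rms) <= limit,
             row.names = NULL)
}

#' Body kinematics of a coordinate trajectory
#'
#' Runs forward kinematics over a solved trajectory and returns the segment
#' frames, joint-centre trajectories and pelvis-origin trajectory needed for
#' waveform extraction and the foot progression angle, in the same
#' `segment_frames` structure produced by [build_pig_frames()].
#'
#' @param model the `skeletal_model` used for the solve.
#' @param q_trajectory frames x coordinates matrix (as in an `ik_result`).
#' @param time frame times (seconds).
#' @return a `segment_frames` object.
#' @export
body_kinematics <- function(model, q_trajectory, time = NULL) {
  if (inherits(q_trajectory, "ik_result")) {
    time <- time %||% q_trajectory$time
    q_trajectory <- q_trajectory$q_trajectory
  }
  assert_that(is.matrix(q_trajectory) &&
                ncol(q_trajectory) == n_coordinates(model),
              "q_trajectory has the wrong number of coordinates")
  time <- time %||% seq_len(nrow(q_trajectory))
  fk <- .fk_trajectory(model, q_trajectory)
  R <- list(pelvis = fk$R$pelvis)
  O <- list(pelvis = fk$origin$pelvis)
  jc <- list(); pts <- list()
  for (side in c("left", "right")) {
    sfx <- substr(side, 1, 1)
    P <- if (side == "right") "R" else "L"
    R[[paste0("femur_", sfx)]] <- fk$R[[paste0("femur_", sfx)]]
    R[[paste0("tibia_", sfx)]] <- fk$R[[paste0("tibia_", sfx)]]
    R[[paste0("foot_", sfx)]] <- fk$R[[paste0("foot_", sfx)]]
    O[[paste0("femur_", sfx)]] <- fk$origin[[paste0("femur_", sfx)]]
    O[[paste0("tibia_", sfx)]] <- fk$origin[[paste0("tibia_", sfx)]]
    O[[paste0("foot_", sfx)]] <- fk$origin[[paste0("foot_", sfx)]]
    jc[[paste0("hip_", sfx)]] <- fk$origin[[paste0("femur_", sfx)]]
    jc[[paste0("knee_", sfx)]] <- fk$origin[[paste0("tibia_", sfx)]]
    jc[[paste0("ankle_", sfx)]] <- fk$origin[[paste0("talus_", sfx)]]
    pts[[paste0("TOE_", sfx)]] <- fk$markers[[paste0(P, "TOE")]]
    pts[[paste0("HEE_", sfx)]] <- fk$markers[[paste0(P, "HEE")]]
  }
  structure(list(time = time, R = R, origin = O, jc = jc,
                 pelvis_origin = fk$origin$pelvis, points = pts,
                 source = "multibody"),
            class = "segment_frames")
}

#' Multibody-IK waveforms for a trial
#'
#' Convenience wrapper: solves the trial, computes body kinematics and
#' extracts per-cycle time-normalised waveforms.
#'
#' @inheritParams solve_trial
#' @inheritParams extract_waveforms
#' @return list of `gait_cycle_waveforms`.
#' @export
extract_waveforms_ik <- function(model, trial, cfg = ik_config(),
                                 sides = c("left", "right"), T = 101) {
  ik <- solve_trial(model, trial, cfg)
  frames <- body_kinematics(model, ik)
  extract_waveforms(frames, trial$events, sides = sides, T = T,
                    meta = c(trial$meta, list(engine = "ik")))
}
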