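# Shared fixture builders. Everything is generated in code; nothing is read
# from disk.

fixture_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_generic_model()
    cache
  }
})

fixture_anthro <- function() generic_anthropometry()

# A clean (zero-artefact) walking trial plus its generating coordinate
# trajectory, cached because several files compare against it.
fixture_clean_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- fixture_model()
      pat <- gait_pattern()
      tr <- generate_trial(m, pat, n_cycles = 3, sta = sta_none(),
                           seed = 11, rate = 100)
      dur <- 120 / pat$cadence
      phi_l <- (tr$time / dur) %% 1
      phi_r <- (tr$time / dur + 0.5) %% 1
      q <- gaitprofile:::.pattern_to_coordinates(m, pat, tr$time, phi_l, phi_r)
      cache <<- list(model = m, pattern = pat, trial = tr, q = q,
                     phi_l = phi_l, phi_r = phi_r)
    }
    cache
  }
})

# Pick one waveform set by side and cycle from an extract_waveforms() list.
wf_pick <- function(wfs, side, cycle = 1) {
  hit <- which(vapply(wfs, function(w) w$side == side && w$cycle == cycle,
                      logical(1)))
  expect_true(length(hit) >= 1)
  wfs[[hit[1]]]
}

# Random rotation matrix from uniform axis + angle.
random_rotation <- function() {
  ax <- stats::rnorm(3)
  gaitprofile:::rot_axis_angle(ax, stats::runif(1, -pi, pi))
}

# Build a gait_cycle_waveforms from a plain matrix of random values.
random_waveforms <- function(T = 101, side = "left", scale = 10) {
  v <- matrix(stats::rnorm(T * 9, sd = scale), T, 9)
  colnames(v) <- gait_variables()
  gait_cycle_waveforms(v, side = side)
}

ref_from_matrix <- function(v, n = 1) reference_profile(v, n_subjects = n)
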