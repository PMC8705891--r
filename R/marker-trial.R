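# The raw observation unit: a labelled 3-D marker trajectory trial with gait
# events and session metadata.

#' Construct a marker trial
#'
#' @param time numeric vector of frame times (seconds), uniformly sampled.
#' @param markers named list; each element an `n x 3` matrix of global marker
#'   positions in metres (laboratory frame: X progression, Y left, Z up).
#' @param events list with elements `left` and `right`, each a list with
#'   numeric vectors `heel_strike` (required, strictly increasing) and
#'   optionally `toe_off`.
#' @param meta named list of metadata (subject id, session, trial id, ...).
#' @param rate sampling rate in Hz; inferred from `time` when `NULL`.
#' @return an object of class `marker_trial`.
#' @export
marker_trial <- function(time, markers, events = list(), meta = list(),
                         rate = NULL) {
  assert_that(is.numeric(time) && length(time) >= 2, "need at least 2 frames")
  dt <- diff(time)
  assert_that(max(abs(dt - dt[1])) < 1e-6, "frame times must be uniform")
  assert_that(is.list(markers) && length(markers) > 0 &&
                !is.null(names(markers)), "markers must be a named list")
  for (l in names(markers)) {
    m <- markers[[l]]
    assert_that(is.matrix(m) && ncol(m) == 3 && nrow(m) == length(time),
                "marker `%s` must be an n x 3 matrix matching `time`", l)
  }
  for (side in names(events)) {
    hs <- events[[side]]$heel_strike
    if (!is.null(hs)) {
      assert_that(all(diff(hs) > 0), "heel strikes for %s must be strictly increasing", side)
    }
  }
  structure(list(time = time, rate = rate %||% (1 / dt[1]),
                 markers = markers, events = events, meta = meta),
            class = "marker_trial")
}

#' @export
print.marker_trial <- function(x, ...) {
  cat("<marker_trial>", length(x$time), "frames @", round(x$rate, 2), "Hz,",
      length(x$markers), "markers\n")
  nhs <- vapply(c("left", "right"), function(s)
    length(x$events[[s]]$heel_strike %||% numeric()), integer(1))
  cat("  heel strikes: left", nhs[1], "/ right", nhs[2], "\n")
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

trial_marker_matrix <- function(trial, labels = names(trial$markers)) {
  miss <- setdiff(labels, names(trial$markers))
  assert_that(length(miss) == 0, "trial is missing marker(s): %s",
              paste(miss, collapse = ", "))
  trial$markers[labels]
}

# Mean marker positions over all frames (quasi-static pose).
static_marker_means <- function(trial) {
  pos <- t(vapply(trial$markers, colMeans, numeric(3)))
  colnames(pos) <- c("x", "y", "z")
  pos
}

# Extract one frame as a named matrix (rows = labels).
trial_frame <- function(trial, f, labels = names(trial$markers)) {
  out <- t(vapply(trial$markers[labels], function(m) m[f, ], numeric(3)))
  rownames(out) <- labels
  out
}

n_frames <- function(trial) length(trial$time)

heel_strikes <- function(trial, side) {
  hs <- trial$events[[side]]$heel_strike
  assert_that(!is.null(hs) && length(hs) >= 1,
              "trial has no heel-strike events for side %s", side)
  hs
}

#' Gait cycles of a trial
#'
#' @param trial a `marker_trial`.
#' @param side `"left"` or `"right"`.
#' @return data frame with columns `start` and `end` (seconds), one row per
#'   complete gait cycle (successive heel strikes).
#' @export
gait_cycles <- function(trial, side) {
  hs <- heel_strikes(trial, check_side(side))
  if (length(hs) < 2) return(data.frame(start = numeric(), end = numeric()))
  data.frame(start = hs[-length(hs)], end = hs[-1])
}
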