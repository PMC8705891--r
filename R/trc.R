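# Readers and writers for the TRC marker-trajectory dialect used by motion
# capture pipelines (tab-separated, two header blocks: file-level fields
# DataRate/NumFrames/Units etc., then Frame#/Time plus X/Y/Z triplets per
# marker), and a MOT/STO-compatible coordinate writer.

#' Write a marker trial as a TRC file
#'
#' @param trial a [marker_trial()].
#' @param path output path.
#' @param units `"m"` or `"mm"` for the written coordinates (positions are
#'   stored in metres internally).
#' @return `path`, invisibly.
#' @export
write_trc <- function(trial, path, units = c("mm", "m")) {
  units <- match.arg(units)
  fac <- if (units == "mm") 1000 else 1
  labels <- names(trial$markers)
  nf <- n_frames(trial)
  rate <- trial$rate
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                     "Units", "OrigDataRate", "OrigDataStartFrame",
                     "OrigNumFrames"), collapse = "\t"), con)
  writeLines(paste(c(format(rate), format(rate), nf, length(labels), units,
                     format(rate), 1, nf), collapse = "\t"), con)
  writeLines(paste(c("Frame#", "Time",
                     as.vector(rbind(labels, "", ""))), collapse = "\t"), con)
  writeLines(paste(c("", "", paste0(rep(c("X", "Y", "Z"), length(labels)),
                                    rep(seq_along(labels), each = 3))),
                   collapse = "\t"), con)
  dat <- do.call(cbind, lapply(trial$markers, function(m) m * fac))
  body <- cbind(seq_len(nf), trial$time, dat)
  utils::write.table(format(body, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a TRC marker file
#'
#' Positions are converted to metres according to the header's `Units`
#' field; the sampling rate is taken from `DataRate`. Malformed headers or
#' a row count that does not match `NumFrames` raise a parse error naming
#' the offending line.
#'
#' @param path a TRC file.
#' @param events,meta optional event/metadata lists attached to the trial
#'   (TRC itself carries neither).
#' @return a [marker_trial()].
#' @export
read_trc <- function(path, events = list(), meta = list()) {
  assert_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  assert_that(length(lines) >= 6, "TRC parse error: fewer than 6 lines in %s", path)
  hdr_names <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  hdr_vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  assert_that(length(hdr_vals) >= length(hdr_names),
              "TRC parse error at line 3: %d header values for %d fields",
              length(hdr_vals), length(hdr_names))
  hdr <- stats::setNames(as.list(hdr_vals[seq_along(hdr_names)]), hdr_names)
  for (f in c("DataRate", "NumFrames", "NumMarkers", "Units")) {
    assert_that(!is.null(hdr[[f]]), "TRC parse error: header field %s missing", f)
  }
  rate <- as.numeric(hdr$DataRate)
  nf <- as.integer(hdr$NumFrames)
  nm <- as.integer(hdr$NumMarkers)
  units <- hdr$Units
  assert_that(units %in% c("m", "mm"), "TRC parse error: unsupported Units `%s`", units)
  fac <- if (units == "mm") 1 / 1000 else 1
  lab_row <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  labels <- lab_row[-(1:2)]
  labels <- labels[labels != ""]
  assert_that(length(labels) == nm,
              "TRC parse error at line 4: %d labels but NumMarkers=%d",
              length(labels), nm)
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  assert_that(length(data_lines) == nf,
              "TRC parse error: %d data rows but NumFrames=%d (truncated file?)",
              length(data_lines), nf)
  cells <- strsplit(data_lines, "\t", fixed = TRUE)
  want <- 2 + 3 * nm
  bad <- which(lengths(cells) != want)
  assert_that(length(bad) == 0,
              "TRC parse error at data row %d: %d columns, expected %d",
              if (length(bad)) bad[1] else 0,
              if (length(bad)) lengths(cells)[bad[1]] else 0, want)
  num <- matrix(as.numeric(unlist(cells)), nrow = nf, byrow = TRUE)
  assert_that(!anyNA(num), "TRC parse error: non-numeric cell in data block")
  time <- num[, 2]
  markers <- list()
  for (i in seq_len(nm)) {
    markers[[labels[i]]] <- num[, 2 + (3 * (i - 1) + 1):(3 * i), drop = FALSE] * fac
  }
  marker_trial(time, markers, events = events, meta = meta, rate = rate)
}

#' Write a coordinate trajectory in MOT/STO column format
#'
#' Time plus named coordinate columns; rotational coordinates are written
#' in degrees (`inDegrees=yes`), translations in metres.
#'
#' @param q_trajectory frames x coordinates matrix with named columns
#'   (radians/metres), or an `ik_result`.
#' @param time frame times (ignored when an `ik_result` is given).
#' @param path output path.
#' @param name dataset name written in the header.
#' @return `path`, invisibly.
#' @export
write_mot <- function(q_trajectory, time = NULL, path, name = "coordinates") {
  if (inherits(q_trajectory, "ik_result")) {
    time <- q_trajectory$time
    q_trajectory <- q_trajectory$q_trajectory
  }
  assert_that(is.matrix(q_trajectory) && !is.null(colnames(q_trajectory)),
              "q_trajectory must be a matrix with named columns")
  assert_that(length(time) == nrow(q_trajectory), "time length mismatch")
  qd <- q_trajectory
  rot <- !grepl("_t[xyz]$", colnames(qd))
  qd[, rot] <- rad2deg(qd[, rot])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name, "version=1",
               sprintf("nRows=%d", nrow(qd)),
               sprintf("nColumns=%d", ncol(qd) + 1L),
               "inDegrees=yes", "endheader"), con)
  writeLines(paste(c("time", colnames(qd)), collapse = "\t"), con)
  body <- cbind(time, qd)
  utils::write.table(format(body, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write per-cycle waveforms to the documented CSV layout
#'
#' One row per normalised time point (0-100%), one column per variable,
#' preceded by identifying columns taken from the waveform metadata.
#'
#' @param waveform_sets list of [gait_cycle_waveforms()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveforms_csv <- function(waveform_sets, path) {
  rows <- lapply(waveform_sets, function(w) {
    Tn <- nrow(w$values)
    data.frame(subject = w$meta$subject %||% NA_character_,
               session = w$meta$session %||% NA_character_,
               trial = w$meta$trial %||% NA_integer_,
               engine = w$meta$engine %||% NA_character_,
               side = w$side, cycle = w$cycle,
               percent = seq(0, 100, length.out = Tn),
               w$values, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
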