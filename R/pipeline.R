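# End-to-end analysis pipeline: synthetic cohort -> kinematics engines ->
# GPS metrics -> outcome statistics, with every artefact written to disk
# under a config-hashed manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. The resolved configuration
#' is validated up front, logged into the results manifest, and hashed so
#' outputs can be traced back to it.
#'
#' @param cohort a [cohort_spec()].
#' @param engines engines to run: subset of `c("dk", "ik")`.
#' @param T normalised-time grid size (default 101).
#' @param mcid responder threshold in degrees.
#' @param alpha_family,n_comparisons family-wise level and Bonferroni
#'   divisor of the waveform comparison.
#' @param n_permutations permutation budget of the waveform test.
#' @param age_groups age-group boundaries (years) for reference profiles.
#' @param ik an [ik_config()].
#' @param run_waveform_test run the pointwise waveform comparison (the
#'   slowest statistic) on the TD cohort.
#' @param seed master seed; overrides the cohort spec's seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), engines = c("dk", "ik"),
                            T = 101, mcid = 1.6, alpha_family = 0.05,
                            n_comparisons = 9, n_permutations = 1000,
                            age_groups = c(10, 16), ik = ik_config(),
                            run_waveform_test = TRUE, seed = NULL) {
  assert_that(all(engines %in% c("dk", "ik")) && length(engines) >= 1,
              "engines must be a non-empty subset of c(\"dk\", \"ik\")")
  assert_that(T >= 2, "T must be >= 2")
  assert_that(mcid > 0, "mcid must be > 0")
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, engines = engines, T = T, mcid = mcid,
                 alpha_family = alpha_family, n_comparisons = n_comparisons,
                 n_permutations = n_permutations, age_groups = age_groups,
                 ik = ik, run_waveform_test = isTRUE(run_waveform_test)),
            class = "pipeline_config")
}

# Stable short hash of the resolved configuration (for the manifest).
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  dump <- config
  dump$ik <- unclass(dump$ik)
  dump$cohort$sta <- unclass(dump$cohort$sta)
  dump$cohort <- unclass(dump$cohort)
  yaml::write_yaml(unclass(dump), tmp, precision = 12)
  unname(tools::md5sum(tmp))
}

# Limb-session mean waveforms for one subject and one engine.
.limb_mean_waveforms <- function(subject, engine, config, model_for_ik = NULL) {
  out <- list()
  for (sess in names(subject$sessions)) {
    trials <- subject$sessions[[sess]]
    per_side <- list(left = list(), right = list())
    for (tr in seq_along(trials)) {
      trial <- trials[[tr]]
      wfs <- if (engine == "dk") {
        extract_waveforms_dk(trial, subject$anthropometry, T = config$T)
      } else {
        extract_waveforms_ik(model_for_ik, trial, cfg = config$ik, T = config$T)
      }
      for (w in wfs) per_side[[w$side]][[length(per_side[[w$side]]) + 1L]] <- w
    }
    for (side in c("left", "right")) {
      if (!length(per_side[[side]])) next
      mw <- average_trials(per_side[[side]])
      mw$meta$subject <- subject$id
      mw$meta$session <- sess
      mw$meta$engine <- engine
      out[[paste(sess, side, sep = ".")]] <- mw
    }
  }
  out
}

# Scale + knee-axis-correct the generic model for a subject from its static
# trial, as the multibody workflow prescribes.
.subject_ik_model <- function(subject, config) {
  generic <- build_generic_model(anthropometry = generic_anthropometry())
  scaled <- scale_model(generic, subject$static, subject$anthropometry)$model
  scaled <- apply_knee_axis_correction(scaled, "left",
                                       clamp(subject$kad_deg$left, -45, 45))
  apply_knee_axis_correction(scaled, "right",
                             clamp(subject$kad_deg$right, -45, 45))
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a synthetic cohort, runs the selected kinematics
#' engines on every trial, computes limb-session mean waveforms, age-matched
#' reference profiles and GVS/GPS scores per engine, assembles outcome
#' records for the operated limbs, and computes the engine-comparison
#' statistics. All artefacts are written as CSV under `outdir` together with
#' a JSON manifest (config echo, seed, config hash, per-file checksums).
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param cohort optionally a pre-generated [generate_cohort()] result
#'   (must match the config's cohort spec).
#' @return list of class `pipeline_result` with `gps_table`, `gvs_table`,
#'   `references`, `records`, `agreement`, `stats`, `rmsd_table`,
#'   `kad_comparison`, `waveform_test`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         cohort = NULL) {
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  t0 <- Sys.time()
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  engines <- config$engines

  # --- engine waveforms per limb/session ---------------------------------
  mean_wfs <- list()  # [[engine]][[subject]][[session.side]]
  for (eng in engines) {
    mean_wfs[[eng]] <- list()
    for (id in names(cohort$subjects)) {
      subj <- cohort$subjects[[id]]
      model_ik <- if (eng == "ik") .subject_ik_model(subj, config) else NULL
      mean_wfs[[eng]][[id]] <- .limb_mean_waveforms(subj, eng, config, model_ik)
    }
  }

  # --- age-matched reference profiles per engine -------------------------
  references <- list()
  td_ids <- cohort$metadata$subject[cohort$metadata$group == "TD"]
  for (eng in engines) {
    wfs <- list(); ages <- numeric()
    for (id in td_ids) {
      for (key in names(mean_wfs[[eng]][[id]])) {
        wfs[[length(wfs) + 1L]] <- mean_wfs[[eng]][[id]][[key]]
        ages <- c(ages, cohort$subjects[[id]]$age)
      }
    }
    references[[eng]] <- build_reference(wfs, ages, config$age_groups)
  }

  # --- GVS / GPS tables --------------------------------------------------
  gps_rows <- list(); gvs_rows <- list()
  for (eng in engines) {
    for (id in names(cohort$subjects)) {
      subj <- cohort$subjects[[id]]
      grp <- .age_group_label(subj$age, config$age_groups)
      ref <- references[[eng]][[grp]]
      for (key in names(mean_wfs[[eng]][[id]])) {
        w <- mean_wfs[[eng]][[id]][[key]]
        sc <- gvs(w, ref)
        gps_rows[[length(gps_rows) + 1L]] <- data.frame(
          subject = id, side = w$side, session = w$meta$session,
          engine = eng, group = subj$group, age = subj$age,
          gps = gps(sc), stringsAsFactors = FALSE)
        gvs_rows[[length(gvs_rows) + 1L]] <- data.frame(
          subject = id, side = w$side, session = w$meta$session,
          engine = eng, variable = names(sc), score = as.numeric(sc),
          stringsAsFactors = FALSE)
      }
    }
  }
  gps_table <- do.call(rbind, gps_rows)
  gvs_table <- do.call(rbind, gvs_rows)

  # --- engine comparison -------------------------------------------------
  stats_out <- list()
  rmsd_table <- NULL
  waveform_test <- NULL
  if (all(c("dk", "ik") %in% engines)) {
    key_cols <- c("subject", "side", "session")
    wide <- merge(gps_table[gps_table$engine == "dk", c(key_cols, "gps")],
                  gps_table[gps_table$engine == "ik", c(key_cols, "gps")],
                  by = key_cols, suffixes = c("_dk", "_ik"))
    stats_out$gps_spearman <- paired_tests(wide$gps_dk, wide$gps_ik, "spearman")
    stats_out$gps_wilcoxon <- paired_tests(wide$gps_dk, wide$gps_ik, "wilcoxon")
    stats_out$gps_mean_abs_diff <- mean(abs(wide$gps_dk - wide$gps_ik))
    # symmetry index per subject/session/engine
    si <- list()
    for (eng in engines) {
      sub <- gps_table[gps_table$engine == eng, ]
      keys <- unique(sub[, c("subject", "session")])
      si[[eng]] <- vapply(seq_len(nrow(keys)), function(i) {
        l <- sub$gps[sub$subject == keys$subject[i] &
                       sub$session == keys$session[i] & sub$side == "left"]
        r <- sub$gps[sub$subject == keys$subject[i] &
                       sub$session == keys$session[i] & sub$side == "right"]
        if (length(l) == 1 && length(r) == 1 && (l + r) > 0)
          symmetry_index(l, r) else NA_real_
      }, numeric(1))
    }
    ok <- stats::complete.cases(si$dk, si$ik)
    if (sum(ok) >= 3) {
      stats_out$si_pearson <- paired_tests(si$dk[ok], si$ik[ok], "pearson")
    }
    # per-variable RMSD between engines (limb-session mean waveforms)
    rmsd_rows <- list()
    for (id in names(cohort$subjects)) {
      for (key in intersect(names(mean_wfs$dk[[id]]), names(mean_wfs$ik[[id]]))) {
        r <- waveform_rmsd(mean_wfs$dk[[id]][[key]], mean_wfs$ik[[id]][[key]])
        rmsd_rows[[length(rmsd_rows) + 1L]] <- data.frame(
          subject = id, key = key, variable = names(r), rmsd = as.numeric(r),
          stringsAsFactors = FALSE)
      }
    }
    rmsd_table <- do.call(rbind, rmsd_rows)
    if (config$run_waveform_test && length(td_ids) >= 2) {
      a <- list(); b <- list()
      for (id in td_ids) {
        for (key in intersect(names(mean_wfs$dk[[id]]), names(mean_wfs$ik[[id]]))) {
          a[[length(a) + 1L]] <- mean_wfs$dk[[id]][[key]]
          b[[length(b) + 1L]] <- mean_wfs$ik[[id]][[key]]
        }
      }
      waveform_test <- pointwise_waveform_test(
        a, b, alpha_family = config$alpha_family,
        n_comparisons = config$n_comparisons,
        n_permutations = config$n_permutations)
    }
  }

  # --- responder classification & agreement ------------------------------
  records <- NULL; agreement <- NULL
  if (any(cohort$limbs$operated)) {
    records <- build_outcome_records(gps_table, cohort$limbs, config$mcid)
    agreement <- tabulate_agreement(records)
    if (all(c("dk", "ik") %in% engines) && nrow(records) >= 3) {
      stats_out$delta_bland_altman <- bland_altman(records$delta_gps_dk,
                                                   records$delta_gps_ik)
      stats_out$delta_paired_t <- paired_tests(records$delta_gps_dk,
                                               records$delta_gps_ik, "paired_t")
    }
  }

  # --- knee-axis correction group comparison -----------------------------
  kad_comparison <- NULL
  kad_groups <- list(
    TD = cohort$limbs$kad_deg[cohort$limbs$group == "TD"],
    CP_pre = cohort$limbs$kad_deg[cohort$limbs$group == "CP"],
    CP_post = cohort$limbs$kad_deg[cohort$limbs$group == "CP"])
  if (all(lengths(kad_groups) >= 2)) {
    kad_comparison <- group_axis_comparison(kad_groups)
  }

  result <- structure(list(
    gps_table = gps_table, gvs_table = gvs_table, references = references,
    records = records, agreement = agreement, stats = stats_out,
    rmsd_table = rmsd_table, kad_comparison = kad_comparison,
    waveform_test = waveform_test, cohort_metadata = cohort$metadata,
    limbs = cohort$limbs, config = config,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "pipeline_result")

  if (!is.null(outdir)) {
    result$manifest <- .write_pipeline_outputs(result, outdir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", nrow(x$gps_table), "limb-session GPS values,",
      "engines:", paste(x$config$engines, collapse = "+"), "\n")
  if (!is.null(x$agreement)) print(x$agreement)
  invisible(x)
}

.write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files[[name]] <<- p
  }
  wr(result$gps_table, "gps_scores.csv")
  wr(result$gvs_table, "gvs_scores.csv")
  wr(result$rmsd_table, "engine_rmsd.csv")
  wr(result$cohort_metadata, "cohort_metadata.csv")
  wr(result$limbs, "limbs.csv")
  if (!is.null(result$records)) wr(as.data.frame(result$records), "outcome_records.csv")
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = result$config$cohort$seed,
    config_hash = .config_hash(result$config),
    engines = result$config$engines,
    skipped_stages = setdiff(c("dk", "ik"), result$config$engines),
    files = lapply(files, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))),
    agreement = if (!is.null(result$agreement)) {
      list(n_limbs = result$agreement$n_limbs,
           clinical_agreement = as.list(result$agreement$clinical_agreement),
           engine_concordance = result$agreement$engine_concordance)
    })
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}
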