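# Outcome statistics: engine comparison statistics (RMSD, R2, Bland-Altman,
# rank tests, pointwise waveform permutation test, Kruskal-Wallis + Dunn)
# and the responder classification against the minimal clinically important
# difference, with agreement tabulation against clinical labels.

#' Classify surgical response from a change in Gait Profile Score
#'
#' A limb is a responder when its change in GPS from pre- to post-surgery
#' satisfies `delta_gps <= -mcid` (boundary inclusive); otherwise it is a
#' non-responder. The default MCID of 1.6 degrees is the published minimal
#' clinically important difference for the GPS. The orientation is
#' post - pre, so improvement is negative.
#'
#' @param delta_gps change in GPS (degrees, post minus pre); vectorised.
#' @param mcid minimal clinically important difference (degrees, positive).
#' @return character vector, `"responder"` or `"non-responder"`.
#' @export
classify_responder <- function(delta_gps, mcid = 1.6) {
  assert_that(all(is.finite(delta_gps)), "delta_gps must be finite")
  assert_that(is_scalar_number(mcid) && mcid > 0, "mcid must be > 0")
  ifelse(delta_gps <= -mcid, "responder", "non-responder")
}

.wf_values <- function(x) {
  if (inherits(x, "gait_cycle_waveforms")) x$values else x
}

#' Per-variable RMS difference between two waveform sets
#'
#' @param a,b [gait_cycle_waveforms()] (or bare matrices) on the same grid.
#' @return named numeric vector (degrees), one value per variable.
#' @export
waveform_rmsd <- function(a, b) {
  av <- .wf_values(a); bv <- .wf_values(b)
  assert_that(identical(dim(av), dim(bv)), "waveform grids differ")
  sqrt(colMeans((av - bv)^2))
}

#' Per-variable coefficient of determination of a linear fit
#'
#' Fits `a ~ b` by least squares per variable and returns
#' `1 - SS_res / SS_tot`, the linear-fit measure of curve similarity.
#'
#' @param a,b waveform sets on the same grid; `b` is the predictor.
#' @return named numeric vector of R-squared values in `[0, 1]` (the
#'   intercept is fitted, so the least-squares fit can never do worse than
#'   the mean).
#' @export
waveform_r2 <- function(a, b) {
  av <- .wf_values(a); bv <- .wf_values(b)
  assert_that(identical(dim(av), dim(bv)), "waveform grids differ")
  out <- stats::setNames(numeric(ncol(av)), colnames(av))
  for (j in seq_len(ncol(av))) {
    x <- bv[, j]; y <- av[, j]
    assert_that(stats::var(x) > 1e-12,
                "undefined fit: predictor waveform `%s` is constant",
                colnames(av)[j] %||% as.character(j))
    fit <- stats::lm.fit(cbind(1, x), y)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    out[j] <- 1 - ss_res / ss_tot
  }
  out
}

#' Bland-Altman agreement analysis
#'
#' @param x,y paired measurements of the same quantity by two methods.
#' @return list with `bias` (mean of x - y), `sd` (sample SD, n-1
#'   denominator), `loa_low`, `loa_high` (bias -/+ 1.96 sd), `n`.
#' @export
bland_altman <- function(x, y) {
  assert_that(length(x) == length(y), "x and y lengths differ")
  assert_that(length(x) >= 2, "Bland-Altman needs at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       n = length(d))
}

#' Paired comparison statistics between two engines' estimates
#'
#' Thin, documented wrappers over the standard tests: Wilcoxon signed-rank
#' (zero differences dropped, ties get average ranks, asymptotic p), paired
#' t, Spearman's rho and Pearson's r (asymptotic p for Spearman in the
#' presence of ties).
#'
#' @param dk_values,ik_values equal-length numeric vectors (n >= 3).
#' @param kind one of `"wilcoxon"`, `"paired_t"`, `"spearman"`, `"pearson"`.
#' @return list with `statistic`, `p_value`, `method`.
#' @export
paired_tests <- function(dk_values, ik_values,
                         kind = c("wilcoxon", "paired_t", "spearman", "pearson")) {
  kind <- match.arg(kind)
  assert_that(length(dk_values) == length(ik_values), "input lengths differ")
  assert_that(length(dk_values) >= 3, "need at least 3 pairs")
  ht <- switch(kind,
    wilcoxon = suppressWarnings(
      stats::wilcox.test(dk_values, ik_values, paired = TRUE, exact = FALSE)),
    paired_t = stats::t.test(dk_values, ik_values, paired = TRUE),
    spearman = suppressWarnings(
      stats::cor.test(dk_values, ik_values, method = "spearman", exact = FALSE)),
    pearson = stats::cor.test(dk_values, ik_values, method = "pearson"))
  est <- if (kind %in% c("spearman", "pearson")) unname(ht$estimate) else
    unname(ht$statistic)
  list(statistic = est, p_value = unname(ht$p.value), method = ht$method)
}

#' Pointwise paired waveform comparison by a max-statistic permutation test
#'
#' For each variable, paired differences between two waveform conditions are
#' tested over the whole normalised gait cycle: the observed paired
#' t-statistic at each time point is compared with the permutation null
#' distribution of the maximum absolute t over the cycle (sign flips of the
#' paired differences), which controls the family-wise error over time.
#' Across the nine variables a Bonferroni correction is applied:
#' the per-variable test level is `alpha_family / n_comparisons`
#' (0.05 / 9 = 0.0056 at the defaults).
#'
#' Sign-flip patterns are enumerated exhaustively when the number of pairs
#' is <= `exhaustive_limit`, otherwise `n_permutations` random flips are
#' used (the identity pattern is always included).
#'
#' @param group_a_waveforms,group_b_waveforms lists of waveform sets (one
#'   per subject, paired by position) on a common grid.
#' @param alpha_family family-wise significance level across variables.
#' @param n_comparisons number of variables compared (Bonferroni divisor).
#' @param n_permutations random sign-flip patterns when not exhaustive.
#' @param exhaustive_limit maximum n for exhaustive enumeration (2^n).
#' @return list with `alpha_per_test`, and per variable: `t_obs` (length-T),
#'   `t_max` (observed max |t|), `p` (permutation p of the max statistic),
#'   `threshold` (critical max-|t|), `mask` (logical length-T suprathreshold
#'   region), `significant`.
#' @export
pointwise_waveform_test <- function(group_a_waveforms, group_b_waveforms,
                                    alpha_family = 0.05, n_comparisons = 9,
                                    n_permutations = 1000,
                                    exhaustive_limit = 12) {
  n <- length(group_a_waveforms)
  assert_that(n == length(group_b_waveforms) && n >= 2,
              "need paired waveform lists with n >= 2")
  alpha <- alpha_family / n_comparisons
  va <- lapply(group_a_waveforms, .wf_values)
  vb <- lapply(group_b_waveforms, .wf_values)
  Tn <- nrow(va[[1]])
  vars <- colnames(va[[1]])
  exhaustive <- n <= exhaustive_limit
  if (exhaustive) {
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    assert_that(n_permutations >= 100, "n_permutations must be >= 100")
    assert_that((n_permutations + 1) * alpha >= 1,
                "insufficient permutations to resolve the requested alpha")
    S <- rbind(rep(1, n),
               matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                      n_permutations, n))
  }
  npat <- nrow(S)
  out <- list(alpha_per_test = alpha, variables = list())
  for (v in vars) {
    D <- t(vapply(seq_len(n), function(i) va[[i]][, v] - vb[[i]][, v],
                  numeric(Tn)))  # n x T
    q2 <- colSums(D^2)
    M <- (S %*% D) / n                      # npat x T permutation means
    # per-flip sd: squares are sign-invariant, so only the mean varies
    s2 <- sweep(-n * M^2, 2, q2, `+`) / (n - 1)
    tmat <- M / sqrt(pmax(s2, 1e-300) / n)
    tmax <- apply(abs(tmat), 1, max)
    iobs <- which(rowSums(S == 1) == n)[1]
    t_obs_max <- tmax[iobs]
    p <- mean(tmax >= t_obs_max - 1e-12)
    thr <- stats::quantile(tmax, 1 - alpha, type = 1, names = FALSE)
    t_obs <- tmat[iobs, ]
    mask <- p <= alpha & abs(t_obs) >= thr
    out$variables[[v]] <- list(t_obs = t_obs, t_max = t_obs_max, p = p,
                               threshold = thr, mask = mask,
                               significant = p <= alpha)
  }
  out
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' Rank-based comparison of knee-axis correction angles (or any numeric
#' outcome) across groups, followed by Dunn's pairwise z tests with average
#' ranks and tie correction; unadjusted and Bonferroni-adjusted pairwise
#' p-values are both reported.
#'
#' @param corrections named list of numeric vectors, one per group (>= 2
#'   groups, each n >= 2).
#' @return list with `omnibus` (`statistic`, `p_value`) and `pairwise`
#'   (data frame: group pair, z, p, p_bonferroni).
#' @export
group_axis_comparison <- function(corrections) {
  assert_that(is.list(corrections) && length(corrections) >= 2,
              "need at least 2 groups")
  for (g in names(corrections)) {
    assert_that(length(corrections[[g]]) >= 2,
                "group `%s` needs at least 2 observations", g)
  }
  kw <- stats::kruskal.test(corrections)
  x <- unlist(corrections, use.names = FALSE)
  grp <- rep(names(corrections), lengths(corrections))
  N <- length(x)
  r <- rank(x)  # average ranks for ties
  rbar <- tapply(r, grp, mean)
  nn <- tapply(r, grp, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  pairs <- utils::combn(names(corrections), 2)
  rows <- apply(pairs, 2, function(pr) {
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) /
      sqrt(s2 * (1 / nn[[pr[1]]] + 1 / nn[[pr[2]]]))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = pr[1], group2 = pr[2], z = z, p = p,
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$p_bonferroni <- pmin(1, pw$p * nrow(pw))
  list(omnibus = list(statistic = unname(kw$statistic),
                      p_value = kw$p.value),
       pairwise = pw)
}

#' Assemble per-limb outcome records
#'
#' Joins pre/post GPS values per engine into one record per operated limb,
#' computes the change in GPS (post - pre) and applies
#' [classify_responder()].
#'
#' @param gps_table data frame with columns `subject`, `side`, `session`
#'   (`"pre"`/`"post"`), `engine` (`"dk"`/`"ik"`), `gps`.
#' @param limb_table data frame with `subject`, `side`, `operated`,
#'   `clinical_label` (as produced by [generate_cohort()]); may contain more
#'   columns, which are carried through.
#' @param mcid MCID threshold in degrees.
#' @return data frame of class `outcome_records`, one row per operated limb.
#' @export
build_outcome_records <- function(gps_table, limb_table, mcid = 1.6) {
  need <- c("subject", "side", "session", "engine", "gps")
  assert_that(all(need %in% names(gps_table)), "gps_table missing columns")
  op <- limb_table[limb_table$operated %in% TRUE, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(op))) {
    sb <- op$subject[i]; sd_ <- op$side[i]
    rec <- op[i, , drop = FALSE]
    for (eng in unique(gps_table$engine)) {
      pre <- gps_table$gps[gps_table$subject == sb & gps_table$side == sd_ &
                             gps_table$engine == eng & gps_table$session == "pre"]
      post <- gps_table$gps[gps_table$subject == sb & gps_table$side == sd_ &
                              gps_table$engine == eng & gps_table$session == "post"]
      assert_that(length(pre) == 1 && length(post) == 1,
                  "missing pre/post GPS for %s %s engine %s", sb, sd_, eng)
      rec[[paste0("gps_pre_", eng)]] <- pre
      rec[[paste0("gps_post_", eng)]] <- post
      rec[[paste0("delta_gps_", eng)]] <- post - pre
      rec[[paste0("responder_", eng)]] <- classify_responder(post - pre, mcid)
    }
    rows[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  class(out) <- c("outcome_records", class(out))
  out
}

#' Tabulate classification agreement for operated limbs
#'
#' Counts, for operated limbs only, each engine's agreement with the
#' clinical responder label and the two engines' concordance with each
#' other; discordant limbs are listed with the absolute difference between
#' the engines' GPS changes.
#'
#' @param records an [build_outcome_records()] data frame (must contain the
#'   per-engine `responder_*` and `delta_gps_*` columns and
#'   `clinical_label`).
#' @return list of class `agreement_summary`: `n_limbs`,
#'   `clinical_agreement` (named counts per engine), `engine_concordance`,
#'   `discordant` (data frame of limbs where the engines disagree, with
#'   `delta_diff`).
#' @export
tabulate_agreement <- function(records) {
  rec <- records[records$operated %in% TRUE, , drop = FALSE]
  assert_that(nrow(rec) > 0, "no operated limbs in records")
  miss <- which(is.na(rec$clinical_label))
  if (length(miss)) {
    stopf("missing clinical label for limb %s (%s)",
          rec$subject[miss[1]], rec$side[miss[1]])
  }
  engines <- sub("^responder_", "", grep("^responder_", names(rec), value = TRUE))
  agree <- vapply(engines, function(e)
    sum(rec[[paste0("responder_", e)]] == rec$clinical_label), integer(1))
  n <- nrow(rec)
  conc <- NA_integer_
  disc <- NULL
  if (all(c("dk", "ik") %in% engines)) {
    same <- rec$responder_dk == rec$responder_ik
    conc <- sum(same)
    disc <- rec[!same, c("subject", "side", "delta_gps_dk", "delta_gps_ik")]
    disc$delta_diff <- abs(disc$delta_gps_dk - disc$delta_gps_ik)
  }
  structure(list(n_limbs = n, clinical_agreement = agree,
                 engine_concordance = conc, discordant = disc),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat("<agreement_summary>", x$n_limbs, "operated limbs\n")
  for (e in names(x$clinical_agreement)) {
    cat(sprintf("  %s vs clinical: %d/%d\n", e, x$clinical_agreement[[e]],
                x$n_limbs))
  }
  if (!is.na(x$engine_concordance)) {
    cat(sprintf("  engine concordance: %d/%d\n", x$engine_concordance,
                x$n_limbs))
  }
  invisible(x)
}

#' Bonferroni-corrected per-test alpha for the waveform comparisons
#'
#' @param alpha_family family-wise level (default 0.05).
#' @param n_comparisons number of kinematic variables compared (default 9).
#' @return per-test alpha (0.05/9 = 0.0056 at 4 decimal places).
#' @export
per_test_alpha <- function(alpha_family = 0.05, n_comparisons = 9) {
  alpha_family / n_comparisons
}
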