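# Paired differential methylation/expression: empirical-Bayes moderated
# paired t on per-patient differences, BH correction, delta-beta and call
# sets, per-patient single-sample delta-beta sets, and cohort kinetics
# summaries.

#' Build a paired design from the sample sheet
#'
#' One row per patient with both timepoints available for the requested
#' cell type and cycle; patients lacking either sample are omitted and
#' recorded in the `omitted_patients` attribute.
#'
#' @param sheet Sample sheet tibble.
#' @param t1,t0 Timepoints contrasted (`t1 - t0`), e.g. `"d8"`, `"d0"`.
#' @param cycle Treatment cycle.
#' @param cell_type `"blast"` or `"tcell"`.
#' @return Tibble with `patient_id`, `sample_t1`, `sample_t0`.
#' @export
paired_design <- function(sheet, t1 = "d8", t0 = "d0", cycle = 1,
                          cell_type = "blast") {
  validate_sample_sheet(sheet)
  sub <- sheet %>%
    filter(.data$cycle == !!cycle, .data$cell_type == !!cell_type,
           .data$timepoint %in% c(t1, t0))
  wide <- sub %>%
    select("patient_id", "timepoint", "sample_id") %>%
    tidyr::pivot_wider(names_from = "timepoint", values_from = "sample_id")
  for (tp in c(t1, t0)) if (!tp %in% colnames(wide)) wide[[tp]] <- NA_character_
  complete <- !is.na(wide[[t1]]) & !is.na(wide[[t0]])
  design <- tibble(patient_id = wide$patient_id[complete],
                   sample_t1 = wide[[t1]][complete],
                   sample_t0 = wide[[t0]][complete]) %>%
    arrange(.data$patient_id)
  attr(design, "omitted_patients") <- sort(wide$patient_id[!complete])
  attr(design, "contrast") <- c(t1 = t1, t0 = t0)
  design
}

paired_differences <- function(values, design) {
  m <- as_feature_matrix(values)
  missing <- setdiff(c(design$sample_t1, design$sample_t0), colnames(m))
  if (length(missing)) {
    abort(sprintf("design sample '%s' is absent from the matrix", missing[1]))
  }
  d <- m[, design$sample_t1, drop = FALSE] - m[, design$sample_t0, drop = FALSE]
  colnames(d) <- design$patient_id
  d
}

# Newton solve of trigamma(x) = y (y > 0); mirrors the standard
# monotone-convergent iteration for this strictly decreasing convex function.
trigamma_inverse <- function(y) {
  stopifnot(all(y > 0))
  x <- ifelse(y > 1e7, 1 / sqrt(y), ifelse(y < 1e-6, 1 / y, 0.5 + 1 / y))
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

# Method-of-moments fit of the scaled-F prior on sample variances:
# s^2 ~ s0^2 * F(d, d0), matched on mean/variance of log s^2.
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) {
    abort("cannot pool variances: fewer than two features with positive variance")
  }
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion beyond chi-squared sampling noise: fully pooled
    warn("log-variance dispersion at or below sampling noise; using a fully pooled variance (infinite prior df)")
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated paired t-test with empirical-Bayes variance shrinkage
#'
#' One-sample moderated t on per-patient paired differences. Per-feature
#' sample variances are shrunk towards a common prior fitted by
#' method-of-moments on log variances (scaled-F model): the posterior
#' variance is `(d0*s0^2 + d*s^2) / (d0 + d)` and the statistic is referred
#' to a t distribution on `d + d0` degrees of freedom. With `prior_df = 0`
#' the statistic reduces exactly to the ordinary paired t.
#'
#' @param values Feature-by-sample tibble on the testing scale (m-values or
#'   log2 intensities).
#' @param design A [paired_design()]; needs at least two patients.
#' @param prior_df,prior_var Optional hyperparameter overrides (`d0`,
#'   `s0^2`); both default to method-of-moments estimates.
#' @return Tibble with `feature_id`, `mean_diff`, `s2`, `mod_t`, `df_total`,
#'   `p`; hyperparameters in attributes `d0` and `s0_sq`.
#' @export
moderated_paired_test <- function(values, design, prior_df = NULL,
                                  prior_var = NULL) {
  if (nrow(design) < 2) abort("paired test needs at least 2 patients")
  d_mat <- paired_differences(values, design)
  n <- ncol(d_mat)
  d <- n - 1
  mean_diff <- rowMeans(d_mat)
  s2 <- row_vars(d_mat)
  if (all(s2 == 0)) {
    abort("all features have identical differences in every patient; no variance to pool")
  }
  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, d)
  } else {
    if (prior_df > 0 && is.null(prior_var)) {
      prior_var <- fit_variance_prior(s2, d)$s0_sq
    }
    prior <- list(d0 = prior_df, s0_sq = prior_var %||% NA_real_)
  }
  d0 <- prior$d0
  s0_sq <- prior$s0_sq
  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- d
  } else {
    s2_post <- (d0 * s0_sq + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  mod_t <- mean_diff / sqrt(s2_post / n)
  mod_t[s2_post == 0] <- NaN
  p <- 2 * pt(abs(mod_t), df = df_total, lower.tail = FALSE)
  p[is.nan(mod_t) & mean_diff == 0] <- 1
  out <- tibble(feature_id = rownames(d_mat), mean_diff = unname(mean_diff),
                s2 = unname(s2), mod_t = unname(mod_t), df_total = df_total,
                p = unname(p))
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "n") <- n
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wraps `stats::p.adjust(method = "BH")`), with
#' input validation.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, order-preserving.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort("p-values must be finite and within [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Group delta-beta for a paired design
#'
#' Mean over patients of the per-patient beta difference (`t1 - t0`).
#'
#' @param beta Beta tibble.
#' @param design A [paired_design()].
#' @return Tibble with `cpg_id`, `delta_beta`.
#' @export
group_delta_beta <- function(beta, design) {
  d <- paired_differences(beta, design)
  tibble(cpg_id = rownames(d), delta_beta = unname(rowMeans(d)))
}

#' Paired differential methylation with delta-beta/FDR calling
#'
#' Runs the moderated paired test on m-values, computes group delta-beta on
#' the beta scale, BH-adjusts, and flags demethylated (`adj_p < alpha` and
#' `delta_beta < -delta_threshold`) and remethylated
#' (`adj_p < alpha` and `delta_beta > +delta_threshold`) CpGs. Thresholds
#' are strict inequalities.
#'
#' @param beta Beta tibble (already filtered with [filter_cpgs()]).
#' @param sheet Sample sheet.
#' @inheritParams paired_design
#' @param alpha BH-adjusted significance threshold. Default 0.05.
#' @param delta_threshold Absolute delta-beta threshold. Default 0.1.
#' @param epsilon Clamp for the logit transform (see [beta_to_m()]).
#' @param prior_df,prior_var Passed to [moderated_paired_test()].
#' @return A `dm_result` object; see [tidy.dm_result()] and
#'   [glance.dm_result()].
#' @export
diff_methylation <- function(beta, sheet, t1 = "d8", t0 = "d0", cycle = 1,
                             cell_type = "blast", alpha = 0.05,
                             delta_threshold = 0.1, epsilon = 0.001,
                             prior_df = NULL, prior_var = NULL) {
  if (nrow(beta) == 0) abort("beta matrix is empty (all CpGs filtered?)")
  design <- paired_design(sheet, t1 = t1, t0 = t0, cycle = cycle,
                          cell_type = cell_type)
  if (nrow(design) < 2) {
    abort(sprintf("fewer than 2 patients with both %s and %s samples", t1, t0))
  }
  mvals <- beta_to_m(beta, epsilon = epsilon)
  fit <- moderated_paired_test(mvals, design, prior_df = prior_df,
                               prior_var = prior_var)
  delta <- group_delta_beta(beta, design)
  adj_p <- bh_adjust(fit$p)
  table <- tibble(
    cpg_id = fit$feature_id,
    delta_beta = delta$delta_beta,
    mean_m_diff = fit$mean_diff,
    mod_t = fit$mod_t,
    p = fit$p,
    adj_p = adj_p,
    demethylated_call = adj_p < alpha & delta$delta_beta < -delta_threshold,
    remethylated_call = adj_p < alpha & delta$delta_beta > delta_threshold)
  structure(list(table = table, design = design,
                 params = list(t1 = t1, t0 = t0, cycle = cycle,
                               cell_type = cell_type, alpha = alpha,
                               delta_threshold = delta_threshold,
                               epsilon = epsilon),
                 d0 = attr(fit, "d0"), s0_sq = attr(fit, "s0_sq"),
                 n_patients = nrow(design)),
            class = "dm_result")
}

#' @export
print.dm_result <- function(x, ...) {
  cat(sprintf("Paired differential methylation: %s vs %s, cycle %s, %s (n = %d patients)\n",
              x$params$t1, x$params$t0, x$params$cycle, x$params$cell_type,
              x$n_patients))
  cat(sprintf("  %d features; %d demethylated, %d remethylated (adj p < %g, |delta beta| > %g)\n",
              nrow(x$table), sum(x$table$demethylated_call),
              sum(x$table$remethylated_call), x$params$alpha,
              x$params$delta_threshold))
  invisible(x)
}

#' Tidy a differential methylation result
#'
#' @param x A `dm_result`.
#' @param ... Unused.
#' @return The per-CpG result tibble.
#' @export
tidy.dm_result <- function(x, ...) x$table

#' One-row summary of a differential methylation result
#'
#' @param x A `dm_result`.
#' @param ... Unused.
#' @return Tibble with counts and shrinkage hyperparameters.
#' @export
glance.dm_result <- function(x, ...) {
  tibble(n_features = nrow(x$table), n_patients = x$n_patients,
         n_demethylated = sum(x$table$demethylated_call),
         n_remethylated = sum(x$table$remethylated_call),
         prior_df = x$d0, prior_var = x$s0_sq,
         alpha = x$params$alpha, delta_threshold = x$params$delta_threshold)
}

#' Extract a call set from a differential methylation table
#'
#' @param table Tidy `dm_result` table (or any tibble with `cpg_id`,
#'   `adj_p`, `delta_beta`).
#' @param alpha,delta_threshold Strict thresholds.
#' @param direction `"demethylated"` (`delta_beta < -delta_threshold`) or
#'   `"remethylated"` (`delta_beta > +delta_threshold`).
#' @return Character vector of CpG ids.
#' @export
call_demethylated <- function(table, alpha = 0.05, delta_threshold = 0.1,
                              direction = c("demethylated", "remethylated")) {
  direction <- match.arg(direction)
  sel <- if (direction == "demethylated") {
    table$adj_p < alpha & table$delta_beta < -delta_threshold
  } else {
    table$adj_p < alpha & table$delta_beta > delta_threshold
  }
  table$cpg_id[sel]
}

#' Per-patient single-sample delta-beta call sets
#'
#' For each patient with both timepoints, the set of CpGs whose raw
#' per-patient beta difference falls below `-delta_threshold` (or above
#' `+delta_threshold` for `direction = "remethylated"`). Single pairs carry
#' no variance estimate, so no per-patient p-value is computed.
#'
#' @inheritParams diff_methylation
#' @param direction Call direction.
#' @return Named list (patient -> CpG id vector); omitted patients in the
#'   `omitted_patients` attribute.
#' @export
single_sample_delta_sets <- function(beta, sheet, t1 = "d8", t0 = "d0",
                                     cycle = 1, cell_type = "blast",
                                     delta_threshold = 0.1,
                                     direction = c("demethylated", "remethylated")) {
  direction <- match.arg(direction)
  design <- paired_design(sheet, t1 = t1, t0 = t0, cycle = cycle,
                          cell_type = cell_type)
  if (nrow(design) == 0) abort("no patients with both timepoints")
  d <- paired_differences(beta, design)
  sets <- lapply(seq_len(ncol(d)), function(j) {
    sel <- if (direction == "demethylated") d[, j] < -delta_threshold
           else d[, j] > delta_threshold
    rownames(d)[sel]
  })
  names(sets) <- colnames(d)
  attr(sets, "omitted_patients") <- attr(design, "omitted_patients")
  sets
}

#' Classify per-patient demethylation magnitude
#'
#' Bins demethylated-CpG counts into strong (`> strong_threshold`), limited
#' (`< limited_threshold`) and intermediate responses. Defaults are the
#' full-array cutoffs (100,000 and 25,000 CpGs); scale them for smaller
#' universes.
#'
#' @param count Vector of demethylated CpG counts.
#' @param strong_threshold,limited_threshold Strict cutoffs.
#' @return Character vector in `{"strong", "intermediate", "limited"}`.
#' @export
classify_demethylation_magnitude <- function(count, strong_threshold = 100000,
                                             limited_threshold = 25000) {
  stopifnot(all(count >= 0))
  ifelse(count > strong_threshold, "strong",
         ifelse(count < limited_threshold, "limited", "intermediate"))
}

#' Per-timepoint median methylation
#'
#' Median beta over all CpG-by-sample values at each timepoint of the given
#' cell type and cycle.
#'
#' @param beta Beta tibble.
#' @param sheet Sample sheet.
#' @param cell_type,cycle Sample subset summarised.
#' @return Tibble with `timepoint`, `n_samples`, `median_beta`.
#' @export
cohort_methylation_summary <- function(beta, sheet, cell_type = "blast",
                                       cycle = 1) {
  validate_sample_sheet(sheet)
  sub <- sheet %>% filter(.data$cell_type == !!cell_type, .data$cycle == !!cycle)
  if (nrow(sub) == 0) abort("no samples for the requested cell type and cycle")
  m <- as_feature_matrix(beta)
  tps <- intersect(TIMEPOINTS, unique(sub$timepoint))
  dplyr::bind_rows(lapply(tps, function(tp) {
    cols <- intersect(sub$sample_id[sub$timepoint == tp], colnames(m))
    tibble(timepoint = tp, n_samples = length(cols),
           median_beta = median(m[, cols, drop = FALSE]))
  }))
}

#' Demethylation call rate stratified by baseline methylation
#'
#' Splits CpGs by their mean day-0 beta into bins (default \[0, 0.5\] and
#' (0.5, 1\]) and reports the fraction of called CpGs per bin; heavily
#' methylated CpGs are expected to be the most affected.
#'
#' @param beta Beta tibble.
#' @param sheet Sample sheet.
#' @param calls Character vector of called CpG ids.
#' @param breaks Bin breaks on baseline beta.
#' @param cell_type,cycle Samples used for the baseline mean.
#' @return Tibble with `baseline_bin`, `n_cpgs`, `n_called`, `call_rate`.
#' @export
demethylation_rate_by_baseline <- function(beta, sheet, calls,
                                           breaks = c(0, 0.5, 1),
                                           cell_type = "blast", cycle = 1) {
  validate_sample_sheet(sheet)
  sub <- sheet %>% filter(.data$cell_type == !!cell_type,
                          .data$cycle == !!cycle, .data$timepoint == "d0")
  m <- as_feature_matrix(beta)
  cols <- intersect(sub$sample_id, colnames(m))
  if (!length(cols)) abort("no day-0 samples to compute the baseline")
  baseline <- rowMeans(m[, cols, drop = FALSE])
  bin <- cut(baseline, breaks = breaks, include.lowest = TRUE)
  called <- rownames(m) %in% calls
  tibble(baseline_bin = levels(bin)) %>%
    mutate(n_cpgs = as.integer(table(bin)[.data$baseline_bin]),
           n_called = vapply(.data$baseline_bin,
                             function(b) sum(called[!is.na(bin) & bin == b]),
                             integer(1)),
           call_rate = ifelse(.data$n_cpgs > 0,
                              .data$n_called / .data$n_cpgs, NA_real_))
}
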