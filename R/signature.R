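# Non-randomness testing of common demethylation: the 1000-random-set
# resampling null, cycle concordance, per-sample Fisher signature
# enrichment, and the responder 80/20 screen.

#' Commonly demethylated CpG set
#'
#' CpGs present in at least `min_fraction` of the per-patient call sets and
#' (optionally) in the group-wise significant set. `min_fraction = 1`
#' reproduces "demethylated in all patients".
#'
#' @param per_patient_sets Named list (patient -> CpG id vector).
#' @param groupwise_significant Optional CpG id vector the common set is
#'   intersected with.
#' @param min_fraction Minimum fraction of patients calling a CpG.
#' @return Sorted character vector of CpG ids.
#' @export
common_demethylated_set <- function(per_patient_sets,
                                    groupwise_significant = NULL,
                                    min_fraction = 1) {
  if (!length(per_patient_sets)) abort("per_patient_sets is empty")
  counts <- table(unlist(lapply(per_patient_sets, unique)))
  need <- min_fraction * length(per_patient_sets)
  common <- names(counts)[counts >= need]
  if (!is.null(groupwise_significant)) {
    common <- intersect(common, groupwise_significant)
  }
  sort(common)
}

#' Random-CpG-set resampling null for the common count
#'
#' Per iteration, draws for each patient a uniform random CpG subset of that
#' patient's observed call-set size (without replacement) from the universe
#' and records the size of the across-patient intersection. This preserves
#' each patient's call burden while destroying any shared structure. The
#' `"single_set"` variant ignores per-patient burden and draws every
#' patient's set at the mean size.
#'
#' @param set_sizes Named integer vector (patient -> observed set size).
#' @param universe_size Number of CpGs in the universe.
#' @param n_iterations Number of random draws. Default 1000.
#' @param seed RNG seed.
#' @param mode `"per_patient"` (default, size-matched) or `"single_set"`.
#' @param universe_indices Optional list (same order as `set_sizes`) of
#'   integer vectors: the subset of the universe each patient's random set
#'   is drawn from. Used when calls are only possible among a
#'   patient-specific candidate set (e.g. rebound among that patient's
#'   demethylated CpGs).
#' @return Integer vector of null intersection counts.
#' @export
random_set_null <- function(set_sizes, universe_size, n_iterations = 1000,
                            seed = 1L, mode = c("per_patient", "single_set"),
                            universe_indices = NULL) {
  mode <- match.arg(mode)
  sizes <- as.integer(set_sizes)
  pool_sizes <- if (is.null(universe_indices)) {
    rep(universe_size, length(sizes))
  } else {
    stopifnot(length(universe_indices) == length(sizes))
    lengths(universe_indices)
  }
  if (any(sizes > pool_sizes)) {
    abort("a patient's set size exceeds the universe size")
  }
  if (mode == "single_set") sizes <- pmin(pool_sizes,
                                          as.integer(round(mean(sizes))))
  k <- length(sizes)
  set.seed(as.integer(seed))
  counts <- integer(n_iterations)
  for (it in seq_len(n_iterations)) {
    hits <- integer(universe_size)
    for (j in seq_len(k)) {
      idx <- if (is.null(universe_indices)) {
        sample.int(universe_size, sizes[j])
      } else {
        universe_indices[[j]][sample.int(pool_sizes[j], sizes[j])]
      }
      hits[idx] <- hits[idx] + 1L
    }
    counts[it] <- sum(hits == k)
  }
  counts
}

#' Upper-tail normal p-value against a resampled null
#'
#' Fits a normal to the null counts and returns the upper-tail probability
#' of the observed count, `1 - Phi((obs - mean) / sd)`. The parametric tail
#' is what makes p-values far below 1/iterations representable. A
#' zero-variance null degenerates to p = 0 (observed above the mean) or 1,
#' with `degenerate = TRUE`.
#'
#' @param observed Observed common count.
#' @param null_counts Integer vector of null counts.
#' @return List with `p_tail`, `z`, `null_mean`, `null_sd`, `degenerate`.
#' @export
normal_tail_p <- function(observed, null_counts) {
  if (!length(null_counts)) abort("null_counts is empty")
  mu <- mean(null_counts)
  sdev <- sd(null_counts)
  if (!is.finite(sdev) || sdev == 0) {
    return(list(p_tail = if (observed > mu) 0 else 1, z = NA_real_,
                null_mean = mu, null_sd = 0, degenerate = TRUE))
  }
  z <- (observed - mu) / sdev
  list(p_tail = pnorm(z, lower.tail = FALSE), z = z, null_mean = mu,
       null_sd = sdev, degenerate = FALSE)
}

#' Test a common demethylation set against the resampling null
#'
#' Convenience wrapper: forms the common set, draws the size-matched random
#' null, and computes the parametric upper-tail p.
#'
#' @inheritParams common_demethylated_set
#' @param universe Character vector of universe CpG ids.
#' @param per_patient_universes Optional named list (patient -> CpG ids):
#'   the candidate pool each patient's random set is drawn from instead of
#'   the whole universe.
#' @inheritParams random_set_null
#' @return A `signature_null` object; see [tidy.signature_null()],
#'   [glance.signature_null()], [autoplot.signature_null()].
#' @export
signature_null_test <- function(per_patient_sets, universe,
                                groupwise_significant = NULL,
                                min_fraction = 1, n_iterations = 1000,
                                seed = 1L, mode = c("per_patient", "single_set"),
                                per_patient_universes = NULL) {
  mode <- match.arg(mode)
  sets <- lapply(per_patient_sets, intersect, y = universe)
  common <- common_demethylated_set(sets, groupwise_significant, min_fraction)
  sizes <- vapply(sets, length, integer(1))
  universe_indices <- if (!is.null(per_patient_universes)) {
    missing <- setdiff(names(sets), names(per_patient_universes))
    if (length(missing)) {
      abort(sprintf("no per-patient universe for patient '%s'", missing[1]))
    }
    lapply(names(sets), function(p) {
      idx <- match(intersect(per_patient_universes[[p]], universe), universe)
      if (!length(idx)) abort(sprintf("empty universe for patient '%s'", p))
      idx
    })
  } else NULL
  null_counts <- random_set_null(sizes, length(universe),
                                 n_iterations = n_iterations, seed = seed,
                                 mode = mode,
                                 universe_indices = universe_indices)
  tail <- normal_tail_p(length(common), null_counts)
  structure(list(observed_common_count = length(common),
                 signature_cpg_ids = common,
                 null_counts = null_counts,
                 null_mean = tail$null_mean, null_sd = tail$null_sd,
                 z = tail$z, p_tail = tail$p_tail,
                 degenerate = tail$degenerate,
                 set_sizes = sizes, n_iterations = n_iterations,
                 seed = as.integer(seed), mode = mode),
            class = "signature_null")
}

#' @export
print.signature_null <- function(x, ...) {
  cat(sprintf("Random-set null (%d iterations, %d patients, mode %s)\n",
              x$n_iterations, length(x$set_sizes), x$mode))
  cat(sprintf("  observed common count %d vs null %.2f +/- %.2f; upper-tail p = %.3g%s\n",
              x$observed_common_count, x$null_mean, x$null_sd, x$p_tail,
              if (x$degenerate) " (degenerate null)" else ""))
  invisible(x)
}

#' Tidy the null counts of a resampling test
#'
#' @param x A `signature_null`.
#' @param ... Unused.
#' @return Tibble with `iteration`, `null_count`.
#' @export
tidy.signature_null <- function(x, ...) {
  tibble(iteration = seq_along(x$null_counts), null_count = x$null_counts)
}

#' One-row summary of a resampling test
#'
#' @param x A `signature_null`.
#' @param ... Unused.
#' @return Tibble with the observed count, null moments and tail p.
#' @export
glance.signature_null <- function(x, ...) {
  tibble(observed_common_count = x$observed_common_count,
         null_mean = x$null_mean, null_sd = x$null_sd, z = x$z,
         p_tail = x$p_tail, degenerate = x$degenerate,
         n_iterations = x$n_iterations, n_patients = length(x$set_sizes))
}

#' Overlap between two cycles' demethylated sets
#'
#' @param set_cycle1,set_cycle2 CpG id vectors.
#' @return List with `intersection`, `n_cycle1`, `n_cycle2`, `n_common`,
#'   `fraction_recurrent` (share of cycle 1 recurring in cycle 2).
#' @export
cycle_overlap <- function(set_cycle1, set_cycle2) {
  inter <- intersect(set_cycle1, set_cycle2)
  list(intersection = sort(inter),
       n_cycle1 = length(unique(set_cycle1)),
       n_cycle2 = length(unique(set_cycle2)),
       n_common = length(inter),
       fraction_recurrent = if (length(set_cycle1))
         length(inter) / length(unique(set_cycle1)) else NA_real_)
}

#' One-sided Fisher's exact test (over-representation)
#'
#' Upper-tail hypergeometric p-value `P(X >= x11)` for a 2x2 table with
#' fixed margins, with the conditional odds-ratio estimate (via
#' `stats::fisher.test`).
#'
#' @param table 2x2 matrix of non-negative integer counts; `table[1, 1]`
#'   is the in-signature-and-called cell.
#' @return Tibble with `odds_ratio`, `p`.
#' @export
fisher_exact_upper <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    abort("fisher_exact_upper requires non-negative integer counts")
  }
  ft <- fisher.test(table, alternative = "greater")
  tibble(odds_ratio = unname(ft$estimate), p = min(1, ft$p.value))
}

#' Per-patient Fisher enrichment of a signature among called CpGs
#'
#' For each patient, classifies every universe CpG by signature membership
#' and by presence in the patient's call set, and tests over-representation
#' one-sided. Also reports the two percentages conventionally plotted:
#' percent of the universe called, and percent of the signature called.
#'
#' @param signature CpG id vector, a subset of `universe`.
#' @param per_patient_sets Named list (patient -> called CpG ids).
#' @param universe Universe CpG id vector.
#' @return Tibble with one row per patient: counts, percentages,
#'   `odds_ratio`, `p`, significance `stars`, and an `empty_call` flag.
#' @export
signature_enrichment_per_sample <- function(signature, per_patient_sets,
                                            universe) {
  if (length(setdiff(signature, universe))) {
    abort("signature must be a subset of the universe")
  }
  n_u <- length(universe)
  n_sig <- length(signature)
  dplyr::bind_rows(lapply(names(per_patient_sets), function(p) {
    called <- intersect(per_patient_sets[[p]], universe)
    a <- length(intersect(signature, called))
    b <- n_sig - a
    cc <- length(called) - a
    d <- n_u - n_sig - cc
    ft <- fisher_exact_upper(matrix(c(a, cc, b, d), 2))
    p_val <- if (length(called) == 0) 1 else ft$p
    tibble(patient_id = p, n_called = length(called),
           n_signature_called = a,
           pct_universe_called = 100 * length(called) / n_u,
           pct_signature_called = if (n_sig > 0) 100 * a / n_sig else 0,
           odds_ratio = ft$odds_ratio, p = p_val,
           stars = if (p_val < 0.001) "***" else if (p_val < 0.01) "**"
                   else if (p_val < 0.05) "*" else "",
           empty_call = length(called) == 0)
  }))
}

#' Responder 80/20 screen
#'
#' CpGs demethylated in at least `hi` of clinical responders and at most
#' `lo` of non-responders (inclusive bounds).
#'
#' @param per_patient_sets Named list (patient -> called CpG ids).
#' @param groups Named character vector (patient -> `"responder"` /
#'   `"nonresponder"`); patients with other labels are dropped.
#' @param hi,lo Inclusive fraction bounds. Defaults 0.8 and 0.2.
#' @return Tibble with `cpg_id`, `frac_responders`, `frac_nonresponders`,
#'   `selected` over the union of all called CpGs.
#' @export
responder_screen <- function(per_patient_sets, groups, hi = 0.8, lo = 0.2) {
  groups <- groups[names(groups) %in% names(per_patient_sets)]
  resp <- names(groups)[groups == "responder"]
  nonresp <- names(groups)[groups == "nonresponder"]
  if (!length(resp) || !length(nonresp)) {
    abort("both responder and non-responder groups must be non-empty")
  }
  all_cpgs <- sort(unique(unlist(per_patient_sets[c(resp, nonresp)])))
  if (!length(all_cpgs)) {
    return(tibble(cpg_id = character(), frac_responders = numeric(),
                  frac_nonresponders = numeric(), selected = logical()))
  }
  frac_in <- function(patients) {
    counts <- table(factor(unlist(lapply(per_patient_sets[patients], unique)),
                           levels = all_cpgs))
    as.numeric(counts) / length(patients)
  }
  fr <- frac_in(resp)
  fn <- frac_in(nonresp)
  tibble(cpg_id = all_cpgs, frac_responders = fr, frac_nonresponders = fn,
         selected = fr >= hi & fn <= lo)
}
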