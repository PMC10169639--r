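# Orchestration: full analysis from one config (simulated or on-disk data),
# with a machine-readable manifest and deterministic outputs.

#' Remethylation analysis (day 15 vs day 8)
#'
#' Quantifies how much of the day-8 demethylation rebounds by day 15 and
#' whether the rebound is random across patients. In `"single_sample"` mode
#' (default) each patient's remethylated set is the part of that patient's
#' own day-8 demethylated set whose per-patient beta difference (d15 - d8)
#' exceeds `+delta_threshold`, and the reported fraction pools patients. In
#' `"groupwise"` mode the remethylated set is the group-wise significant
#' positive call (d15 vs d8) intersected with a supplied group-wise day-8
#' set. Either way the per-patient remethylated sets are tested against the
#' size-matched random-set null, with each patient's random sets drawn from
#' that patient's own day-8 demethylated CpGs — rebound is only possible
#' where demethylation happened, so the null must condition on the day-8
#' sets or shared day-8 structure masquerades as non-random remethylation.
#'
#' The default rebound threshold is half the demethylation call threshold:
#' a partial rebound of a CpG whose total day-8 deficit is barely above 0.1
#' can never reach +0.1, so a full-sized threshold systematically
#' under-counts partial remethylation. Because a lenient threshold also
#' admits measurement-noise crossings, the reported
#' `fraction_remethylated` subtracts an empirical noise floor: read noise
#' is symmetric, so the rate of opposite-direction crossings
#' (`d15 - d8 < -threshold`) within the same day-8 sets estimates the
#' false-rebound rate. The uncorrected rate is kept as `fraction_called`.
#'
#' @param beta Filtered beta tibble.
#' @param sheet Sample sheet.
#' @param d8_sets For `"single_sample"`: named list of per-patient day-8
#'   demethylated CpG sets. For `"groupwise"`: a single CpG id vector.
#' @param mode `"single_sample"` or `"groupwise"`.
#' @param delta_threshold Per-patient (or group) delta-beta threshold for a
#'   partial-rebound call. Default 0.05.
#' @param alpha BH threshold for the groupwise caller.
#' @param cycle,cell_type Sample subset analysed.
#' @param n_iterations,seed Random-set null parameters.
#' @return List of class `remeth_result`: `per_patient_remethylated`,
#'   `remethylated` (union / group set), `fraction_remethylated`, `null`
#'   (a `signature_null`), `mode`.
#' @export
remethylation_analysis <- function(beta, sheet, d8_sets,
                                   mode = c("single_sample", "groupwise"),
                                   delta_threshold = 0.05, alpha = 0.05,
                                   cycle = 1, cell_type = "blast",
                                   n_iterations = 1000, seed = 1L) {
  mode <- match.arg(mode)
  if (!length(d8_sets) || (mode == "groupwise" && !length(d8_sets))) {
    abort("d8_sets is empty")
  }
  universe <- id_column(beta)
  re_sets <- single_sample_delta_sets(beta, sheet, t1 = "d15", t0 = "d8",
                                      cycle = cycle, cell_type = cell_type,
                                      delta_threshold = delta_threshold,
                                      direction = "remethylated")
  if (mode == "single_sample") {
    if (is.null(names(d8_sets))) abort("single_sample mode needs per-patient d8 sets")
    shared <- intersect(names(re_sets), names(d8_sets))
    if (!length(shared)) abort("no patients shared between d8 sets and d15/d8 pairs")
    per_patient <- lapply(shared, function(p) intersect(re_sets[[p]], d8_sets[[p]]))
    names(per_patient) <- shared
    n_d8 <- sum(lengths(d8_sets[shared]))
    if (n_d8 == 0) abort("d8 demethylated sets are empty")
    fraction_called <- sum(lengths(per_patient)) / n_d8
    # symmetric-noise floor: opposite-direction crossings in the same sets
    mirror_sets <- single_sample_delta_sets(beta, sheet, t1 = "d15", t0 = "d8",
                                            cycle = cycle,
                                            cell_type = cell_type,
                                            delta_threshold = delta_threshold,
                                            direction = "demethylated")
    noise_floor <- sum(vapply(shared, function(p) {
      length(intersect(mirror_sets[[p]], d8_sets[[p]]))
    }, integer(1))) / n_d8
    fraction <- max(0, fraction_called - noise_floor)
    remethylated <- sort(unique(unlist(per_patient)))
  } else {
    dm <- diff_methylation(beta, sheet, t1 = "d15", t0 = "d8", cycle = cycle,
                           cell_type = cell_type, alpha = alpha,
                           delta_threshold = delta_threshold)
    group_re <- call_demethylated(dm$table, alpha = alpha,
                                  delta_threshold = delta_threshold,
                                  direction = "remethylated")
    remethylated <- intersect(group_re, d8_sets)
    fraction <- length(remethylated) / length(d8_sets)
    fraction_called <- fraction
    per_patient <- lapply(re_sets, intersect, y = d8_sets)
  }
  pools <- if (mode == "single_sample") {
    d8_sets[names(per_patient)]
  } else {
    setNames(rep(list(d8_sets), length(per_patient)), names(per_patient))
  }
  null <- signature_null_test(per_patient, universe,
                              n_iterations = n_iterations, seed = seed,
                              per_patient_universes = pools)
  structure(list(per_patient_remethylated = per_patient,
                 remethylated = remethylated,
                 fraction_remethylated = fraction,
                 fraction_called = fraction_called,
                 null = null, mode = mode,
                 delta_threshold = delta_threshold),
            class = "remeth_result")
}

#' @export
print.remeth_result <- function(x, ...) {
  cat(sprintf("Remethylation (d15 vs d8, %s mode): %.1f%% of day-8 demethylation rebounds (> +%g)\n",
              x$mode, 100 * x$fraction_remethylated, x$delta_threshold))
  cat(sprintf("  random-set null p = %.3g\n", x$null$p_tail))
  invisible(x)
}

default_pipeline_config <- function() {
  list(alpha = 0.05, delta = 0.1, epsilon = 0.001, iterations = 1000,
       remeth_mode = "single_sample", partial_delta = 0.05,
       min_fraction = 1, magnitude_reference = 456281)
}

#' Run the full demethylation analysis pipeline
#'
#' Executes: data (simulate or load) -> CpG filtering -> group-wise
#' differential methylation (d8 vs d0, d15 vs d0) -> per-patient
#' single-sample sets and magnitude classes -> common-set random-set null ->
#' remethylation (d15 vs d8) -> cycle-2 concordance and per-sample signature
#' enrichment -> T-cell contrast -> responder screen -> expression
#' integration -> genomic-context enrichment. Stages whose samples are
#' absent are skipped and logged. Each result table is written as TSV with a
#' provenance comment; a `manifest.json` records version, seed, parameters
#' and per-stage row counts. Identical config and seed give byte-identical
#' outputs.
#'
#' @param config Either a list (or YAML file path) with optional elements
#'   `simulate` (arguments to [cohort_config()], or `TRUE` for defaults),
#'   `paths` (named `beta`, `sheet`, `annot`, optionally `expression`,
#'   `tcell_beta`), and `thresholds` overriding `alpha`, `delta`,
#'   `epsilon`, `iterations`, `remeth_mode`, `partial_delta`,
#'   `min_fraction`.
#' @param out_dir Output directory.
#' @param seed Master seed for every stochastic stage.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = list(simulate = TRUE), out_dir, seed = 1L) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  th <- modifyList(default_pipeline_config(), config$thresholds %||% list())
  partial_delta <- th$partial_delta %||% th$delta
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  note <- function(stage, status, n = NA_integer_) {
    message(sprintf("[demkin] stage %-14s %s", stage, status))
    stages[[stage]] <<- list(stage = stage, status = status, n_rows = n)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      note(stage, paste("failed:", conditionMessage(e)))
      write_manifest()
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }
  write_manifest <- function() {
    manifest <- list(
      tool = "demkin",
      version = as.character(utils::packageVersion("demkin")),
      seed = seed, thresholds = th,
      stages = dplyr::bind_rows(lapply(stages, tibble::as_tibble)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out_tsv <- function(tbl, name, params = list()) {
    write_result_table(tbl, file.path(out_dir, name), seed = seed,
                       params = params)
  }
  results <- list()

  ## data ---------------------------------------------------------------
  run_stage("data", {
    if (!is.null(config$simulate)) {
      args <- if (isTRUE(config$simulate)) list() else config$simulate
      cohort <- simulate_cohort(do.call(cohort_config, args), seed = seed)
      results$cohort <- cohort
      beta_blast <- cohort$beta_blast
      beta_tcell <- cohort$beta_tcell
      expression <- cohort$expression
      sheet <- cohort$sheet
      annot <- cohort$annot
    } else {
      ds <- load_dataset(config$paths$beta, config$paths$sheet,
                         config$paths$annot)
      beta_blast <- ds$beta
      sheet <- ds$sheet
      annot <- ds$annot
      expression <- if (!is.null(config$paths$expression))
        read_expression_matrix(config$paths$expression) else NULL
      beta_tcell <- if (!is.null(config$paths$tcell_beta))
        read_beta_matrix(config$paths$tcell_beta) else NULL
    }
    note("data", "completed", nrow(beta_blast))
  })

  ## filter -------------------------------------------------------------
  run_stage("filter", {
    beta_blast <- filter_cpgs(beta_blast, annot)
    if (!is.null(beta_tcell)) beta_tcell <- filter_cpgs(beta_tcell, annot)
    note("filter", "completed", nrow(beta_blast))
  })
  universe <- id_column(beta_blast)
  results$universe <- universe

  ## group-wise differential methylation --------------------------------
  run_stage("diffmeth_d8", {
    dm8 <- diff_methylation(beta_blast, sheet, "d8", "d0", cycle = 1,
                            cell_type = "blast", alpha = th$alpha,
                            delta_threshold = th$delta, epsilon = th$epsilon)
    results$dm_d8 <- dm8
    out_tsv(dm8$table, "diffmeth_d8_vs_d0.tsv",
            list(contrast = "d8:d0", cycle = 1, alpha = th$alpha,
                 delta = th$delta))
    note("diffmeth_d8", "completed", nrow(dm8$table))
  })
  demeth_group <- call_demethylated(results$dm_d8$table, th$alpha, th$delta)

  has_d15 <- nrow(paired_design(sheet, "d15", "d0", 1, "blast")) >= 2
  if (has_d15) {
    run_stage("diffmeth_d15", {
      dm15 <- diff_methylation(beta_blast, sheet, "d15", "d0", cycle = 1,
                               cell_type = "blast", alpha = th$alpha,
                               delta_threshold = th$delta,
                               epsilon = th$epsilon)
      results$dm_d15 <- dm15
      out_tsv(dm15$table, "diffmeth_d15_vs_d0.tsv",
              list(contrast = "d15:d0", cycle = 1))
      note("diffmeth_d15", "completed", nrow(dm15$table))
    })
  } else note("diffmeth_d15", "skipped: no day-15 samples")

  ## single-sample sets and magnitudes -----------------------------------
  run_stage("single_sample", {
    ss <- single_sample_delta_sets(beta_blast, sheet, "d8", "d0", 1, "blast",
                                   delta_threshold = th$delta)
    results$single_sample_d8 <- ss
    scale_f <- length(universe) / th$magnitude_reference
    counts <- tibble(patient_id = names(ss),
                     n_demethylated = lengths(ss),
                     magnitude = classify_demethylation_magnitude(
                       lengths(ss), 100000 * scale_f, 25000 * scale_f))
    results$magnitudes <- counts
    out_tsv(counts, "single_sample_d8.tsv", list(delta = th$delta))
    note("single_sample", "completed", nrow(counts))
  })

  ## common set vs random null -------------------------------------------
  run_stage("signature", {
    sig <- signature_null_test(results$single_sample_d8, universe,
                               groupwise_significant = demeth_group,
                               min_fraction = th$min_fraction,
                               n_iterations = th$iterations,
                               seed = sub_seed(seed, 11L))
    results$signature <- sig
    out_tsv(tibble(cpg_id = sig$signature_cpg_ids), "signature_cpgs.tsv",
            list(iterations = th$iterations))
    out_tsv(tidy(sig), "signature_null_counts.tsv",
            list(iterations = th$iterations))
    out_tsv(glance(sig), "signature_summary.tsv", list())
    note("signature", "completed", sig$observed_common_count)
  })

  ## remethylation -------------------------------------------------------
  if (has_d15) {
    run_stage("remethylation", {
      re <- remethylation_analysis(
        beta_blast, sheet,
        d8_sets = if (th$remeth_mode == "single_sample")
          results$single_sample_d8 else demeth_group,
        mode = th$remeth_mode, delta_threshold = partial_delta,
        alpha = th$alpha, n_iterations = th$iterations,
        seed = sub_seed(seed, 12L))
      results$remethylation <- re
      out_tsv(tibble(fraction_remethylated = re$fraction_remethylated,
                     fraction_called = re$fraction_called,
                     n_remethylated = length(re$remethylated),
                     null_p = re$null$p_tail, mode = re$mode),
              "remethylation_summary.tsv", list(partial_delta = partial_delta))
      note("remethylation", "completed", length(re$remethylated))
    })
  } else note("remethylation", "skipped: no day-15 samples")

  ## cycle-2 concordance -------------------------------------------------
  has_c2 <- nrow(paired_design(sheet, "d8", "d0", 2, "blast")) >= 2
  if (has_c2) {
    run_stage("cycle2", {
      dm_c2 <- diff_methylation(beta_blast, sheet, "d8", "d0", cycle = 2,
                                cell_type = "blast", alpha = th$alpha,
                                delta_threshold = th$delta,
                                epsilon = th$epsilon)
      results$dm_c2 <- dm_c2
      c2_group <- call_demethylated(dm_c2$table, th$alpha, th$delta)
      ov <- cycle_overlap(demeth_group, c2_group)
      results$cycle_overlap <- ov
      ss_c2 <- single_sample_delta_sets(beta_blast, sheet, "d8", "d0", 2,
                                        "blast", delta_threshold = th$delta)
      results$single_sample_c2 <- ss_c2
      # recurrence of the cycle-1 signature among CpGs demethylated in all
      # cycle-2 patients (same per-patient construction as the signature)
      c2_common <- common_demethylated_set(ss_c2, min_fraction = th$min_fraction)
      sig_rec <- cycle_overlap(results$signature$signature_cpg_ids, c2_common)
      results$signature_recurrence <- sig_rec
      enr <- signature_enrichment_per_sample(
        results$signature$signature_cpg_ids, ss_c2, universe)
      results$cycle2_enrichment <- enr
      out_tsv(enr, "cycle2_signature_enrichment.tsv", list())
      out_tsv(tibble(n_cycle1 = ov$n_cycle1, n_cycle2 = ov$n_cycle2,
                     n_common = ov$n_common,
                     fraction_recurrent = ov$fraction_recurrent,
                     signature_recurrence = sig_rec$fraction_recurrent),
              "cycle_concordance.tsv", list())
      note("cycle2", "completed", ov$n_common)
    })
  } else note("cycle2", "skipped: no cycle-2 samples")

  ## T-cell contrast -----------------------------------------------------
  has_tcell <- !is.null(beta_tcell) &&
    nrow(paired_design(sheet, "d8", "d0", 1, "tcell")) >= 2
  if (has_tcell) {
    run_stage("tcell", {
      ss_t <- single_sample_delta_sets(beta_tcell, sheet, "d8", "d0", 1,
                                       "tcell", delta_threshold = th$delta)
      results$single_sample_tcell <- ss_t
      dm_t <- diff_methylation(beta_tcell, sheet, "d8", "d0", cycle = 1,
                               cell_type = "tcell", alpha = th$alpha,
                               delta_threshold = th$delta,
                               epsilon = th$epsilon)
      results$dm_tcell <- dm_t
      t_group <- call_demethylated(dm_t$table, th$alpha, th$delta)
      sig_t <- signature_null_test(ss_t, id_column(beta_tcell),
                                   groupwise_significant = t_group,
                                   min_fraction = th$min_fraction,
                                   n_iterations = th$iterations,
                                   seed = sub_seed(seed, 13L))
      results$tcell_signature <- sig_t
      out_tsv(glance(sig_t), "tcell_signature_summary.tsv", list())
      note("tcell", "completed", sig_t$observed_common_count)
    })
  } else note("tcell", "skipped: no T-cell samples")

  ## responder screen ----------------------------------------------------
  run_stage("responder", {
    groups <- setNames(sheet$response_group, sheet$patient_id)
    groups <- groups[!duplicated(names(groups))]
    known <- groups[groups %in% c("responder", "nonresponder")]
    if (length(unique(known)) == 2) {
      rs <- responder_screen(results$single_sample_d8, known)
      results$responder_screen <- rs
      out_tsv(rs[rs$selected, , drop = FALSE], "responder_screen.tsv",
              list(hi = 0.8, lo = 0.2))
      note("responder", "completed", sum(rs$selected))
    } else note("responder", "skipped: need both response groups")
  })

  ## expression integration ----------------------------------------------
  if (!is.null(expression)) {
    run_stage("integration", {
      design <- paired_design(sheet, "d8", "d0", 1, "blast")
      design <- design[design$sample_t1 %in% sample_columns(expression) &
                         design$sample_t0 %in% sample_columns(expression), ]
      deg <- paired_deg(expression, design, alpha = th$alpha)
      results$deg <- deg
      rb <- gene_region_beta(beta_blast, annot)
      screen <- anti_correlation_screen(rb, deg, design, alpha = th$alpha)
      results$screen <- screen
      out_tsv(deg$table, "deg_d8_vs_d0.tsv", list(alpha = th$alpha))
      out_tsv(dplyr::select(tibble::as_tibble(screen), -"pairs"),
              "anticorrelation_screen.tsv", list(alpha = th$alpha))
      note("integration", "completed",
           sum(screen$anti_correlated_call, na.rm = TRUE))
    })
  } else note("integration", "skipped: no expression data")

  ## context enrichment --------------------------------------------------
  run_stage("context", {
    ce <- context_enrichment(results$signature$signature_cpg_ids, universe,
                             annot)
    results$context <- ce
    out_tsv(ce, "context_enrichment.tsv", list())
    note("context", "completed", nrow(ce))
  })

  write_manifest()
  results$manifest <- stages
  invisible(results)
}
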