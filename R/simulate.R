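# Synthetic cohort generator. Emulates the statistical structure of a serial
# decitabine methylome/transcriptome study at desk scale: two-mode baseline
# methylation, patient-specific global demethylation at day 8 (heavier
# baselines preferentially hit), a planted commonly-demethylated CpG
# signature shared by all blast patients in both cycles, partial random
# remethylation at day 15, near-null T-cell effects, and a planted set of
# genes whose expression induction tracks promoter demethylation. A ground
# truth record makes every downstream stage testable.

#' Configure a synthetic cohort
#'
#' Returns the generator configuration with study-scale defaults: 20,000
#' CpGs, 2,000 genes, 12 blast patients (days 0/8/15), 8 T-cell patients
#' (days 0/8), 4 patients with a second treatment cycle. Effect sizes are on
#' the beta scale; expression effects are log2 fold changes.
#'
#' @param n_cpgs Total CpGs on the synthetic array (including the small
#'   sex-chromosome/SNP fractions removed by [filter_cpgs()]).
#' @param n_genes Number of genes (each receives promoter and body CpGs).
#' @param n_patients_blast Patients with serial blast samples.
#' @param n_patients_tcell Patients with serial T-cell samples (a subset of
#'   the blast patients).
#' @param n_cycle2_patients Patients with cycle-2 day 0/8 blast samples.
#' @param hyper_fraction Fraction of CpGs in the heavily methylated baseline
#'   mode.
#' @param baseline_modes Means of the two baseline beta modes.
#' @param baseline_concentration Beta-distribution concentration of baseline
#'   means around their mode.
#' @param signature_size Number of planted commonly demethylated CpGs.
#' @param signature_effect Planted signature delta-beta (negative).
#' @param background_rate_range Range of the per-patient fraction of CpGs
#'   hit by background demethylation (drawn uniformly per patient).
#' @param background_effect Background demethylation delta-beta (negative).
#' @param remethylation_fraction Fraction of each patient's day-8
#'   demethylated CpGs that rebound by day 15.
#' @param rebound_range Fraction of the day-8 deficit restored in rebounding
#'   CpGs (uniform draw per CpG).
#' @param tcell_effect_rate Per-patient fraction of CpGs demethylated in
#'   T cells (near zero, no common structure).
#' @param n_anticorr_genes Number of genes with planted
#'   promoter-demethylation/expression-induction coupling.
#' @param anticorr_slope log2 fold change per unit delta-beta (negative:
#'   expression rises as methylation falls).
#' @param anticorr_meth_effect Maximal planted promoter delta-beta (reached
#'   by the most strongly demethylating patient).
#' @param expression_noise_sd Gaussian noise on per-patient log2 fold
#'   changes.
#' @param measurement_noise_concentration Concentration of the beta-
#'   distributed read noise around the latent methylation level.
#' @param sex_cpg_fraction,snp_cpg_fraction Fractions of CpGs placed on
#'   chrX/chrY or flagged as SNP-overlapping (removed by filtering).
#' @param signature_opensea_weight,signature_repeat_weight,signature_intergenic_weight
#'   Multiplicative selection weights enriching the planted signature for
#'   open-sea, repeat-overlapping and intergenic CpGs.
#' @param responder_fraction Fraction of patients labelled clinical
#'   responders (response carries no methylation effect, as observed
#'   in vivo).
#' @param seed Default master seed for [simulate_cohort()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_cpgs = 20000,
                          n_genes = 2000,
                          n_patients_blast = 12,
                          n_patients_tcell = 8,
                          n_cycle2_patients = 4,
                          hyper_fraction = 0.75,
                          baseline_modes = c(hyper = 0.9, hypo = 0.1),
                          baseline_concentration = 50,
                          signature_size = 100,
                          signature_effect = -0.3,
                          background_rate_range = c(0.02, 0.35),
                          background_effect = -0.3,
                          remethylation_fraction = 0.5,
                          rebound_range = c(0.3, 1.0),
                          tcell_effect_rate = 0.003,
                          n_anticorr_genes = 50,
                          anticorr_slope = -4,
                          anticorr_meth_effect = -0.35,
                          expression_noise_sd = 0.3,
                          measurement_noise_concentration = 300,
                          sex_cpg_fraction = 0.02,
                          snp_cpg_fraction = 0.01,
                          signature_opensea_weight = 3,
                          signature_repeat_weight = 3,
                          signature_intergenic_weight = 2,
                          responder_fraction = 0.5,
                          seed = 1L) {
  cfg <- as.list(environment())
  frac_fields <- c("hyper_fraction", "remethylation_fraction",
                   "tcell_effect_rate", "sex_cpg_fraction",
                   "snp_cpg_fraction", "responder_fraction")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || any(v < 0 | v > 1)) {
      abort(sprintf("config field '%s' must be a fraction in [0, 1]", f))
    }
  }
  if (cfg$signature_size > cfg$n_cpgs) {
    abort("signature_size must not exceed n_cpgs")
  }
  if (cfg$n_anticorr_genes > cfg$n_genes) {
    abort("n_anticorr_genes must not exceed n_genes")
  }
  if (cfg$n_patients_tcell > cfg$n_patients_blast ||
      cfg$n_cycle2_patients > cfg$n_patients_blast) {
    abort("T-cell and cycle-2 patient counts must not exceed n_patients_blast")
  }
  n_autosomal <- cfg$n_cpgs - round(cfg$sex_cpg_fraction * cfg$n_cpgs)
  if (2 * cfg$n_genes > round(0.75 * n_autosomal)) {
    abort("n_genes too large for n_cpgs: each gene needs >=2 CpGs")
  }
  if (any(cfg$background_rate_range < 0 | cfg$background_rate_range > 1) ||
      any(cfg$rebound_range < 0 | cfg$rebound_range > 1)) {
    abort("background_rate_range and rebound_range must lie in [0, 1]")
  }
  structure(cfg, class = "cohort_config")
}

clamp01 <- function(x, lo = 0.02, hi = 0.98) pmin(pmax(x, lo), hi)

draw_baseline <- function(n, cfg, mode_means) {
  hyper <- runif(n) < cfg$hyper_fraction
  mode <- ifelse(hyper, mode_means[1], mode_means[2])
  kappa <- cfg$baseline_concentration
  clamp01(rbeta(n, mode * kappa, (1 - mode) * kappa))
}

#' Simulate a serial demethylation cohort
#'
#' Generates blast beta matrices (cycle 1 days 0/8/15 for all patients plus
#' cycle 2 days 0/8 for a subset), T-cell beta matrices (days 0/8), a
#' gene-level log2 expression matrix (days 0/8), the CpG annotation, the
#' sample sheet, and a ground-truth record. Identical config and seed yield
#' bit-identical output.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed; defaults to `config$seed`. One derived RNG
#'   stream is used per logical component (annotation/baseline, blast
#'   effects, remethylation, T cells, read noise, expression).
#' @return A `dac_cohort` list with elements `beta_blast`, `beta_tcell`,
#'   `expression`, `annot`, `sheet`, `truth`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  cfg <- config
  if (!inherits(cfg, "cohort_config")) abort("config must come from cohort_config()")
  seed <- as.integer(seed)

  ## --- component 1: array layout, annotation, baseline methylome ---------
  set.seed(sub_seed(seed, 1L))
  n_sex <- round(cfg$sex_cpg_fraction * cfg$n_cpgs)
  n_auto <- cfg$n_cpgs - n_sex
  n_genic <- round(0.75 * n_auto)
  n_inter <- n_auto - n_genic

  genes <- tibble(
    gene_id = sprintf("g%05d", seq_len(cfg$n_genes)),
    chromosome = paste0("chr", rep_len(1:22, cfg$n_genes))
  )
  genes <- genes %>%
    group_by(.data$chromosome) %>%
    mutate(tss_position = 50000L + 100000L * (row_number() - 1L)) %>%
    ungroup()

  counts <- rep(floor(n_genic / cfg$n_genes), cfg$n_genes)
  extra <- n_genic - sum(counts)
  if (extra > 0) {
    bump <- sample.int(cfg$n_genes, extra)
    counts[bump] <- counts[bump] + 1L
  }

  prom_pool <- c("TSS200", "TSS1500", "5UTR")
  body_pool <- c("1stExon", "ExonBnd", "Body", "3UTR")
  offset_lo <- c(TSS200 = -200L, TSS1500 = -1500L, "5UTR" = 1L,
                 "1stExon" = 1L, ExonBnd = 500L, Body = 500L, "3UTR" = 8000L)
  offset_hi <- c(TSS200 = 0L, TSS1500 = -201L, "5UTR" = 300L,
                 "1stExon" = 500L, ExonBnd = 8000L, Body = 8000L,
                 "3UTR" = 10000L)
  gene_of <- rep(seq_len(cfg$n_genes), counts)
  within <- sequence(counts)
  n_prom_gene <- pmin(counts, 2L + rbinom(cfg$n_genes, pmax(counts - 2L, 0L), 0.15))
  is_prom <- within <= n_prom_gene[gene_of]
  cats <- character(n_genic)
  cats[is_prom] <- sample(prom_pool, sum(is_prom), replace = TRUE,
                          prob = c(0.4, 0.4, 0.2))
  cats[!is_prom] <- sample(body_pool, sum(!is_prom), replace = TRUE,
                           prob = c(0.15, 0.1, 0.55, 0.2))
  cat_str <- cats
  second <- which(runif(n_genic) < 0.08)
  if (length(second)) {
    cat_str[second] <- vapply(second, function(j) {
      pool <- if (is_prom[j]) prom_pool else body_pool
      alt <- sample(setdiff(pool, cats[j]), 1)
      paste(sort(c(cats[j], alt)), collapse = ";")
    }, character(1))
  }
  lo <- offset_lo[cats]
  hi <- offset_hi[cats]
  offs <- lo + as.integer(floor(runif(n_genic) * (hi - lo + 1L)))
  genic <- tibble(
    chromosome = genes$chromosome[gene_of],
    position = genes$tss_position[gene_of] + offs,
    nearest_gene = genes$gene_id[gene_of],
    tss_distance = offs,
    region_categories = cat_str,
    is_promoter = is_prom
  )

  inter_gene <- sample.int(cfg$n_genes, n_inter, replace = TRUE)
  inter_off <- sample(c(-1L, 1L), n_inter, replace = TRUE) *
    sample(25000:45000, n_inter, replace = TRUE)
  inter <- tibble(
    chromosome = genes$chromosome[inter_gene],
    position = genes$tss_position[inter_gene] + inter_off,
    nearest_gene = genes$gene_id[inter_gene],
    tss_distance = inter_off,
    region_categories = "intergenic",
    is_promoter = FALSE
  )

  sex <- if (n_sex > 0) {
    sex_chr <- sample(c("chrX", "chrY"), n_sex, replace = TRUE, prob = c(0.8, 0.2))
    off <- sample(25000:45000, n_sex, replace = TRUE)
    tibble(
      chromosome = sex_chr,
      position = 50000L + off,
      nearest_gene = ifelse(sex_chr == "chrX", "gX0001", "gY0001"),
      tss_distance = off,
      region_categories = "intergenic",
      is_promoter = FALSE
    )
  } else NULL

  annot <- dplyr::bind_rows(genic, inter, sex)
  n_total <- nrow(annot)
  annot$cpg_id <- sprintf("cg%07d", seq_len(n_total))
  annot$island_status <- sample(ISLAND_STATUSES, n_total, replace = TRUE,
                                prob = c(0.31, 0.23, 0.10, 0.36))
  annot$repeat_overlap <- runif(n_total) < 0.15
  autosomal <- !(annot$chromosome %in% c("chrX", "chrY"))
  n_snp <- round(cfg$snp_cpg_fraction * cfg$n_cpgs)
  annot$snp_overlap <- FALSE
  annot$snp_overlap[sample(which(autosomal), min(n_snp, sum(autosomal)))] <- TRUE
  retained <- which(autosomal & !annot$snp_overlap)

  # planted anti-correlated genes: aberrantly hypermethylated promoters
  anticorr_genes <- sort(sample(genes$gene_id, cfg$n_anticorr_genes))
  ac_prom <- which(annot$nearest_gene %in% anticorr_genes & annot$is_promoter)
  ac_prom <- intersect(ac_prom, retained)

  mu <- draw_baseline(n_total, cfg, cfg$baseline_modes)
  mu[ac_prom] <- clamp01(rbeta(length(ac_prom),
                               0.88 * cfg$baseline_concentration,
                               0.12 * cfg$baseline_concentration))

  # planted signature: heavily methylated, open-sea/repeat/intergenic-leaning
  sig_candidates <- setdiff(retained[mu[retained] > 0.5], ac_prom)
  w <- cfg$signature_opensea_weight ^ (annot$island_status[sig_candidates] == "OpenSea") *
    cfg$signature_repeat_weight ^ annot$repeat_overlap[sig_candidates] *
    cfg$signature_intergenic_weight ^ (annot$region_categories[sig_candidates] == "intergenic")
  if (length(sig_candidates) < cfg$signature_size) {
    abort("not enough heavily methylated CpGs to host the signature")
  }
  sig_idx <- sample(sig_candidates, cfg$signature_size, prob = w)
  signature_ids <- sort(annot$cpg_id[sig_idx])

  ## --- component 2: per-patient blast effects ----------------------------
  set.seed(sub_seed(seed, 2L))
  patients <- sprintf("P%02d", seq_len(cfg$n_patients_blast))
  rates <- runif(cfg$n_patients_blast,
                 cfg$background_rate_range[1], cfg$background_rate_range[2])
  names(rates) <- patients
  sens <- runif(cfg$n_anticorr_genes, 0.7, 1.3)
  names(sens) <- anticorr_genes
  max_rate <- max(cfg$background_rate_range)
  bg_candidates <- setdiff(setdiff(retained, sig_idx), ac_prom)
  ac_prom_by_gene <- split(ac_prom, annot$nearest_gene[ac_prom])

  blast_effects <- function(patient_i) {
    r <- rates[patient_i]
    n_bg <- round(r * length(retained))
    bg <- sample(bg_candidates, min(n_bg, length(bg_candidates)),
                 prob = mu[bg_candidates])
    d8 <- mu
    d8[bg] <- d8[bg] + cfg$background_effect
    d8[sig_idx] <- d8[sig_idx] + cfg$signature_effect
    ac_delta <- setNames(
      cfg$anticorr_meth_effect * (r / max_rate) * sens + rnorm(length(sens), 0, 0.03),
      anticorr_genes)
    for (gn in names(ac_prom_by_gene)) {
      idx <- ac_prom_by_gene[[gn]]
      d8[idx] <- d8[idx] + ac_delta[gn] + rnorm(length(idx), 0, 0.02)
    }
    d8 <- clamp01(d8, lo = 0.02, hi = 0.98)
    list(d8 = d8, ac_delta = ac_delta)
  }

  lat_c1 <- lapply(seq_along(patients), blast_effects)
  names(lat_c1) <- patients
  c2_patients <- patients[seq_len(cfg$n_cycle2_patients)]
  lat_c2 <- lapply(match(c2_patients, patients), blast_effects)
  names(lat_c2) <- c2_patients

  truth_demeth <- function(lat) {
    lapply(lat, function(l) annot$cpg_id[retained][(l$d8 - mu)[retained] < -0.1])
  }
  demeth_c1 <- truth_demeth(lat_c1)
  demeth_c2 <- truth_demeth(lat_c2)

  ## --- component 3: day-15 partial remethylation -------------------------
  set.seed(sub_seed(seed, 3L))
  lat_d15 <- list()
  remeth_sets <- list()
  for (p in patients) {
    dem <- match(demeth_c1[[p]], annot$cpg_id)
    n_re <- round(cfg$remethylation_fraction * length(dem))
    re <- if (n_re > 0) sample(dem, n_re) else integer(0)
    d15 <- lat_c1[[p]]$d8
    if (length(re)) {
      d15[re] <- d15[re] + runif(length(re), cfg$rebound_range[1],
                                 cfg$rebound_range[2]) * (mu[re] - d15[re])
    }
    lat_d15[[p]] <- clamp01(d15)
    remeth_sets[[p]] <- sort(annot$cpg_id[re])
  }

  ## --- component 4: T-cell bystander effects -----------------------------
  set.seed(sub_seed(seed, 4L))
  t_patients <- patients[seq_len(cfg$n_patients_tcell)]
  mu_t <- draw_baseline(n_total, cfg, cfg$baseline_modes)
  lat_t <- list()
  demeth_t <- list()
  for (p in t_patients) {
    n_eff <- round(cfg$tcell_effect_rate * length(retained))
    hit <- if (n_eff > 0) sample(retained, n_eff) else integer(0)
    d8 <- mu_t
    d8[hit] <- clamp01(d8[hit] + cfg$background_effect)
    lat_t[[p]] <- d8
    demeth_t[[p]] <- annot$cpg_id[retained][(d8 - mu_t)[retained] < -0.1]
  }

  ## --- component 5: measurement noise ------------------------------------
  set.seed(sub_seed(seed, 5L))
  noise <- function(latent) {
    cc <- cfg$measurement_noise_concentration
    lv <- clamp01(latent)
    rbeta(length(lv), lv * cc, (1 - lv) * cc)
  }
  blast_cols <- list()
  for (p in patients) {
    blast_cols[[paste0(p, "_blast_c1_d0")]] <- noise(mu)
    blast_cols[[paste0(p, "_blast_c1_d8")]] <- noise(lat_c1[[p]]$d8)
    blast_cols[[paste0(p, "_blast_c1_d15")]] <- noise(lat_d15[[p]])
  }
  for (p in c2_patients) {
    blast_cols[[paste0(p, "_blast_c2_d0")]] <- noise(mu)
    blast_cols[[paste0(p, "_blast_c2_d8")]] <- noise(lat_c2[[p]]$d8)
  }
  tcell_cols <- list()
  for (p in t_patients) {
    tcell_cols[[paste0(p, "_tcell_c1_d0")]] <- noise(mu_t)
    tcell_cols[[paste0(p, "_tcell_c1_d8")]] <- noise(lat_t[[p]])
  }
  beta_blast <- tibble::as_tibble(c(list(cpg_id = annot$cpg_id), blast_cols))
  beta_tcell <- tibble::as_tibble(c(list(cpg_id = annot$cpg_id), tcell_cols))

  ## --- component 6: expression -------------------------------------------
  set.seed(sub_seed(seed, 6L))
  base_expr <- rnorm(cfg$n_genes, 7, 1.5)
  names(base_expr) <- genes$gene_id
  expr_cols <- list()
  for (p in patients) {
    d0 <- base_expr + rnorm(cfg$n_genes, 0, 0.05)
    fc <- rnorm(cfg$n_genes, 0, cfg$expression_noise_sd)
    names(fc) <- genes$gene_id
    # planted genes: induction proportional to realised promoter demethylation
    lat_delta <- vapply(anticorr_genes, function(gn) {
      idx <- ac_prom_by_gene[[gn]]
      mean(lat_c1[[p]]$d8[idx] - mu[idx])
    }, numeric(1))
    fc[anticorr_genes] <- cfg$anticorr_slope * lat_delta +
      rnorm(cfg$n_anticorr_genes, 0, cfg$expression_noise_sd)
    expr_cols[[paste0(p, "_blast_c1_d0")]] <- d0
    expr_cols[[paste0(p, "_blast_c1_d8")]] <- base_expr + fc +
      rnorm(cfg$n_genes, 0, 0.05)
  }
  expression <- tibble::as_tibble(c(list(feature_id = genes$gene_id), expr_cols))

  ## --- sheet and truth -----------------------------------------------------
  resp <- ifelse(seq_along(patients) <= round(cfg$responder_fraction *
                                                length(patients)),
                 "responder", "nonresponder")
  names(resp) <- patients
  sheet_rows <- list()
  for (p in patients) {
    for (tp in c("d0", "d8", "d15")) {
      sheet_rows[[length(sheet_rows) + 1]] <- tibble(
        sample_id = paste0(p, "_blast_c1_", tp), patient_id = p,
        timepoint = tp, cycle = 1L, cell_type = "blast",
        response_group = resp[p])
    }
  }
  for (p in c2_patients) {
    for (tp in c("d0", "d8")) {
      sheet_rows[[length(sheet_rows) + 1]] <- tibble(
        sample_id = paste0(p, "_blast_c2_", tp), patient_id = p,
        timepoint = tp, cycle = 2L, cell_type = "blast",
        response_group = resp[p])
    }
  }
  for (p in t_patients) {
    for (tp in c("d0", "d8")) {
      sheet_rows[[length(sheet_rows) + 1]] <- tibble(
        sample_id = paste0(p, "_tcell_c1_", tp), patient_id = p,
        timepoint = tp, cycle = 1L, cell_type = "tcell",
        response_group = resp[p])
    }
  }
  sheet <- dplyr::bind_rows(sheet_rows)
  validate_sample_sheet(sheet)

  long_sets <- function(sets, cell_type, cycle) {
    dplyr::bind_rows(lapply(names(sets), function(p) {
      if (!length(sets[[p]])) return(NULL)
      tibble(patient_id = p, cell_type = cell_type, cycle = cycle,
             cpg_id = sets[[p]])
    }))
  }
  n_ret <- length(retained)
  scale_f <- n_ret / 456281
  truth <- list(
    signature_cpg_ids = signature_ids,
    anticorrelated_gene_ids = anticorr_genes,
    demethylated = dplyr::bind_rows(
      long_sets(demeth_c1, "blast", 1L),
      long_sets(demeth_c2, "blast", 2L),
      long_sets(demeth_t, "tcell", 1L)),
    remethylated = long_sets(remeth_sets, "blast", 1L),
    patients = tibble(
      patient_id = patients,
      background_rate = unname(rates),
      truth_demeth_count = vapply(demeth_c1, length, integer(1)),
      magnitude_category = classify_demethylation_magnitude(
        vapply(demeth_c1, length, integer(1)),
        strong_threshold = 100000 * scale_f,
        limited_threshold = 25000 * scale_f)),
    n_retained = n_ret
  )

  structure(list(beta_blast = beta_blast, beta_tcell = beta_tcell,
                 expression = expression, annot = tibble::as_tibble(
                   annot[, c("cpg_id", "chromosome", "position", "nearest_gene",
                             "tss_distance", "region_categories",
                             "island_status", "repeat_overlap", "snp_overlap")]),
                 sheet = sheet, truth = truth, config = cfg, seed = seed),
            class = "dac_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits the matrices, sample sheet and annotation in the package's
#' interchange formats plus a `truth.json` ground-truth record.
#'
#' @param cohort A `dac_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dac_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cmt <- sprintf("simulated cohort seed=%d", cohort$seed)
  write_beta_matrix(cohort$beta_blast, file.path(dir, "beta_blast.tsv"), cmt)
  write_beta_matrix(cohort$beta_tcell, file.path(dir, "beta_tcell.tsv"), cmt)
  write_expression_matrix(cohort$expression, file.path(dir, "expression.tsv"), cmt)
  write_sample_sheet(cohort$sheet, file.path(dir, "sample_sheet.csv"))
  write_cpg_annotation(cohort$annot, file.path(dir, "annotation.tsv"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(signature_cpg_ids = truth$signature_cpg_ids,
         anticorrelated_gene_ids = truth$anticorrelated_gene_ids,
         demethylated = truth$demethylated,
         remethylated = truth$remethylated,
         patients = truth$patients,
         n_retained = truth$n_retained),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
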