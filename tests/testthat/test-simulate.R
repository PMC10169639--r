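small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_cpgs = 3000, n_genes = 200, n_patients_blast = 6,
         n_patients_tcell = 3, n_cycle2_patients = 2, n_anticorr_genes = 10),
    list(...))
  do.call(cohort_config, args)
}

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_cohort(small_cfg(), seed = 5)
  b <- simulate_cohort(small_cfg(), seed = 5)
  expect_identical(a, b)
  c <- simulate_cohort(small_cfg(), seed = 6)
  expect_false(identical(a$beta_blast, c$beta_blast))
})

test_that("the null configuration changes day 8 only by measurement noise", {
  co <- simulate_cohort(small_cfg(signature_size = 0,
                                  background_rate_range = c(0, 0),
                                  tcell_effect_rate = 0,
                                  n_anticorr_genes = 0), seed = 3)
  d0 <- as.matrix(co$beta_blast[, grep("c1_d0$", colnames(co$beta_blast))])
  d8 <- as.matrix(co$beta_blast[, grep("c1_d8$", colnames(co$beta_blast))])
  diffs <- d8 - d0
  expect_lt(abs(mean(diffs)), 0.005)
  expect_lt(max(abs(diffs)), 0.2)   # beta read noise only, no planted effect
  expect_equal(nrow(co$truth$demethylated), 0)
})

test_that("planted structure is audited by the truth record", {
  co <- simulate_cohort(cohort_config(n_cpgs = 5000, n_genes = 300,
                                      signature_size = 100,
                                      n_patients_blast = 8,
                                      n_patients_tcell = 2,
                                      n_cycle2_patients = 2,
                                      n_anticorr_genes = 10), seed = 9)
  truth <- co$truth
  expect_length(truth$signature_cpg_ids, 100)
  # every blast patient's truth set contains the whole signature, both cycles
  dem <- truth$demethylated
  for (p in unique(dem$patient_id[dem$cell_type == "blast"])) {
    for (cyc in unique(dem$cycle[dem$patient_id == p & dem$cell_type == "blast"])) {
      s <- dem$cpg_id[dem$patient_id == p & dem$cycle == cyc &
                        dem$cell_type == "blast"]
      expect_true(all(truth$signature_cpg_ids %in% s))
    }
  }
  # signature CpGs are retained (autosomal, non-SNP)
  ann <- co$annot[match(truth$signature_cpg_ids, co$annot$cpg_id), ]
  expect_false(any(ann$chromosome %in% c("chrX", "chrY")))
  expect_false(any(ann$snp_overlap))
})

test_that("emitted betas are valid and the annotation is coherent", {
  co <- shared_cohort()
  expect_silent(validate_beta(co$beta_blast))
  expect_silent(validate_beta(co$beta_tcell))
  expect_silent(validate_annotation(co$annot))
  expect_silent(validate_sample_sheet(co$sheet))
  # nearest-gene assignment is reproducible from positions alone (autosomes)
  auto <- co$annot[!(co$annot$chromosome %in% c("chrX", "chrY")), ]
  tss <- dplyr::distinct(
    tibble::tibble(gene_id = auto$nearest_gene,
                   chromosome = auto$chromosome,
                   tss_position = auto$position - auto$tss_distance))
  sub <- auto[sample.int(nrow(auto), 500), ]
  re <- annotate_nearest_gene(
    sub[, c("cpg_id", "chromosome", "position")], tss)
  expect_gt(mean(re$nearest_gene == sub$nearest_gene), 0.99)
})

test_that("planted effect sizes are recovered on average", {
  co <- shared_cohort()
  sig <- co$truth$signature_cpg_ids
  b <- co$beta_blast
  idx <- match(sig, b$cpg_id)
  d0 <- as.matrix(b[idx, grep("c1_d0$", colnames(b))])
  d8 <- as.matrix(b[idx, grep("c1_d8$", colnames(b))])
  expect_lt(abs(mean(d8 - d0) - co$config$signature_effect), 0.03)
})

test_that("the remethylated truth fraction matches the configured rate", {
  co <- shared_cohort()
  dem <- co$truth$demethylated
  rem <- co$truth$remethylated
  dem1 <- dem[dem$cell_type == "blast" & dem$cycle == 1, ]
  frac <- nrow(rem) / nrow(dem1)
  expect_lt(abs(frac - co$config$remethylation_fraction), 0.02)
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(signature_size = 1e6), "signature_size")
  expect_error(cohort_config(n_anticorr_genes = 5000), "n_anticorr_genes")
  expect_error(cohort_config(hyper_fraction = 1.2), "fraction")
  expect_error(cohort_config(n_cpgs = 1000, n_genes = 900), "n_genes")
})
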