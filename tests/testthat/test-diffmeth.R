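test_that("BH adjustment matches the hand-evaluated step-up and the oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.31), 0.31)
  set.seed(4)
  for (n in 1:8) {
    p <- runif(n)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-14)
  }
  # permutation equivariance
  p <- runif(8)
  perm <- sample(8)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-14)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("group delta-beta is the mean per-patient difference", {
  m <- matrix(c(0.9, 0.7, 0.8, 0.7), 1,
              dimnames = list("cg1", c("P1_t1", "P2_t1", "P1_t0", "P2_t0")))
  # per-patient diffs: P1 = 0.9-0.8 ... build explicit: t1 - t0
  b <- beta_tbl(m)
  design <- tibble::tibble(patient_id = c("P1", "P2"),
                           sample_t1 = c("P1_t1", "P2_t1"),
                           sample_t0 = c("P1_t0", "P2_t0"))
  expect_equal(group_delta_beta(b, design)$delta_beta, mean(c(0.1, 0)))
  set.seed(8)
  m2 <- matrix(runif(40), 10,
               dimnames = list(sprintf("cg%02d", 1:10),
                               c("P1_t1", "P2_t1", "P1_t0", "P2_t0")))
  got <- group_delta_beta(beta_tbl(m2), design)$delta_beta
  want <- rowMeans(m2[, 1:2] - m2[, 3:4])
  expect_equal(got, unname(want), tolerance = 1e-14)
  expect_error(group_delta_beta(beta_tbl(m2[, 1:3]), design), "absent")
})

test_that("demethylation calls use strict thresholds in the right direction", {
  tab <- tibble::tibble(cpg_id = c("a", "b", "c", "d"),
                        adj_p = c(0.01, 0.01, 0.06, 0.04),
                        delta_beta = c(-0.15, -0.10, -0.5, 0.2))
  expect_equal(call_demethylated(tab), "a")          # -0.10 exactly excluded
  expect_equal(call_demethylated(tab, direction = "remethylated"), "d")
  # raising the threshold never enlarges the call set
  for (thr in c(0.05, 0.1, 0.15, 0.25)) {
    expect_true(all(call_demethylated(tab, delta_threshold = thr + 0.05) %in%
                      call_demethylated(tab, delta_threshold = thr)))
  }
})

test_that("swapping the contrast mirrors the calls", {
  co <- simulate_cohort(cohort_config(n_cpgs = 3000, n_genes = 200,
                                      n_patients_blast = 6,
                                      n_patients_tcell = 2,
                                      n_cycle2_patients = 2,
                                      n_anticorr_genes = 5), seed = 21)
  bb <- filter_cpgs(co$beta_blast, co$annot)
  fwd <- diff_methylation(bb, co$sheet, "d8", "d0")
  rev <- diff_methylation(bb, co$sheet, "d0", "d8")
  expect_equal(rev$table$delta_beta, -fwd$table$delta_beta, tolerance = 1e-12)
  expect_equal(rev$table$p, fwd$table$p, tolerance = 1e-12)
  expect_setequal(call_demethylated(rev$table, direction = "remethylated"),
                  call_demethylated(fwd$table, direction = "demethylated"))
})

test_that("single-sample sets track the generator's per-patient truth", {
  co <- shared_cohort()
  bb <- filter_cpgs(co$beta_blast, co$annot)
  ss <- single_sample_delta_sets(bb, co$sheet, "d8", "d0")
  truth <- co$truth$patients
  got <- lengths(ss)[truth$patient_id]
  expect_gt(cor(got, truth$truth_demeth_count, method = "spearman"), 0.9)
  # single CpG contract cases
  m <- matrix(c(0.90, 0.75, 0.90, 0.85), 1,
              dimnames = list("cg1", c("P1_blast_c1_d0", "P1_blast_c1_d8",
                                       "P2_blast_c1_d0", "P2_blast_c1_d8")))
  one <- single_sample_delta_sets(beta_tbl(m), toy_sheet(c("P1", "P2")))
  expect_equal(one$P1, "cg1")     # delta -0.15
  expect_equal(one$P2, character(0))  # delta -0.05
})

test_that("magnitude classes use the published strict cutoffs", {
  expect_equal(classify_demethylation_magnitude(c(150000, 20000, 100000)),
               c("strong", "limited", "intermediate"))
  expect_equal(classify_demethylation_magnitude(25000), "intermediate")
})

test_that("cohort summaries reproduce medians and the baseline-bin skew", {
  m <- matrix(0.8, 4, 4,
              dimnames = list(paste0("cg", 1:4),
                              c("P1_blast_c1_d0", "P1_blast_c1_d8",
                                "P2_blast_c1_d0", "P2_blast_c1_d8")))
  sm <- cohort_methylation_summary(beta_tbl(m), toy_sheet(c("P1", "P2")))
  expect_equal(sm$median_beta, c(0.8, 0.8))
  m2 <- matrix(c(0.1, 0.2, 0.9, 1.0), 4, 1,
               dimnames = list(paste0("cg", 1:4), "P1_blast_c1_d0"))
  sheet1 <- toy_sheet("P1", timepoints = "d0")
  expect_equal(cohort_methylation_summary(beta_tbl(m2), sheet1)$median_beta,
               0.55)

  co <- shared_cohort()
  bb <- filter_cpgs(co$beta_blast, co$annot)
  dm <- diff_methylation(bb, co$sheet)
  rates <- demethylation_rate_by_baseline(bb, co$sheet,
                                          call_demethylated(dm$table))
  hi <- rates$call_rate[rates$baseline_bin == "(0.5,1]"]
  lo <- rates$call_rate[rates$baseline_bin == "[0,0.5]"]
  expect_gt(hi, lo)
})
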