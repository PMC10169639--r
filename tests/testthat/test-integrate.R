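test_that("probe collapse keeps the highest-IQR probe per gene", {
  m <- rbind(p1 = c(1, 5, 9, 2), p2 = c(4, 4.5, 5, 4.2),
             p3 = c(0, 1, 2, 3), p4 = c(7, 7, 7, 7))
  colnames(m) <- paste0("s", 1:4)
  expr <- beta_tbl(m, id_col = "feature_id")
  map <- tibble::tibble(probe_id = c("p1", "p2", "p3", "p4"),
                        gene_id = c("gA", "gA", "gB", NA))
  out <- collapse_probes_by_iqr(expr, map)
  expect_equal(out$feature_id, c("gA", "gB"))
  expect_equal(as.numeric(out[out$feature_id == "gA", -1]), unname(m["p1", ]))
  expect_equal(as.numeric(out[out$feature_id == "gB", -1]), unname(m["p3", ]))
  expect_equal(attr(out, "n_unmapped"), 1L)
  # IQR tie resolves to the lexicographically smallest probe id
  m2 <- rbind(pB = c(0, 1, 2, 3), pA = c(10, 11, 12, 13))
  colnames(m2) <- paste0("s", 1:4)
  out2 <- collapse_probes_by_iqr(
    beta_tbl(m2, id_col = "feature_id"),
    tibble::tibble(probe_id = c("pB", "pA"), gene_id = "g1"))
  expect_equal(as.numeric(out2[1, -1]), unname(m2["pA", ]))
  # brute-force argmax with ordering on random data
  set.seed(5)
  m3 <- matrix(rnorm(60), 15, dimnames = list(sprintf("p%02d", 1:15),
                                              paste0("s", 1:4)))
  map3 <- tibble::tibble(probe_id = rownames(m3),
                         gene_id = paste0("g", rep(1:5, each = 3)))
  out3 <- collapse_probes_by_iqr(beta_tbl(m3, id_col = "feature_id"), map3)
  for (g in unique(map3$gene_id)) {
    probes <- map3$probe_id[map3$gene_id == g]
    iqrs <- apply(m3[probes, ], 1, IQR)
    best <- sort(probes[iqrs == max(iqrs)])[1]
    expect_equal(as.numeric(out3[out3$feature_id == g, -1]),
                 unname(m3[best, ]))
  }
  expect_error(collapse_probes_by_iqr(expr, map[0, ]), "empty")
})

test_that("paired differential expression flags planted induction only", {
  set.seed(6)
  n <- 23
  n_genes <- 2000
  genes <- sprintf("g%04d", seq_len(n_genes))
  base <- matrix(rnorm(n_genes * n, 7, 1), n_genes, dimnames = list(genes, NULL))
  d8 <- base + matrix(rnorm(n_genes * n, 0, 0.1), n_genes)
  d8[1, ] <- d8[1, ] + 1   # planted induced gene, +1 log2 in all patients
  vals <- cbind(d8, base)
  colnames(vals) <- c(paste0("P", 1:n, "_d8"), paste0("P", 1:n, "_d0"))
  design <- tibble::tibble(patient_id = paste0("P", 1:n),
                           sample_t1 = paste0("P", 1:n, "_d8"),
                           sample_t0 = paste0("P", 1:n, "_d0"))
  deg <- paired_deg(beta_tbl(vals, id_col = "feature_id"), design)
  expect_true(deg$table$deg_call[1])
  expect_lt(deg$table$adj_p[1], 0.05)
  expect_equal(deg$table$mean_log2fc[1], 1, tolerance = 0.1)
  # null p-values approximately uniform (Kolmogorov-Smirnov distance)
  null_p <- deg$table$p[-1]
  ks <- max(abs(sort(null_p) - seq_along(null_p) / length(null_p)))
  expect_lt(ks, 0.05)
})

test_that("gene region means follow the promoter/body category sets", {
  ids <- paste0("cg", 1:5)
  ann <- toy_annot(ids)
  ann$nearest_gene <- c("g1", "g1", "g1", "g2", "g2")
  ann$region_categories <- c("TSS200", "5UTR", "Body", "TSS1500;1stExon",
                             "intergenic")
  m <- matrix(c(0.8, 0.6, 0.4, 0.5, 0.9), 5, 1, dimnames = list(ids, "s1"))
  out <- gene_region_beta(beta_tbl(m), ann)
  expect_equal(out$s1[out$gene_id == "g1" & out$region == "promoter"], 0.7)
  expect_equal(out$s1[out$gene_id == "g1" & out$region == "body"], 0.4)
  # dual-category CpG contributes to both regions
  expect_equal(out$s1[out$gene_id == "g2" & out$region == "promoter"], 0.5)
  expect_equal(out$s1[out$gene_id == "g2" & out$region == "body"], 0.5)
  # intergenic CpG contributes to neither; no zero-CpG rows are fabricated
  expect_false(any(out$n_cpgs == 0))

  # brute-force group-by mean on random toy data
  set.seed(10)
  ids2 <- sprintf("cg%02d", 1:40)
  ann2 <- toy_annot(ids2)
  ann2$nearest_gene <- sample(paste0("g", 1:6), 40, replace = TRUE)
  ann2$region_categories <- sample(c("TSS200", "Body", "3UTR", "TSS1500"),
                                   40, replace = TRUE)
  m2 <- matrix(runif(80), 40, 2, dimnames = list(ids2, c("s1", "s2")))
  out2 <- gene_region_beta(beta_tbl(m2), ann2)
  prom <- ann2$region_categories %in% c("TSS200", "TSS1500")
  for (g in unique(ann2$nearest_gene)) {
    sel <- prom & ann2$nearest_gene == g
    if (any(sel)) {
      row <- out2[out2$gene_id == g & out2$region == "promoter", ]
      expect_equal(row$s1, mean(m2[sel, "s1"]))
      expect_equal(row$n_cpgs, sum(sel))
    }
  }
})

test_that("row_spearman matches the brute-force average-rank oracle", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    x <- sample(1:4, n, replace = TRUE)      # heavy ties
    y <- rnorm(n)
    got <- demkin:::row_spearman(matrix(x, 1), matrix(y, 1))
    expect_equal(got, spearman_oracle(x, y), tolerance = 1e-12)
    expect_equal(got, suppressWarnings(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
})

screen_fixture <- function(x_rows, y_rows, patients = paste0("P", 1:5)) {
  n <- length(patients)
  genes <- sprintf("g%02d", seq_len(nrow(x_rows)))
  fc <- x_rows
  dimnames(fc) <- list(genes, patients)
  deg <- structure(list(log2fc = beta_tbl(fc, id_col = "gene_id")),
                   class = "deg_result")
  d0 <- matrix(0.5, nrow(y_rows), n)
  vals <- cbind(0.5 + y_rows / 20, d0)   # delta is a monotone map of y
  colnames(vals) <- c(paste0(patients, "_d8"), paste0(patients, "_d0"))
  rb <- tibble::as_tibble(cbind(
    tibble::tibble(gene_id = genes, region = "promoter",
                   n_cpgs = 2L),
    tibble::as_tibble(as.data.frame(vals))))
  design <- tibble::tibble(patient_id = patients,
                           sample_t1 = paste0(patients, "_d8"),
                           sample_t0 = paste0(patients, "_d0"))
  list(rb = rb, deg = deg, design = design)
}

test_that("the anti-correlation screen calls direction and significance", {
  f <- screen_fixture(matrix(1:5, 1), matrix(5:1, 1))
  out <- anti_correlation_screen(f$rb, f$deg, f$design)
  expect_equal(out$rho, -1)
  expect_true(out$anti_correlated_call)
  # perfect positive correlation is never called
  f2 <- screen_fixture(matrix(1:5, 1), matrix(1:5, 1))
  out2 <- anti_correlation_screen(f2$rb, f2$deg, f2$design)
  expect_equal(out2$rho, 1)
  expect_false(out2$anti_correlated_call)
  # zero variance flagged, not called
  f3 <- screen_fixture(matrix(rep(1, 5), 1), matrix(5:1, 1))
  out3 <- anti_correlation_screen(f3$rb, f3$deg, f3$design)
  expect_true(out3$zero_variance)
  expect_false(out3$anti_correlated_call)
  expect_error(anti_correlation_screen(f$rb, f$deg, f$design[1:4, ]),
               "at least 5")
})

test_that("the screen is invariant under monotone transforms (rank-based)", {
  set.seed(20)
  x <- matrix(rnorm(8 * 10), 8)
  y <- matrix(rnorm(8 * 10), 8)
  pats <- paste0("P", 1:10)
  f <- screen_fixture(x, y, pats)
  base <- anti_correlation_screen(f$rb, f$deg, f$design)
  f2 <- screen_fixture(exp(x), y, pats)       # monotone transform of x
  mono <- anti_correlation_screen(f2$rb, f2$deg, f2$design)
  expect_equal(base$rho, mono$rho, tolerance = 1e-12)
  expect_equal(base$anti_correlated_call, mono$anti_correlated_call)
})

test_that("screen calls among independent genes stay near the alpha level", {
  set.seed(23)
  x <- matrix(rnorm(500 * 12), 500)
  y <- matrix(rnorm(500 * 12), 500)
  f <- screen_fixture(x, y, paste0("P", 1:12))
  out <- anti_correlation_screen(f$rb, f$deg, f$design)
  expect_lt(mean(out$anti_correlated_call), 0.05 + 0.025)
})
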