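test_that("the common set is the patient intersection filtered group-wise", {
  sets <- list(P1 = c("a", "b", "c"), P2 = c("b", "c"), P3 = c("b", "c", "d"))
  expect_equal(common_demethylated_set(sets, c("a", "b", "c", "d")),
               c("b", "c"))
  expect_equal(common_demethylated_set(sets["P1"], c("a", "c")), c("a", "c"))
  expect_error(common_demethylated_set(list()), "empty")
})

test_that("min_fraction thresholds match brute-force counting", {
  set.seed(12)
  universe <- sprintf("cg%02d", 1:20)
  sets <- lapply(1:4, function(i) sample(universe, sample(5:15, 1)))
  names(sets) <- paste0("P", 1:4)
  got <- common_demethylated_set(sets, min_fraction = 0.5)
  counts <- vapply(universe, function(cg) {
    sum(vapply(sets, function(s) cg %in% s, logical(1)))
  }, numeric(1))
  expect_setequal(got, universe[counts >= 2])
})

test_that("random-set null honours forced and degenerate sizes", {
  u <- 30
  expect_true(all(random_set_null(c(P1 = 30), u, 50, seed = 1) == 30))
  expect_true(all(random_set_null(c(P1 = 0, P2 = 10), u, 50, seed = 1) == 0))
  expect_error(random_set_null(c(P1 = 31), u), "exceeds")
  # reproducible under seed
  expect_identical(random_set_null(c(P1 = 10, P2 = 15), u, 100, seed = 9),
                   random_set_null(c(P1 = 10, P2 = 15), u, 100, seed = 9))
})

test_that("normal tail p behaves like the standard normal", {
  null <- rep(c(8, 12), 500)   # mean 10, sd ~2
  mu <- mean(null); s <- sd(null)
  expect_equal(normal_tail_p(mu, null)$p_tail, 0.5)
  expect_equal(normal_tail_p(mu + 1.6449 * s, null)$p_tail, 0.05,
               tolerance = 1e-3)
  expect_equal(normal_tail_p(mu - s, null)$p_tail, pnorm(1), tolerance = 1e-12)
  # strictly decreasing in the observed count
  ps <- vapply(seq(0, 20), function(o) normal_tail_p(o, null)$p_tail,
               numeric(1))
  expect_true(all(diff(ps) < 0))
  # degenerate null
  expect_equal(normal_tail_p(5, rep(2, 10))$p_tail, 0)
  expect_equal(normal_tail_p(2, rep(2, 10))$p_tail, 1)
  expect_true(normal_tail_p(5, rep(2, 10))$degenerate)
  expect_error(normal_tail_p(1, integer(0)), "empty")
})

test_that("cycle overlap reports exact intersections and fractions", {
  ov <- cycle_overlap(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov$intersection, c("b", "c"))
  expect_equal(ov$fraction_recurrent, 2 / 3)
  expect_equal(cycle_overlap(c("a", "b"), c("a", "b"))$fraction_recurrent, 1)
  expect_equal(cycle_overlap(c("a", "b"), c("x", "y"))$fraction_recurrent, 0)
})

test_that("one-sided Fisher matches the hypergeometric enumeration", {
  expect_equal(fisher_exact_upper(matrix(c(2, 0, 0, 2), 2))$p, 1 / 6,
               tolerance = 1e-12)
  expect_equal(fisher_exact_upper(matrix(c(0, 3, 5, 2), 2))$p, 1,
               tolerance = 1e-12)
  for (a in 0:4) for (b in 0:4) for (cc in 0:4) for (d in 0:4) {
    got <- fisher_exact_upper(matrix(c(a, cc, b, d), 2))$p
    expect_equal(got, fisher_upper_oracle(a, b, cc, d), tolerance = 1e-12)
  }
  expect_error(fisher_exact_upper(matrix(c(-1, 0, 0, 1), 2)), "non-negative")
})

test_that("per-sample signature enrichment flags the expected patterns", {
  universe <- sprintf("cg%03d", 1:200)
  signature <- universe[1:20]
  sets <- list(Pfull = signature,                  # only signature called
               Pnone = character(0))
  enr <- signature_enrichment_per_sample(signature, sets, universe)
  full <- enr[enr$patient_id == "Pfull", ]
  expect_equal(full$p, fisher_upper_oracle(20, 0, 0, 180), tolerance = 1e-12)
  expect_equal(full$pct_signature_called, 100)
  none <- enr[enr$patient_id == "Pnone", ]
  expect_equal(none$p, 1)
  expect_true(none$empty_call)
  expect_error(signature_enrichment_per_sample(c("zz"), sets, universe),
               "subset")
})

test_that("per-sample enrichment p is approximately uniform under random calls", {
  set.seed(99)
  universe <- sprintf("cg%03d", 1:400)
  signature <- universe[1:40]
  ps <- replicate(200, {
    sets <- list(P = sample(universe, 80))
    signature_enrichment_per_sample(signature, sets, universe)$p
  })
  # discrete conservative p: sub-uniform tails on both ends
  expect_lt(mean(ps < 0.05), 0.09)
  expect_gt(mean(ps), 0.4)
})

test_that("the responder screen uses inclusive 80/20 bounds", {
  sets <- c(lapply(1:5, function(i) if (i <= 4) c("hit", "r_only") else "r_only"),
            lapply(1:5, function(i) if (i == 1) "hit" else "bg"))
  names(sets) <- c(paste0("R", 1:5), paste0("N", 1:5))
  groups <- setNames(rep(c("responder", "nonresponder"), each = 5), names(sets))
  out <- responder_screen(sets, groups)
  # 4/5 responders (0.8 >= 0.8) and 1/5 non-responders (0.2 <= 0.2): selected
  expect_true(out$selected[out$cpg_id == "hit"])
  # 5/5 responders but present in 0 non-responders: selected
  expect_true(out$selected[out$cpg_id == "r_only"])
  # called in 3/5 responders: excluded
  sets$R4 <- "r_only"; sets$R5 <- "r_only"
  out2 <- responder_screen(sets, groups)
  expect_false(out2$selected[out2$cpg_id == "hit"])
  expect_error(responder_screen(sets, groups[1:5]), "non-empty")
})

test_that("responder screen fractions match brute-force counting", {
  set.seed(3)
  cpgs <- sprintf("cg%02d", 1:20)
  sets <- lapply(1:10, function(i) sample(cpgs, sample(3:12, 1)))
  names(sets) <- paste0("P", 1:10)
  groups <- setNames(rep(c("responder", "nonresponder"), each = 5),
                     names(sets))
  out <- responder_screen(sets, groups)
  for (i in seq_len(nrow(out))) {
    fr <- mean(vapply(sets[1:5], function(s) out$cpg_id[i] %in% s, logical(1)))
    fn <- mean(vapply(sets[6:10], function(s) out$cpg_id[i] %in% s, logical(1)))
    expect_equal(out$frac_responders[i], fr)
    expect_equal(out$frac_nonresponders[i], fn)
    expect_equal(out$selected[i], fr >= 0.8 && fn <= 0.2)
  }
})
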