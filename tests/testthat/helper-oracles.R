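# Independent oracles and small fixture builders shared across tests.

# Brute-force BH step-up: adjusted_i = min over j >= rank(i) of m*p_(j)/j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# Exhaustive hypergeometric upper tail for a 2x2 table with fixed margins.
fisher_upper_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  sum(exp(logp)[xs >= a])
}

# Average ranks from first principles: rank(v) = #less + (#equal + 1) / 2.
avg_rank_oracle <- function(v) {
  vapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))
}

# Spearman with ties via Pearson's product-moment formula on average ranks.
spearman_oracle <- function(x, y) {
  rx <- avg_rank_oracle(x)
  ry <- avg_rank_oracle(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (den == 0) NA_real_ else num / den
}

# Method-of-moments hyperparameters for the scaled-F variance prior, solved
# independently with uniroot rather than Newton iteration.
variance_prior_oracle <- function(s2, d) {
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (evar <= 0) return(list(d0 = Inf, s0_sq = exp(mean(e))))
  half_d0 <- uniroot(function(x) trigamma(x) - evar,
                     lower = 1e-8, upper = 1e8, tol = 1e-14)$root
  d0 <- 2 * half_d0
  list(d0 = d0, s0_sq = exp(mean(e) + digamma(half_d0) - log(half_d0)))
}

# All permutations of 1..n as rows of a matrix.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# --- fixture builders -----------------------------------------------------

beta_tbl <- function(m, id_col = "cpg_id") {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  out <- tibble::as_tibble(as.data.frame(m))
  tibble::add_column(out, !!id_col := rownames(m), .before = 1)
}

toy_sheet <- function(patients, timepoints = c("d0", "d8"), cycle = 1L,
                      cell_type = "blast", response = "unknown") {
  do.call(rbind, lapply(patients, function(p) {
    data.frame(sample_id = paste0(p, "_", cell_type, "_c", cycle, "_", timepoints),
               patient_id = p, timepoint = timepoints, cycle = cycle,
               cell_type = cell_type, response_group = response)
  })) |> tibble::as_tibble()
}

toy_annot <- function(cpg_ids, chromosome = "chr1",
                      region = "Body", island = "OpenSea",
                      repeats = FALSE, snp = FALSE) {
  tibble::tibble(cpg_id = cpg_ids, chromosome = chromosome,
                 position = seq_along(cpg_ids) * 1000L,
                 nearest_gene = "g00001",
                 tss_distance = seq_along(cpg_ids) * 1000L,
                 region_categories = region, island_status = island,
                 repeat_overlap = repeats, snp_overlap = snp)
}

# One default cohort shared by the heavier tests, built once per run.
.cohort_cache <- new.env(parent = emptyenv())
shared_cohort <- function(seed = 2024) {
  key <- paste0("c", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- demkin::simulate_cohort(demkin::cohort_config(),
                                                    seed = seed)
  }
  .cohort_cache[[key]]
}
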