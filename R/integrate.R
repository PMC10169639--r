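# Methylome-transcriptome integration: probe-to-gene collapse, paired
# differential expression, CpG-to-gene promoter/body aggregation, and the
# gene-wise Spearman anti-correlation screen.

#' Collapse probe-level expression to genes by highest IQR
#'
#' Keeps, per gene, the single probe row with the largest across-sample
#' interquartile range; IQR ties resolve to the lexicographically smallest
#' probe id. Unmapped probes are dropped (count in attribute `n_unmapped`).
#'
#' @param expr Probe-level expression tibble (`feature_id` + samples).
#' @param probe_to_gene Tibble with `probe_id`, `gene_id`.
#' @return Gene-level expression tibble (`feature_id` = gene ids).
#' @export
collapse_probes_by_iqr <- function(expr, probe_to_gene) {
  if (!nrow(probe_to_gene)) abort("probe_to_gene mapping is empty")
  m <- as_feature_matrix(expr)
  map <- probe_to_gene[match(rownames(m), probe_to_gene$probe_id), ]
  mapped <- !is.na(map$gene_id)
  n_unmapped <- sum(!mapped)
  iqr <- apply(m, 1, IQR)
  sel <- tibble(probe_id = rownames(m), gene_id = map$gene_id, iqr = iqr) %>%
    filter(mapped) %>%
    arrange(.data$gene_id, dplyr::desc(.data$iqr), .data$probe_id) %>%
    distinct(.data$gene_id, .keep_all = TRUE)
  out <- as_feature_tibble(m[sel$probe_id, , drop = FALSE], "feature_id")
  out$feature_id <- sel$gene_id
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Paired differential expression
#'
#' Per-patient log2 fold changes (`t1 - t0`, intensities already log2) with
#' the same empirical-Bayes moderated paired test and BH adjustment as the
#' methylation analysis.
#'
#' @param expr Gene-level expression tibble.
#' @param design A [paired_design()].
#' @param alpha BH threshold for the `deg_call` flag.
#' @param prior_df,prior_var Passed to [moderated_paired_test()].
#' @return List of class `deg_result`: `table` (per-gene statistics) and
#'   `log2fc` (gene-by-patient fold-change tibble).
#' @export
paired_deg <- function(expr, design, alpha = 0.05, prior_df = NULL,
                       prior_var = NULL) {
  fit <- moderated_paired_test(expr, design, prior_df = prior_df,
                               prior_var = prior_var)
  fc <- paired_differences(expr, design)
  adj_p <- bh_adjust(fit$p)
  table <- tibble(gene_id = fit$feature_id, mean_log2fc = fit$mean_diff,
                  mod_t = fit$mod_t, p = fit$p, adj_p = adj_p,
                  deg_call = adj_p < alpha)
  structure(list(table = table,
                 log2fc = as_feature_tibble(fc, "gene_id"),
                 d0 = attr(fit, "d0"), s0_sq = attr(fit, "s0_sq"),
                 n_patients = nrow(design), alpha = alpha),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf("Paired differential expression: %d genes, %d patients, %d DEGs (adj p < %g)\n",
              nrow(x$table), x$n_patients, sum(x$table$deg_call), x$alpha))
  invisible(x)
}

#' @rdname paired_deg
#' @param x A `deg_result`.
#' @param ... Unused.
#' @export
tidy.deg_result <- function(x, ...) x$table

#' @rdname paired_deg
#' @export
glance.deg_result <- function(x, ...) {
  tibble(n_genes = nrow(x$table), n_patients = x$n_patients,
         n_deg = sum(x$table$deg_call), prior_df = x$d0, prior_var = x$s0_sq,
         alpha = x$alpha)
}

#' Per-gene promoter and body methylation
#'
#' Unweighted mean beta per sample over a gene's promoter CpGs (TSS1500,
#' TSS200, 5'UTR) and body CpGs (1stExon, ExonBnd, Body, 3'UTR). CpGs
#' carrying both promoter and body categories contribute to both regions;
#' genes with no CpG in a region are absent from that region (never 0).
#'
#' @param beta Beta tibble.
#' @param annot CpG annotation covering all matrix CpGs.
#' @return Tibble with `gene_id`, `region` (`"promoter"`/`"body"`),
#'   `n_cpgs`, and one column per sample.
#' @export
gene_region_beta <- function(beta, annot) {
  ids <- id_column(beta)
  missing <- setdiff(ids, annot$cpg_id)
  if (length(missing)) {
    abort(sprintf("CpG '%s' has no annotation row", missing[1]))
  }
  ann <- annot[match(ids, annot$cpg_id), ]
  cats <- strsplit(ann$region_categories, ";", fixed = TRUE)
  in_prom <- vapply(cats, function(x) any(x %in% PROMOTER_CATEGORIES), logical(1))
  in_body <- vapply(cats, function(x) any(x %in% BODY_CATEGORIES), logical(1))
  m <- as_feature_matrix(beta)

  region_means <- function(sel, region) {
    if (!any(sel)) return(NULL)
    sub <- m[sel, , drop = FALSE]
    genes <- ann$nearest_gene[sel]
    means <- rowsum(sub, genes) / as.vector(table(genes)[sort(unique(genes))])
    out <- as_feature_tibble(means, "gene_id")
    tibble::add_column(out, region = region,
                       n_cpgs = as.integer(table(genes)[out$gene_id]),
                       .after = 1)
  }
  dplyr::bind_rows(region_means(in_prom, "promoter"),
                   region_means(in_body, "body")) %>%
    arrange(.data$region, .data$gene_id)
}

# Rowwise Spearman rho between paired matrices: Pearson on average ranks,
# computed row by row. Zero-variance rows yield NA.
row_spearman <- function(x_mat, y_mat) {
  stopifnot(identical(dim(x_mat), dim(y_mat)))
  rx <- t(apply(x_mat, 1, rank))
  ry <- t(apply(y_mat, 1, rank))
  if (ncol(x_mat) == 1) {
    rx <- t(rx)
    ry <- t(ry)
  }
  cx <- rx - rowMeans(rx)
  cy <- ry - rowMeans(ry)
  den <- sqrt(rowSums(cx^2) * rowSums(cy^2))
  ifelse(den == 0, NA_real_, rowSums(cx * cy) / den)
}

# Fisher-z one/two-sided p for a (rank) correlation.
fisher_z_p <- function(rho, n, alternative) {
  rho_c <- pmin(pmax(rho, -(1 - 1e-12)), 1 - 1e-12)
  z <- atanh(rho_c) * sqrt(n - 3)
  if (alternative == "anti") pnorm(z) else 2 * pnorm(-abs(z))
}

#' Gene-wise methylation-expression anti-correlation screen
#'
#' For each gene and region, correlates per-patient log2 fold change with
#' per-patient region delta-beta using Spearman's rho (average ranks for
#' ties), and tests anti-correlation one-sided via the Fisher z normal
#' approximation: `p = Phi(atanh(rho) * sqrt(n - 3))`. A gene is called
#' anti-correlated when `p < alpha` and `rho < 0`. Zero-variance vectors
#' leave rho undefined; the gene is flagged, never called.
#'
#' @param region_beta Output of [gene_region_beta()] on the full beta
#'   matrix (both timepoints present as samples).
#' @param deg A `deg_result` from [paired_deg()] (its per-patient fold
#'   changes are used).
#' @param design The [paired_design()] shared by both modalities; at least
#'   5 patients are required.
#' @param alpha Significance threshold. Default 0.05.
#' @param alternative `"anti"` (one-sided, default) or `"two.sided"`.
#' @param keep_pairs Retain the per-patient (delta-beta, log2FC) pairs as a
#'   `pairs` list-column for audit and plotting. Default `TRUE`.
#' @return Tibble of class `correlation_screen`: `gene_id`, `region`,
#'   `n_cpgs`, `rho`, `n`, `p`, `anti_correlated_call`, `zero_variance`,
#'   and (with `keep_pairs`) a `pairs` list-column.
#' @export
anti_correlation_screen <- function(region_beta, deg, design, alpha = 0.05,
                                    alternative = c("anti", "two.sided"),
                                    keep_pairs = TRUE) {
  alternative <- match.arg(alternative)
  n <- nrow(design)
  if (n < 5) abort("anti-correlation screen requires at least 5 patients")
  fc <- as_feature_matrix(deg$log2fc)
  rb <- region_beta
  meta <- rb[, c("gene_id", "region", "n_cpgs")]
  vals <- as.matrix(rb[, setdiff(colnames(rb), colnames(meta)), drop = FALSE])
  missing <- setdiff(c(design$sample_t1, design$sample_t0), colnames(vals))
  if (length(missing)) {
    abort(sprintf("design sample '%s' is absent from region_beta", missing[1]))
  }
  delta <- vals[, design$sample_t1, drop = FALSE] -
    vals[, design$sample_t0, drop = FALSE]
  colnames(delta) <- design$patient_id

  keep <- which(meta$gene_id %in% rownames(fc))
  y_mat <- delta[keep, , drop = FALSE]
  x_mat <- fc[meta$gene_id[keep], design$patient_id, drop = FALSE]
  rho <- unname(row_spearman(x_mat, y_mat))
  zero_var <- is.na(rho)
  p <- ifelse(zero_var, NA_real_, fisher_z_p(rho, n, alternative))
  out <- tibble(gene_id = meta$gene_id[keep], region = meta$region[keep],
                n_cpgs = meta$n_cpgs[keep], rho = rho, n = n, p = p,
                anti_correlated_call = !zero_var & !is.na(p) &
                  p < alpha & rho < 0,
                zero_variance = zero_var)
  if (keep_pairs) {
    out$pairs <- lapply(seq_along(keep), function(i) {
      tibble(patient_id = design$patient_id,
             delta_beta = unname(y_mat[i, ]), log2fc = unname(x_mat[i, ]))
    })
  }
  class(out) <- c("correlation_screen", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "alternative") <- alternative
  out
}
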