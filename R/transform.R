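# Beta <-> m-value transforms, CpG filtering, nearest-gene annotation.

#' Convert beta values to m-values
#'
#' The m-value is the logit2 of the methylated fraction,
#' m = log2(beta / (1 - beta)). Beta values are clamped into
#' \[epsilon, 1 - epsilon\] first so that fully (un)methylated CpGs map to
#' finite values; on normalized array data the clamp is inert.
#'
#' @param beta Beta tibble (`cpg_id` + sample columns), values in \[0, 1\].
#' @param epsilon Clamp width, in (0, 0.5). Default 0.001.
#' @return Tibble of the same shape holding finite m-values.
#' @export
beta_to_m <- function(beta, epsilon = 0.001) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon <= 0 || epsilon >= 0.5) {
    abort("epsilon must be a single number in (0, 0.5)")
  }
  validate_beta(beta)
  m <- as_feature_matrix(beta)
  m <- pmin(pmax(m, epsilon), 1 - epsilon)
  m <- log2(m / (1 - m))
  as_feature_tibble(m, colnames(beta)[1])
}

#' Convert m-values back to beta values
#'
#' Inverse of [beta_to_m()]: beta = 2^m / (1 + 2^m). Round-trips with
#' [beta_to_m()] to numerical precision for beta inside the clamp range.
#'
#' @param m M-value tibble (id + sample columns), finite values.
#' @return Beta tibble of the same shape.
#' @export
m_to_beta <- function(m) {
  validate_matrix_tbl(m, "m-value matrix")
  x <- as_feature_matrix(m)
  b <- 1 / (1 + 2^(-x))
  as_feature_tibble(b, colnames(m)[1])
}

#' Remove sex-chromosome and SNP-overlapping CpGs
#'
#' Drops CpGs on chrX/chrY and CpGs flagged as overlapping known SNPs,
#' preserving the input row order. Every CpG must carry an annotation row.
#'
#' @param beta Beta tibble.
#' @param annot CpG annotation tibble.
#' @return Filtered beta tibble.
#' @export
filter_cpgs <- function(beta, annot) {
  ids <- id_column(beta)
  missing <- setdiff(ids, annot$cpg_id)
  if (length(missing)) {
    abort(sprintf("CpG '%s' has no annotation row", missing[1]))
  }
  ann <- annot[match(ids, annot$cpg_id), ]
  keep <- !(ann$chromosome %in% c("chrX", "chrY")) & !ann$snp_overlap
  beta[keep, , drop = FALSE]
}

#' Annotate CpGs with their nearest gene by TSS distance
#'
#' Assigns each CpG the gene whose transcription start site is closest in
#' absolute base pairs on the same chromosome. The signed distance is
#' `position - tss` (negative when the CpG lies upstream of a plus-strand
#' TSS); strand is ignored for the magnitude. Exact-distance ties are broken
#' by the lexicographically smallest gene id.
#'
#' @param cpg_loci Tibble with `cpg_id`, `chromosome`, `position`.
#' @param tss_table Tibble with `gene_id`, `chromosome`, `tss_position`.
#' @return Tibble with `cpg_id`, `nearest_gene`, `tss_distance`.
#' @export
annotate_nearest_gene <- function(cpg_loci, tss_table) {
  stopifnot(all(c("cpg_id", "chromosome", "position") %in% colnames(cpg_loci)),
            all(c("gene_id", "chromosome", "tss_position") %in% colnames(tss_table)))
  no_tss <- setdiff(unique(cpg_loci$chromosome), unique(tss_table$chromosome))
  if (length(no_tss)) {
    abort(sprintf("chromosome '%s' hosts CpGs but has no TSS entries", no_tss[1]))
  }
  pieces <- lapply(split(seq_len(nrow(cpg_loci)), cpg_loci$chromosome), function(idx) {
    chr <- cpg_loci$chromosome[idx[1]]
    tss <- tss_table[tss_table$chromosome == chr, ]
    # order by (position, gene_id); equal-position duplicates resolve to the
    # lexicographically smallest id, which is the one kept first
    tss <- tss[order(tss$tss_position, tss$gene_id), ]
    tss <- tss[!duplicated(tss$tss_position), ]
    pos <- cpg_loci$position[idx]
    i <- findInterval(pos, tss$tss_position)
    left <- pmax(i, 1L)
    right <- pmin(i + 1L, nrow(tss))
    d_left <- abs(pos - tss$tss_position[left])
    d_right <- abs(pos - tss$tss_position[right])
    d_left[i < 1L] <- Inf
    use_left <- d_left < d_right |
      (d_left == d_right & tss$gene_id[left] <= tss$gene_id[right])
    pick <- ifelse(use_left, left, right)
    tibble(cpg_id = cpg_loci$cpg_id[idx],
           nearest_gene = tss$gene_id[pick],
           tss_distance = as.integer(pos - tss$tss_position[pick]),
           .row = idx)
  })
  out <- dplyr::bind_rows(pieces)
  out <- out[order(out$.row), c("cpg_id", "nearest_gene", "tss_distance")]
  tibble::as_tibble(out)
}
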