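# ggplot2 helpers mirroring the figures practitioners draw from these
# results: null-count densities with the observed count, per-patient call
# burdens, methylation-density shifts, and per-gene correlation scatters.

#' Density of null counts with the observed common count
#'
#' @param object A `signature_null`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.signature_null <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_count)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = object$observed_common_count,
                        linewidth = 0.8) +
    ggplot2::labs(x = "common CpGs in random sets",
                  y = "density",
                  title = sprintf("observed = %d, null %.1f +/- %.1f, p = %.2g",
                                  object$observed_common_count,
                                  object$null_mean, object$null_sd,
                                  object$p_tail)) +
    ggplot2::theme_minimal()
}

#' Per-patient demethylated CpG counts
#'
#' Bar chart of per-patient single-sample call-set sizes, optionally split
#' by a second contrast (e.g. d8 vs d0 and d15 vs d0).
#'
#' @param sets Named list (patient -> CpG ids) or a named list of such
#'   lists, one per contrast.
#' @return A ggplot.
#' @export
plot_demethylation_counts <- function(sets) {
  if (is.list(sets[[1]])) {
    df <- dplyr::bind_rows(lapply(names(sets), function(ct) {
      tibble(patient_id = names(sets[[ct]]), contrast = ct,
             n_demethylated = lengths(sets[[ct]]))
    }))
  } else {
    df <- tibble(patient_id = names(sets), contrast = "d8 vs d0",
                 n_demethylated = lengths(sets))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$patient_id,
                                   y = .data$n_demethylated,
                                   fill = .data$contrast)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "demethylated CpGs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Methylation density by timepoint for a CpG set
#'
#' Density of beta values over the given CpGs, one curve per timepoint —
#' the conventional view of demethylation at day 8 and rebound at day 15.
#'
#' @param beta Beta tibble.
#' @param sheet Sample sheet.
#' @param cpg_set CpG ids to plot.
#' @param cell_type,cycle Samples used.
#' @return A ggplot.
#' @export
plot_methylation_density <- function(beta, sheet, cpg_set,
                                     cell_type = "blast", cycle = 1) {
  m <- as_feature_matrix(beta)
  m <- m[rownames(m) %in% cpg_set, , drop = FALSE]
  sub <- sheet %>% filter(.data$cell_type == !!cell_type,
                          .data$cycle == !!cycle)
  df <- dplyr::bind_rows(lapply(unique(sub$timepoint), function(tp) {
    cols <- intersect(sub$sample_id[sub$timepoint == tp], colnames(m))
    tibble(timepoint = tp, beta = as.vector(m[, cols, drop = FALSE]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, colour = .data$timepoint)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "beta", y = "density") +
    ggplot2::theme_minimal()
}

#' Scatter of methylation change vs expression change for one gene
#'
#' @param screen A `correlation_screen` tibble.
#' @param gene Gene id to plot.
#' @return A ggplot.
#' @export
plot_gene_correlation <- function(screen, gene) {
  rows <- screen[screen$gene_id == gene, ]
  if (!nrow(rows)) abort(sprintf("gene '%s' not in the screen", gene))
  df <- dplyr::bind_rows(lapply(seq_len(nrow(rows)), function(i) {
    dplyr::mutate(rows$pairs[[i]], region = rows$region[i])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$delta_beta,
                                   colour = .data$region)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", se = FALSE, formula = y ~ x) +
    ggplot2::labs(title = gene, x = "expression log2 fold change",
                  y = "delta beta") +
    ggplot2::theme_minimal()
}
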