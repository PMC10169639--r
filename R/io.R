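# Readers/writers and validators for the tabular interchange formats:
# beta / expression matrices (TSV, first column `id`), the sample sheet
# (CSV) and the CpG annotation table (TSV). All readers return tibbles and
# fail loudly, naming the offending row/column.

TIMEPOINTS <- c("d0", "d8", "d15")
CELL_TYPES <- c("blast", "tcell")
RESPONSE_GROUPS <- c("responder", "nonresponder", "unknown")
REGION_CATEGORIES <- c("TSS1500", "TSS200", "5UTR", "1stExon", "ExonBnd",
                       "Body", "3UTR", "intergenic")
PROMOTER_CATEGORIES <- c("TSS1500", "TSS200", "5UTR")
BODY_CATEGORIES <- c("1stExon", "ExonBnd", "Body", "3UTR")
ISLAND_STATUSES <- c("Island", "Shore", "Shelf", "OpenSea")

#' Validate a beta-value table
#'
#' Checks that a CpG-by-sample beta table has unique CpG and sample ids and
#' that every value is finite and within \[0, 1\]. The first offending cell is
#' reported by CpG and sample id.
#'
#' @param beta Tibble with a `cpg_id` first column and one numeric column per
#'   sample.
#' @return `beta`, invisibly, if valid.
#' @export
validate_beta <- function(beta) {
  validate_matrix_tbl(beta, what = "beta matrix", range01 = TRUE)
}

validate_matrix_tbl <- function(tbl, what, range01 = FALSE) {
  if (!is.data.frame(tbl) || ncol(tbl) < 2) {
    abort(sprintf("%s must be a data frame with an id column plus >=1 sample column", what))
  }
  ids <- id_column(tbl)
  if (anyDuplicated(ids)) {
    abort(sprintf("%s has duplicate feature ids (e.g. '%s')", what,
                  ids[duplicated(ids)][1]))
  }
  samples <- sample_columns(tbl)
  if (anyDuplicated(samples)) {
    abort(sprintf("%s has duplicate sample ids (e.g. '%s')", what,
                  samples[duplicated(samples)][1]))
  }
  m <- as_feature_matrix(tbl)
  bad <- if (range01) !is.finite(m) | m < 0 | m > 1 else !is.finite(m)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("%s value %s at CpG/feature '%s', sample '%s' is %s",
                  what, format(m[idx[1], idx[2]]),
                  rownames(m)[idx[1]], colnames(m)[idx[2]],
                  if (range01) "outside [0, 1] or non-finite" else "non-finite"))
  }
  invisible(tbl)
}

read_matrix_tsv <- function(path, id_col, what, range01) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(tbl) < 2 || colnames(tbl)[1] != "id") {
    abort(sprintf("%s '%s': malformed header, first column must be 'id'", what, path))
  }
  colnames(tbl)[1] <- id_col
  tbl[[1]] <- as.character(tbl[[1]])
  validate_matrix_tbl(tbl, what = what, range01 = range01)
  tbl
}

#' Read a beta-value matrix from TSV
#'
#' Expects a tab-separated file whose first column is `id` (CpG identifiers)
#' and remaining columns are samples; `#`-prefixed leading lines are ignored.
#'
#' @param path Path to the TSV file.
#' @return Tibble with `cpg_id` plus one numeric column per sample.
#' @export
read_beta_matrix <- function(path) {
  read_matrix_tsv(path, "cpg_id", "beta matrix", range01 = TRUE)
}

#' Read a log2 expression matrix from TSV
#'
#' @inheritParams read_beta_matrix
#' @return Tibble with `feature_id` plus one numeric column per sample.
#' @export
read_expression_matrix <- function(path) {
  read_matrix_tsv(path, "feature_id", "expression matrix", range01 = FALSE)
}

write_matrix_tsv <- function(tbl, path, comment = NULL) {
  out <- tbl
  colnames(out)[1] <- "id"
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_tsv(out, path, append = TRUE, col_names = TRUE, progress = FALSE)
  } else {
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Write a beta or expression matrix to TSV
#'
#' @param tbl Feature-by-sample tibble (id first column).
#' @param path Output path.
#' @param comment Optional single-line comment written as a leading `#` line.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(tbl, path, comment = NULL) {
  validate_beta(tbl)
  write_matrix_tsv(tbl, path, comment)
}

#' @rdname write_beta_matrix
#' @export
write_expression_matrix <- function(tbl, path, comment = NULL) {
  validate_matrix_tbl(tbl, "expression matrix", range01 = FALSE)
  write_matrix_tsv(tbl, path, comment)
}

#' Validate a sample sheet
#'
#' Enforces the sheet contract: required columns, known factor levels, and
#' uniqueness of `sample_id` and of (patient, timepoint, cycle, cell type).
#'
#' @param sheet Sample sheet tibble.
#' @return `sheet`, invisibly, if valid.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "patient_id", "timepoint", "cycle", "cell_type",
           "response_group")
  missing <- setdiff(req, colnames(sheet))
  if (length(missing)) {
    abort(sprintf("sample sheet is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(sheet$sample_id)) {
    abort(sprintf("duplicate sample_id '%s' in sample sheet",
                  sheet$sample_id[duplicated(sheet$sample_id)][1]))
  }
  check_levels <- function(col, levels) {
    bad <- setdiff(unique(sheet[[col]]), levels)
    if (length(bad)) {
      abort(sprintf("sample sheet column '%s' has unknown value '%s'", col, bad[1]))
    }
  }
  check_levels("timepoint", TIMEPOINTS)
  check_levels("cell_type", CELL_TYPES)
  check_levels("response_group", RESPONSE_GROUPS)
  if (any(!is.finite(sheet$cycle) | sheet$cycle < 1 | sheet$cycle != round(sheet$cycle))) {
    abort("sample sheet column 'cycle' must contain integers >= 1")
  }
  key <- paste(sheet$patient_id, sheet$timepoint, sheet$cycle, sheet$cell_type)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate (patient, timepoint, cycle, cell_type) combination: %s",
                  key[duplicated(key)][1]))
  }
  invisible(sheet)
}

#' Read a sample sheet from CSV
#'
#' @param path CSV with header
#'   `sample_id,patient_id,timepoint,cycle,cell_type,response_group`.
#' @return Validated sample-sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             sample_id = readr::col_character(),
                             patient_id = readr::col_character(),
                             timepoint = readr::col_character(),
                             cycle = readr::col_integer(),
                             cell_type = readr::col_character(),
                             response_group = readr::col_character()))
  validate_sample_sheet(sheet)
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet Sample-sheet tibble.
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  readr::write_csv(sheet, path, progress = FALSE)
  invisible(path)
}

#' Validate a CpG annotation table
#'
#' @param annot Annotation tibble with columns `cpg_id`, `chromosome`,
#'   `position`, `nearest_gene`, `tss_distance`, `region_categories`
#'   (semicolon-separated), `island_status`, `repeat_overlap`, `snp_overlap`.
#' @return `annot`, invisibly, if valid.
#' @export
validate_annotation <- function(annot) {
  req <- c("cpg_id", "chromosome", "position", "nearest_gene", "tss_distance",
           "region_categories", "island_status", "repeat_overlap", "snp_overlap")
  missing <- setdiff(req, colnames(annot))
  if (length(missing)) {
    abort(sprintf("annotation is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(annot$cpg_id)) {
    abort(sprintf("duplicate cpg_id '%s' in annotation",
                  annot$cpg_id[duplicated(annot$cpg_id)][1]))
  }
  cats <- strsplit(annot$region_categories, ";", fixed = TRUE)
  n_cat <- lengths(cats)
  if (any(n_cat == 0)) {
    abort(sprintf("CpG '%s' has empty region_categories",
                  annot$cpg_id[n_cat == 0][1]))
  }
  flat <- unique(unlist(cats))
  bad <- setdiff(flat, REGION_CATEGORIES)
  if (length(bad)) {
    abort(sprintf("unknown region category '%s'", bad[1]))
  }
  inter <- vapply(cats, function(x) "intergenic" %in% x && length(x) > 1, logical(1))
  if (any(inter)) {
    abort(sprintf("CpG '%s': 'intergenic' must be the sole region category",
                  annot$cpg_id[inter][1]))
  }
  bad_island <- setdiff(unique(annot$island_status), ISLAND_STATUSES)
  if (length(bad_island)) {
    abort(sprintf("unknown island_status '%s'", bad_island[1]))
  }
  if (!is.logical(annot$repeat_overlap) || !is.logical(annot$snp_overlap)) {
    abort("repeat_overlap and snp_overlap must be logical")
  }
  invisible(annot)
}

#' Read a CpG annotation table from TSV
#'
#' @param path Annotation TSV; booleans encoded as `true`/`false`.
#' @return Validated annotation tibble.
#' @export
read_cpg_annotation <- function(path) {
  annot <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(
                             cpg_id = readr::col_character(),
                             chromosome = readr::col_character(),
                             position = readr::col_integer(),
                             nearest_gene = readr::col_character(),
                             tss_distance = readr::col_integer(),
                             region_categories = readr::col_character(),
                             island_status = readr::col_character(),
                             repeat_overlap = readr::col_logical(),
                             snp_overlap = readr::col_logical()))
  validate_annotation(annot)
  annot
}

#' @rdname read_cpg_annotation
#' @param annot Annotation tibble.
#' @param path Output path.
#' @export
write_cpg_annotation <- function(annot, path) {
  validate_annotation(annot)
  out <- annot
  out$repeat_overlap <- ifelse(out$repeat_overlap, "true", "false")
  out$snp_overlap <- ifelse(out$snp_overlap, "true", "false")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Load and cross-validate a methylation dataset
#'
#' Reads a beta matrix, sample sheet and CpG annotation, and checks that every
#' sheet sample has a matrix column and every matrix CpG has an annotation row.
#'
#' @param beta_path,sheet_path,annot_path File paths (see the reader functions
#'   for the expected dialects).
#' @return Named list with elements `beta`, `sheet`, `annot`.
#' @export
load_dataset <- function(beta_path, sheet_path, annot_path) {
  beta <- read_beta_matrix(beta_path)
  sheet <- read_sample_sheet(sheet_path)
  annot <- read_cpg_annotation(annot_path)
  missing_samples <- setdiff(sheet$sample_id, sample_columns(beta))
  if (length(missing_samples)) {
    abort(sprintf("sample '%s' listed in the sheet is absent from the beta matrix",
                  missing_samples[1]))
  }
  missing_annot <- setdiff(id_column(beta), annot$cpg_id)
  if (length(missing_annot)) {
    abort(sprintf("CpG '%s' in the beta matrix has no annotation row",
                  missing_annot[1]))
  }
  list(beta = beta, sheet = sheet, annot = annot)
}

#' Write a result table with a provenance comment line
#'
#' All pipeline result tables are TSVs with a leading `#` line recording the
#' tool version, the seed and the parameters used to produce them.
#'
#' @param tbl Result tibble.
#' @param path Output path.
#' @param seed Integer seed used (or `NA`).
#' @param params Named list of parameters to record.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(tbl, path, seed = NA, params = list()) {
  kv <- if (length(params)) {
    paste(vapply(names(params), function(k) {
      paste0(k, "=", paste(format(params[[k]]), collapse = ","))
    }, character(1)), collapse = " ")
  } else ""
  header <- sprintf("# demkin %s seed=%s %s",
                    as.character(utils::packageVersion("demkin")),
                    format(seed), kv)
  writeLines(trimws(header), path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
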