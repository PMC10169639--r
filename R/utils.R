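# Internal helpers shared across modules.

# Derive a component-specific RNG seed from one master seed; keeps every
# sub-seed a valid 32-bit integer.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 999983 * as.numeric(k)) %% 2147483647L)
}

# Feature-major tibble (id column + one column per sample) -> numeric matrix.
as_feature_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), ncol(tbl) >= 2)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tbl[[1]])
  m
}

# Numeric matrix -> feature-major tibble with the given id column name.
as_feature_tibble <- function(m, id_col) {
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, !!id_col := rownames(m), .before = 1)
  out
}

id_column <- function(tbl) as.character(tbl[[1]])

sample_columns <- function(tbl) colnames(tbl)[-1]

# Row variances without matrixStats.
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
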