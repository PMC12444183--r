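#' Read a genes x samples expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; the body is numeric (FPKM, upper-quartile FPKM, or already
#' log-transformed values).
#'
#' @param path TSV path.
#' @param scale One of `"fpkm"`, `"fpkm_uq"`, `"log2_fpkm_uq_plus1"`; recorded
#'   as the matrix `scale` attribute.
#' @return Numeric matrix with gene rownames, sample colnames and a `scale`
#'   attribute.
#' @export
read_expression_tsv <- function(path, scale = c("log2_fpkm_uq_plus1", "fpkm", "fpkm_uq")) {
  scale <- match.arg(scale)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  validate_expression(mat, scale)
  expression_matrix(mat, scale = scale)
}

#' Tag a numeric matrix as an expression matrix
#'
#' @param mat Genes x samples numeric matrix with dimnames.
#' @param scale Expression scale tag.
#' @return The matrix with a validated `scale` attribute.
#' @export
expression_matrix <- function(mat, scale = c("log2_fpkm_uq_plus1", "fpkm", "fpkm_uq")) {
  scale <- match.arg(scale)
  validate_expression(mat, scale)
  attr(mat, "scale") <- scale
  mat
}

validate_expression <- function(mat, scale) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("Expression matrix needs gene rownames and sample colnames.", call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) stop("Duplicate gene identifiers.", call. = FALSE)
  if (anyDuplicated(colnames(mat))) stop("Duplicate sample identifiers.", call. = FALSE)
  if (!all(is.finite(mat))) stop("Expression matrix contains non-finite values.", call. = FALSE)
  if (scale %in% c("fpkm", "fpkm_uq") && any(mat < 0)) {
    stop("Negative values are invalid on the ", scale, " scale.", call. = FALSE)
  }
  invisible(mat)
}

#' Transform upper-quartile FPKM values to log2(fpkm-uq + 1)
#'
#' The representation used for depiction and (by default) for clustering
#' distances and gene-set scores.
#'
#' @param expr Expression matrix with scale `"fpkm_uq"` (or `"fpkm"`).
#' @return Matrix of identical shape with values `log2(v + 1)` and updated
#'   scale attribute.
#' @export
to_log2_fpkm_uq <- function(expr) {
  scale <- attr(expr, "scale") %||% "fpkm_uq"
  if (identical(scale, "log2_fpkm_uq_plus1")) {
    stop("Matrix is already on the log2(fpkm-uq+1) scale.", call. = FALSE)
  }
  if (any(expr < 0)) stop("Negative values cannot be log-transformed.", call. = FALSE)
  out <- log2(expr + 1)
  attr(out, "scale") <- "log2_fpkm_uq_plus1"
  out
}

#' Per-sample gene-set score
#'
#' A gene-set score is the unweighted average expression across all member
#' genes present in the matrix, computed per sample. Used, e.g., to relate
#' inflammatory to lipid-metabolic programs across a cohort.
#'
#' @param expr Genes x samples expression matrix.
#' @param set A one-row `lipo_gene_sets` tibble.
#' @return Tibble with columns `set_name`, `sample_id`, `score`, and
#'   `n_genes_used` (the member count after restriction to matrix rows).
#' @export
geneset_score <- function(expr, set) {
  r <- restrict_to_matrix(set, expr)
  genes <- r$set$genes[[1]]
  scores <- colMeans(expr[genes, , drop = FALSE])
  tibble::tibble(
    set_name = r$set$name,
    sample_id = colnames(expr),
    score = unname(scores),
    n_genes_used = length(genes)
  )
}

#' Percentile-normalize matrix rows to [0, 1]
#'
#' Each row is mapped through its within-row ranks: value `(rank - 1)/(n - 1)`
#' with ties receiving the mean of the ranks they span, so per row the minimum
#' maps to 0 and the maximum to 1 (when not globally tied). Constant rows map
#' to 0.5 everywhere with a warning. The heatmap normalization used to display
#' relative expression within samples.
#'
#' @param mat Numeric matrix with >= 2 columns.
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
percentile_normalize_rows <- function(mat) {
  if (ncol(mat) < 2L) stop("Need >= 2 samples to percentile-normalize.", call. = FALSE)
  n <- ncol(mat)
  out <- t(apply(mat, 1L, function(row) (rank(row, ties.method = "average") - 1) / (n - 1)))
  const <- apply(mat, 1L, function(row) max(row) == min(row))
  if (any(const)) {
    warning(sum(const), " constant row(s) mapped to 0.5.", call. = FALSE)
    out[const, ] <- 0.5
  }
  dimnames(out) <- dimnames(mat)
  out
}

#' Split samples at the median into low/high groups
#'
#' Values at or below the median are labeled `"low"`, values strictly above
#' `"high"` — the convention behind single-gene Kaplan-Meier comparisons.
#'
#' @param values Numeric vector (length >= 2, finite).
#' @return Factor with levels `low`, `high`, names preserved.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("Need >= 2 values for a median split.", call. = FALSE)
  if (!all(is.finite(values))) stop("Non-finite values in median split.", call. = FALSE)
  if (max(values) == min(values)) {
    stop("All values identical; median split undefined.", call. = FALSE)
  }
  m <- stats::median(values)
  out <- factor(ifelse(values <= m, "low", "high"), levels = c("low", "high"))
  names(out) <- names(values)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
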