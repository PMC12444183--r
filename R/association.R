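#' Pearson correlation with significance
#'
#' Pairs with any missing value are dropped; both vectors must be
#' non-constant after dropping. The two-sided p-value comes from the usual
#' t transform `t = r * sqrt((n - 2)/(1 - r^2))`.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return Tibble with columns `r`, `n`, `p.value`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("Need >= 3 complete pairs.", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Constant vector; correlation undefined.", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), n = length(x), p.value = ct$p.value)
}

#' Two-group comparison by Student's t-test
#'
#' Paired tests use the one-sample t on within-pair differences; unpaired
#' tests use the pooled-variance Student form by default, with Welch's
#' unequal-variance form behind a flag.
#'
#' @param a,b Numeric vectors (equal lengths when `paired`).
#' @param paired Paired test? Default `FALSE`.
#' @param welch Use Welch's correction for the unpaired test? Default `FALSE`.
#' @return Tibble with columns `t`, `df`, `p.value`.
#' @export
t_test <- function(a, b, paired = FALSE, welch = FALSE) {
  if (paired && length(a) != length(b)) stop("Paired test needs equal lengths.", call. = FALSE)
  degenerate <- if (paired) stats::sd(a - b) == 0 else stats::sd(c(a, b)) == 0
  if (is.na(degenerate) || degenerate) {
    stop("Zero-variance comparison; t-test undefined.", call. = FALSE)
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = !welch && !paired)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p.value = tt$p.value)
}

#' One-way ANOVA with Bonferroni post-hoc pairwise tests
#'
#' The omnibus F compares between- to within-group mean squares; pairwise
#' two-group Student t-tests are then adjusted by multiplying each p-value by
#' the number of pairs, capped at 1.
#'
#' @param values Numeric vector of observations (or a named list of >= 3
#'   group vectors, in which case `group` is ignored).
#' @param group Group labels aligned with `values`.
#' @return List with `anova` (one-row tibble: `F`, `df1`, `df2`, `p.value`)
#'   and `pairwise` (tibble: `group1`, `group2`, `t`, `p.value`, `p.adj`).
#' @export
anova_bonferroni <- function(values, group = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    group <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  ok <- stats::complete.cases(values, group)
  dropped <- sum(!ok)
  if (dropped) message("Dropping ", dropped, " incomplete observation(s).")
  values <- values[ok]; group <- factor(group[ok])
  if (nlevels(group) < 3L) stop("Need >= 3 groups.", call. = FALSE)
  if (any(table(group) < 2L)) stop("Each group needs >= 2 values.", call. = FALSE)
  if (stats::sd(values) == 0) stop("All values identical; ANOVA undefined.", call. = FALSE)
  fit <- stats::aov(values ~ group)
  sm <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(
    F = sm[["F value"]][1], df1 = sm[["Df"]][1], df2 = sm[["Df"]][2],
    p.value = sm[["Pr(>F)"]][1]
  )
  pairs <- utils::combn(levels(group), 2L)
  m <- ncol(pairs)
  pairwise <- purrr::map_dfr(seq_len(m), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    tt <- stats::t.test(values[group == g1], values[group == g2], var.equal = TRUE)
    tibble::tibble(group1 = g1, group2 = g2,
                   t = unname(tt$statistic), p.value = tt$p.value)
  })
  pairwise$p.adj <- pmin(1, pairwise$p.value * m)
  list(anova = anova_tbl, pairwise = pairwise)
}

#' Chi-square test of independence on a contingency table
#'
#' `sum (O - E)^2 / E` with expectations from the row/column margins and
#' `(r - 1)(c - 1)` degrees of freedom; no continuity correction.
#'
#' @param table Integer matrix of counts, at least 2 x 2.
#' @return Tibble with columns `statistic`, `df`, `p.value`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stop("Need at least a 2x2 table.", call. = FALSE)
  if (any(table < 0)) stop("Negative counts.", call. = FALSE)
  if (sum(table) == 0) stop("Empty table.", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("Zero row/column margin; expectations undefined.", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p.value = ct$p.value)
}

#' Correlate every lipid species with every cell-type frequency
#'
#' Computes per-pair Pearson correlations between the rows of a lipid-species
#' x sample table and the rows of a cell-frequency x sample table over their
#' shared samples, mirroring species-by-cell-type correlation panels.
#'
#' @param lipids Species x samples numeric matrix.
#' @param cells Cell-type x samples numeric matrix.
#' @param bonferroni Multiply p-values by the number of pairs (capped at 1)?
#'   Default `FALSE` (raw p-values).
#' @return Tibble with columns `species`, `cell_type`, `r`, `n`, `p.value`
#'   (and `p.adj` when `bonferroni`).
#' @export
correlate_tables <- function(lipids, cells, bonferroni = FALSE) {
  shared <- intersect(colnames(lipids), colnames(cells))
  if (length(shared) < 3L) stop("Need >= 3 shared samples.", call. = FALSE)
  grid <- tidyr::expand_grid(species = rownames(lipids), cell_type = rownames(cells))
  out <- purrr::pmap_dfr(grid, function(species, cell_type) {
    res <- pearson_cor(lipids[species, shared], cells[cell_type, shared])
    tibble::tibble(species = species, cell_type = cell_type,
                   r = res$r, n = res$n, p.value = res$p.value)
  })
  if (bonferroni) out$p.adj <- pmin(1, out$p.value * nrow(out))
  out
}
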