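#' Euclidean distance between samples over a gene set
#'
#' Distances are computed between sample expression profiles restricted to the
#' member genes of one gene set: `d(i,j) = sqrt(sum_g (x_gi - x_gj)^2)`.
#'
#' @param expr Genes x samples expression matrix.
#' @param set One-row `lipo_gene_sets` tibble.
#' @return Symmetric samples x samples matrix with zero diagonal and sample
#'   dimnames.
#' @export
euclidean_distance_matrix <- function(expr, set) {
  if (!all(is.finite(expr))) stop("Non-finite expression values.", call. = FALSE)
  if (ncol(expr) < 2L) stop("Need >= 2 samples.", call. = FALSE)
  r <- restrict_to_matrix(set, expr)
  sub <- expr[r$set$genes[[1]], , drop = FALSE]
  d <- as.matrix(stats::dist(t(sub), method = "euclidean"))
  diag(d) <- 0
  d
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("Distance matrix must be square.", call. = FALSE)
  if (any(d < 0)) stop("Distance matrix has negative entries.", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12 * max(1, max(abs(d)))) {
    stop("Distance matrix is not symmetric.", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("Distance matrix diagonal must be zero.", call. = FALSE)
  invisible(d)
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' Repeatedly merges the pair of clusters with the smallest mean inter-point
#' distance (Lance-Williams update). Ties in the minimal linkage distance are
#' broken deterministically towards the pair with lexicographically smallest
#' member indices, so results are bit-stable across platforms.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal (as from
#'   [euclidean_distance_matrix()]).
#' @return An object of class `hclust` (merge matrix, heights, order, labels),
#'   usable with [stats::cutree()] and `plot()`.
#' @export
average_linkage <- function(d) {
  check_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("Need >= 2 samples to cluster.", call. = FALSE)
  labels <- rownames(d) %||% as.character(seq_len(n))
  D <- (d + t(d)) / 2  # symmetrize exactly
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  code <- -seq_len(n)        # hclust codes: -obs or +merge step
  minmem <- seq_len(n)       # smallest original index in each cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))
  for (step in seq_len(n - 1L)) {
    Dact <- D
    Dact[!active, ] <- Inf
    Dact[, !active] <- Inf
    m <- min(Dact)
    hits <- which(Dact == m, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # deterministic tie-break: smallest (min member of first, then second)
    a <- pmin(minmem[hits[, 1]], minmem[hits[, 2]])
    b <- pmax(minmem[hits[, 1]], minmem[hits[, 2]])
    pick <- order(a, b)[1L]
    i <- hits[pick, 1]; j <- hits[pick, 2]
    ci <- code[i]; cj <- code[j]
    # hclust convention: singletons before merges, then ascending
    pair <- sort(c(ci, cj))
    merge[step, ] <- pair
    height[step] <- m
    ni <- size[i]; nj <- size[j]
    new_d <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    D[i, ] <- new_d
    D[, i] <- new_d
    D[i, i] <- Inf
    active[j] <- FALSE
    size[i] <- ni + nj
    code[i] <- step
    minmem[i] <- min(minmem[i], minmem[j])
    members[[i]] <- c(members[[i]], members[[j]])
  }
  out <- list(
    merge = merge, height = height,
    order = hclust_order(merge),
    labels = labels, method = "average",
    call = match.call(), dist.method = "euclidean"
  )
  class(out) <- "hclust"
  out
}

# leaf order for plotting, by recursive left-right traversal of the merge tree
hclust_order <- function(merge) {
  n <- nrow(merge) + 1L
  leaves <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    get_side <- function(v) if (v < 0) -v else leaves[[v]]
    leaves[[s]] <- c(get_side(merge[s, 1]), get_side(merge[s, 2]))
  }
  as.integer(leaves[[n - 1L]])
}

#' Cut a merge tree into a fixed number of flat clusters
#'
#' Undoes the last `k - 1` merges. Labels are renumbered by decreasing cluster
#' size (ties by first occurrence) so that reporting is stable.
#'
#' @param tree An `hclust` object from [average_linkage()].
#' @param k Number of clusters (the stratification uses a fixed cut of 20).
#' @return Named integer vector of cluster labels, one per sample.
#' @export
cut_tree <- function(tree, k) {
  n <- nrow(tree$merge) + 1L
  if (k < 1L || k > n) {
    stop("Cut depth k = ", k, " outside 1..", n, " (number of samples).", call. = FALSE)
  }
  raw <- stats::cutree(tree, k = k)
  relabel_by_size(raw)
}

relabel_by_size <- function(labels) {
  tab <- table(labels)
  ord <- names(tab)[order(-as.integer(tab), seq_along(tab))]
  map <- stats::setNames(seq_along(ord), ord)
  out <- as.integer(map[as.character(labels)])
  names(out) <- names(labels)
  out
}

#' Flag dominant clusters
#'
#' A cluster is "dominant" when it contains at least `dominant_fraction` of
#' all samples (inclusive threshold: exactly 25% of the cohort qualifies at
#' the default); smaller clusters are "minor" and are treated as outliers.
#'
#' @param labels Integer cluster labels.
#' @param dominant_fraction Fraction of the cohort required, default 0.25.
#' @return Sorted integer vector of dominant cluster ids (possibly empty).
#' @export
find_dominant <- function(labels, dominant_fraction = 0.25) {
  if (length(labels) == 0L) stop("Empty label vector.", call. = FALSE)
  if (dominant_fraction <= 0 || dominant_fraction > 1) {
    stop("dominant_fraction must be in (0, 1].", call. = FALSE)
  }
  tab <- table(labels)
  ids <- as.integer(names(tab)[as.integer(tab) >= dominant_fraction * length(labels)])
  sort(ids)
}

#' Number dominant clusters in decreasing order of overall survival
#'
#' Clusters are ranked by Kaplan-Meier restricted mean survival time (RMST,
#' area under the KM curve up to the largest observed time among
#' dominant-cluster samples): cluster 1 has the best survival. Ties are broken
#' towards the larger cluster, then the smaller raw id.
#'
#' @param labels Named integer cluster labels (names = sample ids).
#' @param dominant_ids Integer ids from [find_dominant()].
#' @param clinical Tibble with columns `sample_id`, `time`, `event`.
#' @return Named integer vector: names are raw dominant cluster ids, values
#'   their survival rank (1 = best).
#' @export
order_clusters_by_survival <- function(labels, dominant_ids, clinical) {
  if (length(dominant_ids) == 0L) stop("No dominant clusters to order.", call. = FALSE)
  ids <- names(labels)
  if (is.null(ids)) stop("Labels must be named by sample id.", call. = FALSE)
  miss <- setdiff(ids[labels %in% dominant_ids], clinical$sample_id)
  if (length(miss)) {
    stop("Missing survival records for sample(s): ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  cl <- clinical[match(ids, clinical$sample_id), ]
  dom_samples <- labels %in% dominant_ids
  tau <- max(cl$time[dom_samples])
  stats_tbl <- purrr::map_dfr(dominant_ids, function(id) {
    inx <- which(labels == id)
    tt <- cl$time[inx]; ee <- cl$event[inx]
    if (sum(ee) == 0 && all(tt == 0)) {
      stop("Dominant cluster ", id, " has zero events and zero follow-up; ",
           "survival ordering undefined.", call. = FALSE)
    }
    km <- km_estimate(tt, ee)
    tibble::tibble(id = id, rmst = km_rmst(km, tau), n = length(inx))
  })
  ord <- order(-stats_tbl$rmst, -stats_tbl$n, stats_tbl$id)
  ranks <- integer(nrow(stats_tbl))
  ranks[ord] <- seq_along(ord)
  stats::setNames(ranks, stats_tbl$id)
}

#' Mean silhouette score per dominant cluster
#'
#' Silhouette widths are computed only among samples of dominant clusters:
#' for sample `i`, `a(i)` is its mean distance to the other members of its
#' cluster and `b(i)` the smallest mean distance to any *other dominant*
#' cluster; `s(i) = (b - a)/max(a, b)`, with `s(i) = 0` for singleton clusters
#' or when `max(a, b) = 0`. Minor-cluster samples are excluded entirely.
#'
#' @param d Samples x samples distance matrix.
#' @param labels Integer cluster labels aligned with `d`.
#' @param dominant_ids At least two dominant cluster ids.
#' @return Tibble with columns `cluster`, `n`, `mean_silhouette`.
#' @export
mean_silhouette <- function(d, labels, dominant_ids) {
  check_distance_matrix(d)
  if (length(dominant_ids) < 2L) {
    stop("Silhouette undefined with fewer than two dominant clusters.", call. = FALSE)
  }
  keep <- which(labels %in% dominant_ids)
  Dsub <- d[keep, keep, drop = FALSE]
  lab <- labels[keep]
  k <- length(dominant_ids)
  M <- vapply(dominant_ids, function(id) as.numeric(lab == id), numeric(length(lab)))
  sums <- Dsub %*% M                       # per-sample sum of distances to each cluster
  sizes <- colSums(M)
  own <- match(lab, dominant_ids)
  idx <- cbind(seq_along(lab), own)
  a <- sums[idx] / pmax(sizes[own] - 1, 1)
  mean_other <- sweep(sums, 2L, sizes, "/")
  mean_other[idx] <- Inf
  b <- apply(mean_other, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[pmax(a, b) == 0] <- 0
  s[sizes[own] == 1] <- 0
  tibble::tibble(
    cluster = dominant_ids,
    n = as.integer(sizes),
    mean_silhouette = vapply(seq_len(k), function(j) mean(s[own == j]), numeric(1))
  )
}

#' Compare favorable-cluster membership across three clustering runs
#'
#' Counts the seven Venn regions (and the complement) of three sample sets
#' drawn from a common cohort — e.g., which patients are assigned to the
#' favorable cluster only when two gene sets are combined.
#'
#' @param favorable_a,favorable_b,favorable_combined Character vectors of
#'   sample ids.
#' @param cohort Character vector of all sample ids.
#' @return Tibble with columns `region` and `count`, rows summing to
#'   `length(cohort)`.
#' @export
compare_assignments <- function(favorable_a, favorable_b, favorable_combined, cohort) {
  sets <- list(A = favorable_a, B = favorable_b, C = favorable_combined)
  out_of <- setdiff(unique(unlist(sets)), cohort)
  if (length(out_of)) {
    stop("Sample(s) outside the cohort: ", paste(utils::head(out_of, 5L), collapse = ", "),
         call. = FALSE)
  }
  inA <- cohort %in% sets$A
  inB <- cohort %in% sets$B
  inC <- cohort %in% sets$C
  sample_region <- dplyr::case_when(
    inA & inB & inC ~ "A&B&C",
    inA & inB ~ "A&B",
    inA & inC ~ "A&C",
    inB & inC ~ "B&C",
    inA ~ "A_only",
    inB ~ "B_only",
    inC ~ "C_only",
    TRUE ~ "none"
  )
  region_names <- c("A_only", "B_only", "C_only", "A&B", "A&C", "B&C", "A&B&C", "none")
  counts <- vapply(region_names, function(l) sum(sample_region == l), integer(1))
  tibble::tibble(region = region_names, count = unname(counts))
}
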