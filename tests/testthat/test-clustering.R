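dist_1d <- function(x) {
  d <- as.matrix(stats::dist(matrix(x)))
  dimnames(d) <- list(paste0("s", seq_along(x)), paste0("s", seq_along(x)))
  d
}

test_that("euclidean distances over a gene set match the definition", {
  e <- expression_matrix(matrix(c(0, 0, 3, 4), 2,
                                dimnames = list(c("g1", "g2"), c("a", "b"))),
                         scale = "log2_fpkm_uq_plus1")
  d <- euclidean_distance_matrix(e, gene_sets(S = c("g1", "g2")))
  expect_equal(d["a", "b"], 5)  # 3-4-5 triangle
  expect_equal(diag(d), c(a = 0, b = 0))
  # identical samples -> 0
  e2 <- expression_matrix(cbind(e, c = e[, "a"]), scale = "log2_fpkm_uq_plus1")
  expect_equal(euclidean_distance_matrix(e2, gene_sets(S = c("g1", "g2")))["a", "c"], 0)
  # brute-force double loop on a random matrix
  set.seed(21)
  m <- expression_matrix(matrix(rnorm(5 * 4, 5), 5,
                                dimnames = list(paste0("g", 1:5), paste0("s", 1:4))),
                         scale = "log2_fpkm_uq_plus1")
  dm <- euclidean_distance_matrix(m, gene_sets(S = paste0("g", 1:5)))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(dm[i, j], sqrt(sum((m[, i] - m[, j])^2)), tolerance = 1e-12)
  }
})

test_that("average linkage reproduces the hand-computed 1-D tree", {
  d <- dist_1d(c(0, 1, 10))
  tree <- average_linkage(d)
  expect_equal(tree$height, c(1, 9.5))  # mean(10, 9) = 9.5
  labs <- cut_tree(tree, 2)
  expect_equal(labs[["s1"]], labs[["s2"]])
  expect_true(labs[["s3"]] != labs[["s1"]])
  # two samples -> single merge at their distance
  t2 <- average_linkage(dist_1d(c(0, 7)))
  expect_equal(t2$height, 7)
})

test_that("average linkage rejects invalid distance input", {
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(average_linkage(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2)
  expect_error(average_linkage(neg), "negative")
})

test_that("merge heights are monotone and labels are permutation-invariant on Euclidean input", {
  set.seed(31)
  for (rep in 1:5) {
    e <- expression_matrix(matrix(rnorm(6 * 25, 5), 6,
                                  dimnames = list(paste0("g", 1:6), paste0("s", 1:25))),
                           scale = "log2_fpkm_uq_plus1")
    set <- gene_sets(S = paste0("g", 1:6))
    d <- euclidean_distance_matrix(e, set)
    tree <- average_linkage(d)
    expect_true(all(diff(tree$height) >= -1e-12))
    labs <- cut_tree(tree, 4)
    perm <- sample(ncol(e))
    e2 <- expression_matrix(unclass(e)[, perm], scale = "log2_fpkm_uq_plus1")
    labs2 <- cut_tree(average_linkage(euclidean_distance_matrix(e2, set)), 4)
    expect_true(same_partition(labs[colnames(e2)], labs2))
  }
})

test_that("cut_tree covers the degenerate depths and rejects k > n", {
  set.seed(41)
  d <- as.matrix(stats::dist(matrix(rnorm(12), 6)))
  tree <- average_linkage(d)
  expect_equal(length(unique(cut_tree(tree, 6))), 6L)
  expect_equal(unique(cut_tree(tree, 1)), 1L)
  expect_error(cut_tree(tree, 7), "outside")
})

test_that("dominance threshold is inclusive at exactly 25%", {
  labels <- rep(1:3, c(60, 30, 10))
  expect_equal(find_dominant(labels), c(1L, 2L))
  labels2 <- rep(1:4, c(25, 40, 20, 15))
  expect_true(1L %in% find_dominant(labels2))  # exactly 25 of 100 qualifies
  labels3 <- rep(1:20, each = 5)
  expect_length(find_dominant(labels3), 0L)
})

test_that("clusters are numbered in decreasing order of overall survival", {
  # cluster 10: all alive at study end; cluster 20: all dead at t = 1
  labels <- stats::setNames(rep(c(10L, 20L), each = 5), paste0("p", 1:10))
  clinical <- tibble::tibble(
    sample_id = paste0("p", 1:10),
    time = c(rep(100, 5), rep(1, 5)),
    event = c(rep(0L, 5), rep(1L, 5))
  )
  num <- order_clusters_by_survival(labels, c(10L, 20L), clinical)
  expect_equal(num[["10"]], 1L)
  expect_equal(num[["20"]], 2L)
  # single dominant cluster gets number 1
  expect_equal(unname(order_clusters_by_survival(labels, 10L, clinical)), 1L)
  expect_error(order_clusters_by_survival(labels, c(10L, 20L), clinical[1:3, ]),
               "Missing survival")
})

test_that("higher-hazard clusters are numbered last across simulated replicates", {
  worse_gets_2 <- vapply(1:40, function(seed) {
    set.seed(seed + 1000)
    n <- 200
    labels <- stats::setNames(rep(c(1L, 2L), each = n), paste0("p", 1:(2 * n)))
    time <- c(rexp(n, 1), rexp(n, 3))  # cluster 2 has hazard ratio 3
    clinical <- tibble::tibble(sample_id = names(labels), time = time,
                               event = rep(1L, 2 * n))
    num <- order_clusters_by_survival(labels, c(1L, 2L), clinical)
    num[["2"]] == 2L
  }, logical(1))
  expect_gte(mean(worse_gets_2), 0.95)
})

test_that("silhouette matches the hand-evaluated 1-D example and conventions", {
  d <- dist_1d(c(0, 1, 10, 11))
  labels <- c(1L, 1L, 2L, 2L)
  ms <- mean_silhouette(d, labels, c(1L, 2L))
  expect_equal(ms$mean_silhouette[1], (9.5 / 10.5 + 8.5 / 9.5) / 2, tolerance = 1e-12)
  expect_equal(ms$mean_silhouette[1], ms$mean_silhouette[2], tolerance = 1e-12)
  # coincident clusters -> all widths 0 by convention
  d0 <- matrix(0, 4, 4)
  expect_equal(mean_silhouette(d0, labels, c(1L, 2L))$mean_silhouette, c(0, 0))
  expect_error(mean_silhouette(d, rep(1L, 4), 1L), "fewer than two")
})

test_that("silhouette ignores minor clusters entirely", {
  # a far-away minor point must not perturb dominant-cluster widths
  d <- dist_1d(c(0, 1, 10, 11, 500))
  labels <- c(1L, 1L, 2L, 2L, 3L)
  ms <- mean_silhouette(d, labels, c(1L, 2L))
  ref <- mean_silhouette(dist_1d(c(0, 1, 10, 11)), labels[1:4], c(1L, 2L))
  expect_equal(ms$mean_silhouette, ref$mean_silhouette, tolerance = 1e-12)
})

test_that("Venn region counts enumerate three favorable sets over a cohort", {
  venn <- compare_assignments(c("1", "2"), c("2", "3"), c("2", "3", "4"),
                              cohort = as.character(1:5))
  counts <- stats::setNames(venn$count, venn$region)
  expect_equal(unname(counts[c("A_only", "A&B&C", "B&C", "C_only", "none")]),
               c(1L, 1L, 1L, 1L, 1L))
  expect_equal(sum(venn$count), 5L)
  # all-equal sets put everything in the triple intersection
  v2 <- compare_assignments(c("a", "b"), c("a", "b"), c("a", "b"), c("a", "b", "c"))
  expect_equal(v2$count[v2$region == "A&B&C"], 2L)
  # disjoint singletons
  v3 <- compare_assignments("a", "b", "c", c("a", "b", "c"))
  expect_equal(unname(v3$count[v3$region %in% c("A_only", "B_only", "C_only")]),
               c(1L, 1L, 1L))
  expect_error(compare_assignments("z", "b", "c", c("a", "b", "c")), "outside")
})

test_that("the dominant-cluster structure is robust to the linkage choice", {
  # complete linkage fragments large groups at a deep fixed cut, so the
  # robustness comparison uses its top-level split against the average-linkage
  # dominant partition
  co <- simulate_cohort(cohort_config(seed = 17))
  d <- euclidean_distance_matrix(co$expr, co$sets)
  labs_avg <- cut_tree(average_linkage(d), 20)
  dom_avg <- find_dominant(labs_avg)
  labs_comp <- stats::cutree(stats::hclust(stats::as.dist(d), method = "complete"), 2)
  keep <- labs_avg %in% dom_avg
  ari <- mclust::adjustedRandIndex(labs_avg[keep], labs_comp[keep])
  expect_gte(ari, 0.8)
})
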