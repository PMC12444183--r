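# Independent brute-force oracles; deliberately naive and loop-based so they
# share no code path with the package implementations they check.

# silhouette widths by direct per-point evaluation of (b - a)/max(a, b)
naive_silhouette <- function(d, labels, dominant_ids) {
  keep <- which(labels %in% dominant_ids)
  res <- lapply(dominant_ids, function(id) {
    members <- keep[labels[keep] == id]
    s_vals <- vapply(members, function(i) {
      own <- setdiff(members, i)
      if (length(own) == 0) return(0)
      a <- mean(d[i, own])
      b <- min(vapply(setdiff(dominant_ids, id), function(other) {
        mean(d[i, keep[labels[keep] == other]])
      }, numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    mean(s_vals)
  })
  data.frame(cluster = dominant_ids, mean_silhouette = unlist(res))
}

# UPGMA by O(n^3) re-scan: at every step recompute all pairwise mean
# inter-cluster distances from the raw matrix; same lexicographic tie-break.
# Returns merge heights and the list of partitions after each merge.
naive_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        dist_ij <- mean(d[clusters[[i]], clusters[[j]]])
        key <- c(dist_ij,
                 min(min(clusters[[i]]), min(clusters[[j]])),
                 max(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) ||
            key[1] < best$key[1] - 1e-12 ||
            (abs(key[1] - best$key[1]) <= 1e-12 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    heights <- c(heights, best$key[1])
    labels <- integer(n)
    for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1L]] <- labels
  }
  list(heights = heights, partitions = partitions)
}

same_partition <- function(a, b) {
  identical(as.integer(match(a, unique(a))), as.integer(match(b, unique(b))))
}

# log-rank by direct accumulation of O, E and hypergeometric V (two groups)
naive_logrank_2g <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  O1 <- E1 <- V1 <- 0
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V1 <- V1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V1
}

# Cox log partial likelihood (no ties) evaluated directly; used for a
# grid-search maximizer oracle
naive_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# small deterministic synthetic cohort for pipeline tests
tiny_cohort <- function(seed = 11, n = 120) {
  cfg <- cohort_config(n_samples = n, n_background_genes = 60L,
                       signal_sets = tibble::tibble(name = "SIG", size = 20L, shift = 2.5),
                       seed = seed)
  simulate_cohort(cfg)
}
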