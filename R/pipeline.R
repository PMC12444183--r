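#' End-to-end prognostic stratification of an expression cohort
#'
#' Runs the full analysis chain on one gene set (or a combination): restrict
#' the expression matrix to the set, compute Euclidean sample distances,
#' average-linkage clustering cut at a fixed depth, flag dominant clusters
#' (>= `dominant_fraction` of the cohort), number them in decreasing order of
#' overall survival, score their stability by mean silhouette, compare their
#' survival by Kaplan-Meier/log-rank, and fit a Cox proportional-hazards
#' model with one-hot TNM stage, linear age and an "is cluster 1" indicator.
#' With fewer than two dominant clusters the run degrades gracefully to a
#' single-dominant-cluster outcome instead of failing.
#'
#' @param expr Genes x samples expression matrix.
#' @param clinical Clinical tibble (`sample_id`, `time`, `event`, stages, `age`).
#' @param sets A `lipo_gene_sets` tibble.
#' @param use_sets Character vector of set names; more than one name combines
#'   the sets by membership union.
#' @param k Fixed cut depth (default 20 clusters).
#' @param dominant_fraction Dominance threshold (default 0.25, inclusive).
#' @param exclude_stages Optional stage categories to drop before analysis
#'   (e.g. `c("T3", "T4")` to exclude large tumors).
#' @param stage_levels,reference Passed to [one_hot_encode()].
#' @param fit_cox Fit the confounder-adjusted Cox model? Default `TRUE`.
#' @return A `lipo_strat` object: `assignments` tibble (per-sample
#'   `raw_label`, `dominant`, `cluster_number`), `silhouette`, `km`
#'   (`lipo_km_set`), `logrank`, `cox`, `outcome`, `tree`, and run metadata.
#' @export
run_stratification <- function(expr, clinical, sets, use_sets,
                               k = 20L, dominant_fraction = 0.25,
                               exclude_stages = NULL,
                               stage_levels = list(t_stage = c("T1", "T2", "T3", "T4"),
                                                   n_stage = c("N0", "N1"),
                                                   m_stage = c("M0", "M1")),
                               reference = NULL,
                               fit_cox = TRUE) {
  shared <- intersect(colnames(expr), clinical$sample_id)
  if (length(shared) < 2L) {
    stop("Expression and clinical tables share fewer than 2 samples.", call. = FALSE)
  }
  clinical <- clinical[match(shared, clinical$sample_id), ]
  if (!is.null(exclude_stages)) {
    stage_cols <- intersect(c("t_stage", "n_stage", "m_stage"), names(clinical))
    excl <- rep(FALSE, nrow(clinical))
    for (col in stage_cols) excl <- excl | clinical[[col]] %in% exclude_stages
    if (any(excl)) {
      message("Excluding ", sum(excl), " sample(s) in stage(s) ",
              paste(exclude_stages, collapse = ", "), ".")
    }
    clinical <- clinical[!excl, ]
    shared <- clinical$sample_id
  }
  expr <- expr[, shared, drop = FALSE]

  set <- if (length(use_sets) > 1L) {
    combine_sets(sets, new_name = paste(use_sets, collapse = "+"), which = use_sets)
  } else {
    get_set(sets, use_sets)
  }
  n <- ncol(expr)
  k_eff <- min(as.integer(k), n)
  d <- euclidean_distance_matrix(expr, set)
  tree <- average_linkage(d)
  labels <- cut_tree(tree, k_eff)
  dominant_ids <- find_dominant(labels, dominant_fraction)

  assignments <- tibble::tibble(
    sample_id = shared,
    raw_label = unname(labels),
    dominant = unname(labels) %in% dominant_ids,
    cluster_number = NA_integer_
  )
  silhouette <- NULL; logrank <- NULL; cox <- NULL; km <- NULL
  numbering <- NULL
  outcome <- if (length(dominant_ids) >= 2L) "stratified"
             else if (length(dominant_ids) == 1L) "single_dominant_cluster"
             else "no_dominant_cluster"

  if (length(dominant_ids) >= 1L) {
    numbering <- order_clusters_by_survival(labels, dominant_ids, clinical)
    assignments$cluster_number <-
      unname(numbering[as.character(assignments$raw_label)])
    dom <- assignments$dominant
    km <- km_curves(clinical$time[dom], clinical$event[dom],
                    group = paste0("cluster ", assignments$cluster_number[dom]))
  }
  if (outcome == "stratified") {
    silhouette <- mean_silhouette(d, labels, dominant_ids)
    silhouette$cluster_number <- unname(numbering[as.character(silhouette$cluster)])
    dom <- assignments$dominant
    logrank <- logrank_test(clinical$time[dom], clinical$event[dom],
                            group = assignments$cluster_number[dom])
  }
  if (fit_cox && outcome == "stratified" &&
      all(c("t_stage", "n_stage", "m_stage", "age") %in% names(clinical))) {
    is_c1 <- !is.na(assignments$cluster_number) & assignments$cluster_number == 1L
    design <- one_hot_encode(clinical, stage_levels = stage_levels,
                             reference = reference, cluster1 = is_c1)
    keep <- match(rownames(design), clinical$sample_id)
    cox <- cox_fit(clinical$time[keep], clinical$event[keep], design)
  }

  out <- list(
    assignments = assignments,
    dominant_ids = dominant_ids,
    numbering = numbering,
    silhouette = silhouette,
    km = km,
    logrank = logrank,
    cox = cox,
    tree = tree,
    outcome = outcome,
    set_name = set$name,
    n_genes_used = length(set$genes[[1]]),
    config = list(use_sets = use_sets, k = k_eff,
                  dominant_fraction = dominant_fraction,
                  exclude_stages = exclude_stages,
                  input_scale = attr(expr, "scale") %||% "unknown",
                  n_samples = n)
  )
  class(out) <- "lipo_strat"
  out
}

#' @export
print.lipo_strat <- function(x, ...) {
  cat("Stratification on gene set '", x$set_name, "' (", x$n_genes_used,
      " genes, n = ", x$config$n_samples, ", cut at k = ", x$config$k, ")\n",
      sep = "")
  cat("Outcome: ", x$outcome, "; dominant clusters: ",
      length(x$dominant_ids), "\n", sep = "")
  if (!is.null(x$silhouette)) {
    print(dplyr::select(x$silhouette, "cluster_number", "n", "mean_silhouette"))
  }
  if (!is.null(x$logrank)) {
    cat("Log-rank across dominant clusters: chi-square = ",
        format(x$logrank$statistic, digits = 4), ", p = ",
        format.pval(x$logrank$p.value, digits = 3), "\n", sep = "")
  }
  if (!is.null(x$cox)) {
    cat("Cox model (", x$cox$ties, " ties):\n", sep = "")
    print(tidy(x$cox), n = Inf)
  }
  invisible(x)
}

#' @export
tidy.lipo_strat <- function(x, ...) x$assignments

#' @export
glance.lipo_strat <- function(x, ...) {
  hr_c1 <- if (!is.null(x$cox) && "is_cluster1" %in% names(x$cox$hazard_ratio)) {
    unname(x$cox$hazard_ratio[["is_cluster1"]])
  } else NA_real_
  tibble::tibble(
    set_name = x$set_name,
    n = x$config$n_samples,
    k = x$config$k,
    n_dominant = length(x$dominant_ids),
    outcome = x$outcome,
    logrank_stat = if (is.null(x$logrank)) NA_real_ else x$logrank$statistic,
    logrank_p = if (is.null(x$logrank)) NA_real_ else x$logrank$p.value,
    cluster1_hazard_ratio = hr_c1
  )
}

#' @export
autoplot.lipo_strat <- function(object, ...) {
  if (is.null(object$km)) stop("No dominant-cluster KM curves to plot.", call. = FALSE)
  autoplot(object$km) +
    ggplot2::labs(title = paste0("Overall survival by dominant cluster (",
                                 object$set_name, ")"))
}

#' Samples assigned to the prognostically favorable cluster
#'
#' The favorable cluster is the dominant cluster numbered 1 (best survival).
#' Runs without at least two dominant clusters have, by convention, an empty
#' favorable set.
#'
#' @param run A `lipo_strat` object.
#' @return Character vector of sample ids (possibly empty).
#' @export
favorable_samples <- function(run) {
  if (run$outcome != "stratified") return(character(0))
  run$assignments$sample_id[!is.na(run$assignments$cluster_number) &
                              run$assignments$cluster_number == 1L]
}

#' Compare single-set runs against a combined-set run
#'
#' Counts the Venn regions of favorable-cluster membership across two
#' single-set runs and their combined-set run (which patients are found
#' favorable only by the combination?) and puts dominant-cluster silhouette
#' means side by side.
#'
#' @param run_a,run_b,run_combined `lipo_strat` objects from the same cohort.
#' @return List with `venn` (region-count tibble; regions `A`/`B`/`C` are
#'   `run_a`/`run_b`/`run_combined`) and `silhouette` (per-run tibble).
#' @export
compare_gene_set_runs <- function(run_a, run_b, run_combined) {
  runs <- list(A = run_a, B = run_b, C = run_combined)
  cohorts <- purrr::map(runs, function(r) sort(r$assignments$sample_id))
  if (!all(purrr::map_lgl(cohorts[-1], identical, cohorts[[1]]))) {
    stop("Runs were not performed on identical cohorts.", call. = FALSE)
  }
  venn <- compare_assignments(favorable_samples(run_a),
                              favorable_samples(run_b),
                              favorable_samples(run_combined),
                              cohort = cohorts[[1]])
  sil <- purrr::imap_dfr(runs, function(r, key) {
    if (is.null(r$silhouette)) return(tibble::tibble())
    dplyr::mutate(r$silhouette, run = key, set_name = r$set_name,
                  .before = 1L)
  })
  list(venn = venn, silhouette = sil)
}

#' Write a stratification report directory
#'
#' Emits the on-disk artifacts of a run: `clusters.tsv`, `km_curves.tsv`,
#' `logrank.json`, `cox_table.tsv`, `silhouette.json`, `run_config.json`.
#'
#' @param run A `lipo_strat` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_stratification_report <- function(run, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("write_stratification_report() needs the jsonlite package.", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$assignments, file.path(dir, "clusters.tsv"), progress = FALSE)
  if (!is.null(run$km)) {
    readr::write_tsv(tibble::as_tibble(run$km), file.path(dir, "km_curves.tsv"),
                     progress = FALSE)
  }
  if (!is.null(run$logrank)) {
    jsonlite::write_json(tidy(run$logrank), file.path(dir, "logrank.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$cox)) {
    readr::write_tsv(tidy(run$cox), file.path(dir, "cox_table.tsv"), progress = FALSE)
  }
  if (!is.null(run$silhouette)) {
    jsonlite::write_json(run$silhouette, file.path(dir, "silhouette.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(c(run$config, list(set_name = run$set_name,
                                          n_genes_used = run$n_genes_used,
                                          outcome = run$outcome)),
                       file.path(dir, "run_config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Placeholder for differential-expression comparison between clusters
#'
#' Differential expression between dominant clusters (TMM-normalized edgeR
#' fits in the original analyses) is outside this package's scope; this stub
#' records the interface where such a comparison would plug in.
#'
#' @param run A `lipo_strat` object.
#' @return Never returns; signals a "not implemented" condition.
#' @export
differential_expression_stub <- function(run) {
  stop("Differential expression between clusters is not implemented here; ",
       "export the cluster assignments (tidy(run)) to a dedicated DE tool.",
       call. = FALSE)
}
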