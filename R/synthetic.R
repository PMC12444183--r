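#' Configuration for a synthetic survival-linked expression cohort
#'
#' Defines the generative model the stratification pipeline assumes: a latent
#' patient grouping that shifts the means of designated "signal" gene sets on
#' the log2 expression scale, proportional-hazards survival whose log-hazard
#' depends on the latent group, TNM stage and (centered) age, and independent
#' censoring (administrative horizon plus an exponential dropout process).
#'
#' @param n_samples Cohort size.
#' @param n_background_genes Number of group-independent noise genes.
#' @param signal_sets Tibble with columns `name`, `size`, `shift`: one row per
#'   signal gene set; `shift` is the between-group mean separation in units of
#'   the within-group SD.
#' @param group_proportions Latent group proportions (sum to 1; >= 2 groups).
#' @param within_group_sd Within-group expression SD (log2 units).
#' @param baseline_mean Baseline log2 expression mean.
#' @param baseline_hazard Exponential baseline hazard (per day) for latent
#'   group 1 at mean age in the reference stages.
#' @param weibull_shape Weibull shape of the baseline (1 = exponential).
#' @param log_hazard_group Per-group log-hazard offsets (first entry 0 makes
#'   group 1 the favorable, lower-hazard group).
#' @param log_hazard_age Log-hazard per year of age (age is centered at
#'   `age_mean` inside the hazard).
#' @param log_hazard_stage Named list of per-category log-hazard offsets for
#'   `t_stage`, `n_stage`, `m_stage`.
#' @param stage_freq Named list of category sampling frequencies.
#' @param censor_admin Administrative censoring horizon (days).
#' @param censor_rate Rate of the independent exponential censoring process.
#' @param age_mean,age_sd,age_bounds Age distribution (truncated normal).
#' @param seed Integer seed; a fixed seed makes [simulate_cohort()] fully
#'   reproducible.
#' @return A `lipo_cohort_config` list.
#' @export
cohort_config <- function(n_samples = 300L,
                          n_background_genes = 470L,
                          signal_sets = tibble::tibble(name = "SIG", size = 30L, shift = 2.0),
                          group_proportions = c(0.5, 0.5),
                          within_group_sd = 1,
                          baseline_mean = 6,
                          baseline_hazard = 1 / 2000,
                          weibull_shape = 1,
                          log_hazard_group = c(0, log(3)),
                          log_hazard_age = 0.02,
                          log_hazard_stage = list(
                            t_stage = c(T1 = 0, T2 = 0.3, T3 = 0.7, T4 = 1.0),
                            n_stage = c(N0 = 0, N1 = 0.5),
                            m_stage = c(M0 = 0, M1 = 1.0)
                          ),
                          stage_freq = list(
                            t_stage = c(T1 = 0.50, T2 = 0.12, T3 = 0.30, T4 = 0.08),
                            n_stage = c(N0 = 0.80, N1 = 0.20),
                            m_stage = c(M0 = 0.85, M1 = 0.15)
                          ),
                          censor_admin = 3000,
                          censor_rate = 1 / 6000,
                          age_mean = 60, age_sd = 10, age_bounds = c(30, 90),
                          seed = 1L) {
  if (abs(sum(group_proportions) - 1) > 1e-8) {
    stop("group_proportions must sum to 1.", call. = FALSE)
  }
  if (length(log_hazard_group) != length(group_proportions)) {
    stop("log_hazard_group must match group_proportions in length.", call. = FALSE)
  }
  if (baseline_hazard <= 0 || censor_rate <= 0 || weibull_shape <= 0) {
    stop("Rates and shape must be > 0.", call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "lipo_cohort_config"
  cfg
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a survival-linked expression cohort
#'
#' Draws a latent grouping, an expression matrix in which only the signal
#' gene sets separate the groups, and proportional-hazards survival times
#' with stage/age confounding and independent censoring (see
#' [cohort_config()] for the model).
#'
#' @param config A [cohort_config()] object.
#' @return List with `expr` (genes x samples log2-scale matrix), `clinical`
#'   (tibble: `sample_id`, `time`, `event`, stages, `age`), `truth` (tibble:
#'   `sample_id`, `group`), `sets` (the signal gene sets as
#'   `lipo_gene_sets`), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "lipo_cohort_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    props <- config$group_proportions
    # largest-remainder apportionment, robust to floating-point group targets
    target <- props * n
    sizes <- floor(target + 1e-9)
    short <- n - sum(sizes)
    if (short > 0) {
      top_up <- order(target - sizes, decreasing = TRUE)[seq_len(short)]
      sizes[top_up] <- sizes[top_up] + 1L
    }
    if (any(sizes < 1L)) {
      stop("group_proportions leave a group with < 1 sample.", call. = FALSE)
    }
    group <- sample(rep(seq_along(props), sizes))
    sample_ids <- sprintf("S%04d", seq_len(n))

    ss <- config$signal_sets
    sig_genes <- purrr::map2(ss$name, ss$size,
                             function(nm, sz) sprintf("%s_%03d", nm, seq_len(sz)))
    bg_genes <- sprintf("BG_%04d", seq_len(config$n_background_genes))
    gene_ids <- c(unlist(sig_genes), bg_genes)
    n_genes <- length(gene_ids)

    sd0 <- config$within_group_sd
    mat <- matrix(stats::rnorm(n_genes * n, mean = config$baseline_mean, sd = sd0),
                  nrow = n_genes, dimnames = list(gene_ids, sample_ids))
    # group-specific offsets for signal genes: equally spaced, consecutive
    # groups separated by shift * sd
    g_centered <- group - (length(props) + 1) / 2
    for (k in seq_len(nrow(ss))) {
      offs <- g_centered * ss$shift[k] * sd0
      mat[sig_genes[[k]], ] <- mat[sig_genes[[k]], ] +
        matrix(offs, nrow = ss$size[k], ncol = n, byrow = TRUE)
    }
    mat <- pmax(mat, 0)  # log2(fpkm-uq+1) values are non-negative
    expr <- expression_matrix(mat, scale = "log2_fpkm_uq_plus1")

    age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                     config$age_bounds[1]), config$age_bounds[2])
    stages <- purrr::imap(config$stage_freq, function(freq, col) {
      sample(names(freq), n, replace = TRUE, prob = freq)
    })
    log_h <- config$log_hazard_group[group] +
      config$log_hazard_age * (age - config$age_mean) +
      config$log_hazard_stage$t_stage[stages$t_stage] +
      config$log_hazard_stage$n_stage[stages$n_stage] +
      config$log_hazard_stage$m_stage[stages$m_stage]
    hazard <- config$baseline_hazard * exp(unname(log_h))
    u <- stats::runif(n)
    event_time <- (-log(u) / hazard)^(1 / config$weibull_shape)
    censor_time <- pmin(config$censor_admin, stats::rexp(n, config$censor_rate))
    time <- pmin(event_time, censor_time)
    event <- as.integer(event_time <= censor_time)

    clinical <- tibble::tibble(
      sample_id = sample_ids, time = time, event = event,
      t_stage = stages$t_stage, n_stage = stages$n_stage, m_stage = stages$m_stage,
      age = age
    )
    sets <- gene_sets(stats::setNames(sig_genes, ss$name), description = "synthetic signal set")
    list(expr = expr, clinical = clinical,
         truth = tibble::tibble(sample_id = sample_ids, group = group),
         sets = sets, config = config)
  })
}

#' Configuration for paired lipid-species and immune-frequency tables
#'
#' A Gaussian-copula generator: jointly normal latents with identity
#' within-block correlation and a configurable species-by-cell-type
#' cross-correlation block; species are mapped to normal marginals and cell
#' frequencies through a logistic transform onto \[0, 100\]%.
#'
#' @param n_samples Number of samples.
#' @param species Lipid species names.
#' @param cell_types Immune cell-type names.
#' @param cross_cor Species x cell-type target correlation matrix (entries in
#'   \[-1, 1\]; the implied joint matrix must be positive semi-definite).
#' @param species_mean,species_sd Marginal mean/SD per species (recycled).
#' @param freq_mean Marginal mean frequency per cell type, in percent.
#' @param freq_sd_logit Latent SD on the logit scale (small values keep the
#'   transform near-linear so realized correlations track the target).
#' @param seed Integer seed.
#' @return A `lipo_lipid_config` list.
#' @export
lipid_immune_config <- function(n_samples = 30L,
                                species = c("CE 18:1", "CE 18:2", "TG 52:2", "LPC 16:0"),
                                cell_types = c("CD4", "CD8"),
                                cross_cor = matrix(0, length(species), length(cell_types),
                                                   dimnames = list(species, cell_types)),
                                species_mean = 10, species_sd = 2,
                                freq_mean = 30, freq_sd_logit = 0.5,
                                seed = 1L) {
  cross_cor <- as.matrix(cross_cor)
  if (!all(dim(cross_cor) == c(length(species), length(cell_types)))) {
    stop("cross_cor must be species x cell_types.", call. = FALSE)
  }
  if (any(abs(cross_cor) > 1)) stop("Correlations must lie in [-1, 1].", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "lipo_lipid_config"
  cfg
}

#' Simulate paired lipid and immune-frequency tables with known correlation
#'
#' @param config A [lipid_immune_config()] object.
#' @return List with `lipids` (species x samples), `cells` (cell-type x
#'   samples, percent), `truth` (target cross-correlation matrix), `config`.
#' @export
simulate_lipid_immune <- function(config = lipid_immune_config()) {
  stopifnot(inherits(config, "lipo_lipid_config"))
  s <- length(config$species); k <- length(config$cell_types)
  R <- rbind(cbind(diag(s), config$cross_cor),
             cbind(t(config$cross_cor), diag(k)))
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("Target correlation structure is not positive semi-definite ",
         "(smallest eigenvalue ", format(min(ev$values), digits = 3), ").",
         call. = FALSE)
  }
  with_seed(config$seed, {
    n <- config$n_samples
    Z <- matrix(stats::rnorm(n * (s + k)), n) %*%
      (ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), s + k) %*% t(ev$vectors))
    zl <- Z[, seq_len(s), drop = FALSE]
    zc <- Z[, s + seq_len(k), drop = FALSE]
    lipids <- t(sweep(sweep(zl, 2L, rep_len(config$species_sd, s), "*"),
                      2L, rep_len(config$species_mean, s), "+"))
    rownames(lipids) <- config$species
    mu_logit <- stats::qlogis(rep_len(config$freq_mean, k) / 100)
    cells <- t(100 * stats::plogis(sweep(zc * config$freq_sd_logit, 2L, mu_logit, "+")))
    rownames(cells) <- config$cell_types
    ids <- sprintf("S%04d", seq_len(n))
    colnames(lipids) <- colnames(cells) <- ids
    list(lipids = lipids, cells = cells, truth = config$cross_cor, config = config)
  })
}

#' Write a simulated cohort to the pipeline's TSV dialects
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, "expression.tsv")
  clin_path <- file.path(dir, "clinical.tsv")
  gmt_path <- file.path(dir, "gene_sets.gmt")
  expr_df <- tibble::as_tibble(cohort$expr, rownames = "gene_id")
  readr::write_tsv(expr_df, expr_path, progress = FALSE)
  clin <- dplyr::rename(cohort$clinical, time_days = "time")
  readr::write_tsv(clin, clin_path, progress = FALSE)
  lines <- purrr::pmap_chr(cohort$sets, function(name, description, genes) {
    paste(c(name, description, genes), collapse = "\t")
  })
  writeLines(lines, gmt_path)
  invisible(c(expr = expr_path, clinical = clin_path, gmt = gmt_path))
}
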