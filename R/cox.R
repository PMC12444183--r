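#' One-hot design matrix for TNM stage, linear age, and cluster membership
#'
#' Builds the covariate matrix for the confounder-adjusted Cox model: one
#' indicator column per non-reference category of each of the T, N and M
#' stages, age in years as a single linear column, and optionally an
#' "is cluster 1" indicator for membership in the prognostically favorable
#' cluster. Reference categories (by default the lowest stage: T1, N0, M0)
#' produce no column. Subjects whose stage is missing or unassessable
#' (`TX`/`NX`/`MX`/`NA`) are dropped with a message.
#'
#' @param clinical Tibble with columns `sample_id`, and the stage/age columns
#'   being encoded.
#' @param stage_levels Named list of declared category levels per stage
#'   column, in order; the first level is the reference unless overridden.
#' @param reference Named character vector of reference categories.
#' @param age Include the linear age column? Default `TRUE`.
#' @param cluster1 Optional logical vector (aligned with `clinical` rows) or
#'   the name of a logical column in `clinical`, encoded as `is_cluster1`.
#' @param missing_codes Stage codes treated as missing.
#' @return Numeric design matrix with `sample_id` rownames; dropped sample
#'   ids are in `attr(, "dropped")` and the reference categories in
#'   `attr(, "reference")`.
#' @export
one_hot_encode <- function(clinical,
                           stage_levels = list(t_stage = c("T1", "T2", "T3", "T4"),
                                               n_stage = c("N0", "N1"),
                                               m_stage = c("M0", "M1")),
                           reference = NULL,
                           age = TRUE,
                           cluster1 = NULL,
                           missing_codes = c("TX", "NX", "MX")) {
  stage_cols <- intersect(names(stage_levels), names(clinical))
  if (is.character(cluster1) && length(cluster1) == 1L) {
    cluster1 <- clinical[[cluster1]]
  }
  if (!is.null(cluster1)) {
    stopifnot(length(cluster1) == nrow(clinical))
    cluster1 <- as.logical(cluster1)
  }
  # drop missing-stage subjects
  is_missing <- rep(FALSE, nrow(clinical))
  for (col in stage_cols) {
    v <- as.character(clinical[[col]])
    unseen <- setdiff(stats::na.omit(unique(v)), c(stage_levels[[col]], missing_codes))
    if (length(unseen)) {
      stop("Unseen ", col, " categor(ies): ", paste(unseen, collapse = ", "), call. = FALSE)
    }
    is_missing <- is_missing | is.na(v) | v %in% missing_codes
  }
  if (age && any(is.na(clinical$age))) is_missing <- is_missing | is.na(clinical$age)
  dropped <- clinical$sample_id[is_missing]
  if (length(dropped)) {
    message("Dropping ", length(dropped), " subject(s) with missing stage/age.")
  }
  keep <- !is_missing
  cl <- clinical[keep, ]
  if (!is.null(cluster1)) cluster1 <- cluster1[keep]

  blocks <- list()
  ref_used <- character(0)
  for (col in stage_cols) {
    lev <- stage_levels[[col]]
    ref <- if (!is.null(reference) && col %in% names(reference)) reference[[col]] else lev[1]
    if (!ref %in% lev) stop("Reference ", ref, " not among levels of ", col, call. = FALSE)
    ref_used[col] <- ref
    for (l in setdiff(lev, ref)) {
      ind <- as.numeric(cl[[col]] == l)
      if (any(ind > 0)) blocks[[l]] <- ind  # unobserved categories yield no column
    }
  }
  if (age) blocks[["age"]] <- as.numeric(cl$age)
  if (!is.null(cluster1)) blocks[["is_cluster1"]] <- as.numeric(cluster1)
  if (length(blocks) == 0L) stop("Design matrix has no columns.", call. = FALSE)
  X <- do.call(cbind, blocks)
  rownames(X) <- cl$sample_id
  attr(X, "dropped") <- dropped
  attr(X, "reference") <- ref_used
  X
}

#' Fit a Cox proportional-hazards model by partial likelihood
#'
#' Newton-Raphson maximization of the Cox log partial likelihood with the
#' Efron correction for tied event times (Breslow available), step-halving,
#' and convergence declared at gradient norm below `tol`. Standard errors
#' come from the inverse observed information; p-values are two-sided Wald.
#'
#' @param time Follow-up durations.
#' @param event Event indicators (0/1), at least one event.
#' @param design Numeric covariate matrix (rows = subjects), full column
#'   rank; see [one_hot_encode()].
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol Convergence tolerance on the max absolute score component,
#'   scaled by `max(1, |log partial likelihood|)`.
#' @param max_iter Newton iteration cap.
#' @return A `lipo_cox` object with per-term `coefficients`, `hazard_ratio`
#'   (`exp(coef)`), `se`, `z` and Wald `p.value`; supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
cox_fit <- function(time, event, design, ties = c("efron", "breslow"),
                    tol = 1e-8, max_iter = 100L) {
  ties <- match.arg(ties)
  event <- as.integer(event)
  if (is.null(dim(design))) design <- matrix(design, ncol = 1L,
                                             dimnames = list(NULL, "x"))
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(time)
  stopifnot(nrow(X) == n, length(event) == n)
  if (sum(event) == 0L) stop("No events; Cox model undefined.", call. = FALSE)
  const <- apply(X, 2L, function(v) max(v) == min(v))
  if (any(const)) {
    stop("Constant covariate column(s): ", paste(colnames(X)[const], collapse = ", "),
         " (non-identifiable).", call. = FALSE)
  }
  if (qr(X)$rank < ncol(X)) stop("Design matrix is column-rank deficient.", call. = FALSE)

  # center covariates for numerical stability; coefficients are unaffected
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  ord <- order(time)
  tt <- time[ord]; ee <- event[ord]; Xo <- Xc[ord, , drop = FALSE]
  p <- ncol(Xo)
  # distinct event times and, per event time, the at-risk start index and
  # the indices of the tied deaths (all relative to ascending time order)
  ev_times <- unique(tt[ee == 1L])
  risk_start <- vapply(ev_times, function(t) match(TRUE, tt >= t), integer(1))
  death_idx <- lapply(ev_times, function(t) which(tt == t & ee == 1L))
  # triangular index pairs for the p x p second-moment accumulators
  tri <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)

  unpack_sym <- function(v) {
    M <- matrix(0, p, p)
    M[cbind(tri[, 1], tri[, 2])] <- v
    M[cbind(tri[, 2], tri[, 1])] <- v
    M
  }
  rev_cumsum <- function(m) {
    if (is.null(dim(m))) rev(cumsum(rev(m)))
    else apply(m, 2L, function(col) rev(cumsum(rev(col))))
  }

  objective <- function(beta, want_deriv = TRUE) {
    eta <- drop(Xo %*% beta)
    w <- exp(eta)
    WX <- Xo * w
    WXX <- Xo[, tri[, 1], drop = FALSE] * Xo[, tri[, 2], drop = FALSE] * w
    r0 <- rev_cumsum(w)
    r1 <- rev_cumsum(WX); if (is.null(dim(r1))) r1 <- matrix(r1, ncol = 1L)
    r2 <- rev_cumsum(WXX); if (is.null(dim(r2))) r2 <- matrix(r2, ncol = 1L)
    ll <- 0
    g <- numeric(p)
    H <- matrix(0, p, p)
    for (k in seq_along(ev_times)) {
      D <- death_idx[[k]]
      d <- length(D)
      s <- risk_start[k]
      S0 <- r0[s]; S1 <- r1[s, ]; S2v <- r2[s, ]
      ll <- ll + sum(eta[D])
      if (want_deriv) g <- g + colSums(Xo[D, , drop = FALSE])
      if (ties == "breslow" || d == 1L) {
        denom <- S0
        z <- S1 / denom
        ll <- ll - d * log(denom)
        if (want_deriv) {
          g <- g - d * z
          H <- H + d * (unpack_sym(S2v) / denom - tcrossprod(z))
        }
      } else {
        sd0 <- sum(w[D])
        sd1 <- colSums(WX[D, , drop = FALSE])
        sd2 <- colSums(WXX[D, , drop = FALSE])
        for (l in seq_len(d) - 1L) {
          f <- l / d
          denom <- S0 - f * sd0
          z <- (S1 - f * sd1) / denom
          ll <- ll - log(denom)
          if (want_deriv) {
            g <- g - z
            H <- H + unpack_sym(S2v - f * sd2) / denom - tcrossprod(z)
          }
        }
      }
    }
    list(loglik = ll, gradient = g, information = H)
  }

  beta <- numeric(p)
  ob <- objective(beta)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # score tolerance scaled by the log-likelihood magnitude so convergence
    # is declared consistently across problem sizes
    if (max(abs(ob$gradient)) < tol * max(1, abs(ob$loglik))) { converged <- TRUE; break }
    step <- tryCatch(solve(ob$information, ob$gradient),
                     error = function(e) stop("Singular information matrix; ",
                                              "model not identifiable.", call. = FALSE))
    # step-halving on the log partial likelihood
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ob_new <- objective(cand)
      if (is.finite(ob_new$loglik) && ob_new$loglik >= ob$loglik - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    beta <- beta + lambda * step
    ob <- ob_new
  }
  scale_x <- apply(Xc, 2L, stats::sd)
  if (max(abs(beta) * scale_x) > 20) {
    stop("Cox coefficients diverging (max |beta * sd(x)| = ",
         format(max(abs(beta) * scale_x), digits = 3),
         ") - monotone likelihood / perfect separation suspected.", call. = FALSE)
  }
  if (!converged && max(abs(ob$gradient)) >= tol * max(1, abs(ob$loglik))) {
    stop("Cox fit did not converge after ", max_iter,
         " iterations (max |score| = ", format(max(abs(ob$gradient)), digits = 3), ").",
         call. = FALSE)
  }
  cov <- solve(ob$information)
  se <- sqrt(diag(cov))
  z <- beta / se
  out <- list(
    coefficients = stats::setNames(beta, colnames(X)),
    hazard_ratio = stats::setNames(exp(beta), colnames(X)),
    se = stats::setNames(se, colnames(X)),
    z = stats::setNames(z, colnames(X)),
    p.value = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
    vcov = cov,
    loglik = ob$loglik,
    n = n, n_event = sum(ee), ties = ties, iterations = iter,
    reference = attr(design, "reference"),
    dropped = attr(design, "dropped")
  )
  class(out) <- "lipo_cox"
  out
}

#' @export
print.lipo_cox <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties), n = ", x$n,
      ", events = ", x$n_event, "\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.lipo_cox <- function(x, conf.level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    hazard_ratio = unname(x$hazard_ratio),
    std.error = unname(x$se),
    statistic = unname(x$z),
    p.value = unname(x$p.value),
    conf.low = unname(x$coefficients - q * x$se),
    conf.high = unname(x$coefficients + q * x$se)
  )
}

#' @export
#' @importFrom generics glance
glance.lipo_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event, loglik = x$loglik,
                 iterations = x$iterations, ties = x$ties)
}
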