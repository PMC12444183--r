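#' Read a clinical table from TSV
#'
#' Expects columns `sample_id`, `time_days` (or `time`), `event`, and
#' optionally `t_stage`, `n_stage`, `m_stage`, `age`.
#'
#' @param path TSV path.
#' @return Tibble with a `time` column in days and `event` coerced to 0/1.
#' @export
read_clinical_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"time" %in% names(df) && "time_days" %in% names(df)) {
    df <- dplyr::rename(df, time = "time_days")
  }
  req <- c("sample_id", "time", "event")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("Clinical table missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df$event <- as.integer(df$event)
  if (!all(df$event %in% c(0L, 1L))) stop("event must be 0/1.", call. = FALSE)
  if (any(df$time < 0)) stop("Negative follow-up time.", call. = FALSE)
  tibble::as_tibble(df)
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times `t_i`,
#' with `d_i` deaths among the `n_i` subjects still at risk. A subject
#' censored at an event time is counted in that time's risk set and removed
#' afterwards.
#'
#' @param time Non-negative follow-up durations.
#' @param event Event indicators (1 = death observed, 0 = censored).
#' @return A `lipo_km` tibble with one row per distinct event time and columns
#'   `time`, `n_risk`, `n_event`, `survival`; attributes record `n` and the
#'   largest observed time.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("Need >= 1 record.", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0)) stop("Times must be finite and >= 0.", call. = FALSE)
  event <- as.integer(event)
  ev_times <- sort(unique(time[event == 1L]))
  if (length(ev_times) == 0L) {
    out <- tibble::tibble(time = numeric(0), n_risk = integer(0),
                          n_event = integer(0), survival = numeric(0))
  } else {
    n_risk <- vapply(ev_times, function(t) sum(time >= t), integer(1))
    n_event <- vapply(ev_times, function(t) sum(time == t & event == 1L), integer(1))
    out <- tibble::tibble(
      time = ev_times, n_risk = n_risk, n_event = n_event,
      survival = cumprod(1 - n_event / n_risk)
    )
  }
  attr(out, "n") <- length(time)
  attr(out, "max_time") <- max(time)
  class(out) <- c("lipo_km", class(out))
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km A `lipo_km` object.
#' @param t Times at which to evaluate the step function.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- sum(km$time <= tt)
    if (i == 0L) 1 else km$survival[i]
  }, numeric(1))
}

#' Restricted mean survival time under a Kaplan-Meier curve
#'
#' Area under the KM step function from 0 to the horizon `tau`; the last
#' survival value is carried forward beyond the last event time. Used to
#' order dominant clusters by overall survival.
#'
#' @param km A `lipo_km` object.
#' @param tau Restriction horizon (> 0).
#' @return The RMST in the time units of the input.
#' @export
km_rmst <- function(km, tau) {
  if (tau <= 0) stop("tau must be > 0.", call. = FALSE)
  knots <- c(0, km$time[km$time < tau], tau)
  surv <- c(1, km$survival[km$time < tau])
  sum(surv * diff(knots))
}

#' Log-rank test across two or more survival groups
#'
#' The standard observed-minus-expected formulation: at each distinct event
#' time the expected deaths per group follow the at-risk proportions and the
#' variance is hypergeometric; the statistic is the quadratic form of the
#' (O - E) vector of the first k-1 groups in the summed covariance, with
#' k - 1 degrees of freedom.
#'
#' @param time Follow-up durations.
#' @param event Event indicators (0/1).
#' @param group Group labels (>= 2 non-empty groups).
#' @return A `lipo_logrank` list with `statistic`, `df`, `p.value`, and the
#'   per-group observed/expected table; supports [generics::tidy()].
#' @export
logrank_test <- function(time, event, group) {
  event <- as.integer(event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) stop("Need >= 2 non-empty groups.", call. = FALSE)
  group <- droplevels(group)
  if (sum(event) == 0L) stop("No events; log-rank undefined.", call. = FALSE)
  k <- nlevels(group)
  ev_times <- sort(unique(time[event == 1L]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    if (n < 2L) next
    d <- sum(event == 1L & time == t)
    ng <- vapply(levels(group), function(g) sum(at_risk & group == g), numeric(1))
    dg <- vapply(levels(group), function(g) sum(event == 1L & time == t & group == g), numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    f <- d * (n - d) / (n - 1)
    V <- V + f * (diag(ng / n, k) - tcrossprod(ng / n))
  }
  u <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  stat <- if (all(abs(u) < 1e-12)) 0 else drop(t(u) %*% solve(Vk, u))
  out <- list(
    statistic = stat, df = k - 1L,
    p.value = stats::pchisq(stat, df = k - 1L, lower.tail = FALSE),
    table = tibble::tibble(group = levels(group), n = as.integer(table(group)),
                           observed = O, expected = E)
  )
  class(out) <- "lipo_logrank"
  out
}

#' @export
print.lipo_logrank <- function(x, ...) {
  cat("Log-rank test: chi-square =", format(x$statistic, digits = 4),
      "on", x$df, "df, p =", format.pval(x$p.value, digits = 3), "\n")
  print(x$table)
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.lipo_logrank <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value)
}

#' Kaplan-Meier curves for plotting, one per group
#'
#' @param time,event,group As in [logrank_test()]; `group` optional.
#' @return Tibble of step-function coordinates with class `lipo_km_set`.
#' @export
km_curves <- function(time, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.factor(group)
  out <- purrr::map_dfr(levels(group), function(g) {
    sel <- group == g
    km <- km_estimate(time[sel], event[sel])
    tibble::tibble(group = g,
                   time = c(0, km$time),
                   survival = c(1, km$survival),
                   n_risk = c(sum(sel), km$n_risk))
  })
  class(out) <- c("lipo_km_set", class(out))
  out
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.lipo_km_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}
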