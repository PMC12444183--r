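test_that("product-limit estimate matches the hand-computed 4-subject example", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(km_survival_at(km, 1), 3 / 4)
  expect_equal(km_survival_at(km, 3), 3 / 8)
  # all censored -> S = 1 everywhere
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km_survival_at(km0, c(0, 2, 10)), c(1, 1, 1))
  # single observed death -> S drops to 0
  km1 <- km_estimate(5, 1)
  expect_equal(km_survival_at(km1, 5), 0)
  expect_error(km_estimate(-1, 1), ">= 0")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(8)
  t <- round(rexp(40, 0.3), 2)
  km <- km_estimate(t, rep(1L, 40))
  grid <- sort(unique(t))
  expect_equal(km_survival_at(km, grid),
               vapply(grid, function(tt) mean(t > tt), numeric(1)))
})

test_that("RMST integrates the KM step function to the horizon", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 0))
  # S = 1 on [0,1), 3/4 on [1,3), 3/8 on [3,4]
  expect_equal(km_rmst(km, 4), 1 + 2 * 3 / 4 + 1 * 3 / 8)
  expect_equal(km_rmst(km, 0.5), 0.5)
})

test_that("log-rank is exactly zero on identical groups and matches a hand oracle", {
  t <- c(1, 2, 3, 4, 5, 6)
  e <- c(1, 0, 1, 1, 0, 1)
  lr0 <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 6))
  expect_identical(lr0$statistic, 0)
  expect_equal(lr0$p.value, 1)
  # hand-checkable 6-subject two-group instance
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  group <- rep(c("x", "y"), each = 3)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$statistic, naive_logrank_2g(time, event, group), tolerance = 1e-12)
  expect_equal(lr$df, 1L)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "No events")
})

test_that("log-rank agrees with survival::survdiff on 2- and 3-group data", {
  set.seed(12)
  n <- 90
  time <- rexp(n, 0.5); event <- rbinom(n, 1, 0.8)
  g2 <- rep(c("a", "b"), length.out = n)
  g3 <- rep(c("a", "b", "c"), length.out = n)
  for (g in list(g2, g3)) {
    lr <- logrank_test(time, event, g)
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-10)
  }
})

test_that("one-hot encoding emits one column per non-reference category", {
  cl <- tibble::tibble(
    sample_id = paste0("p", 1:5),
    t_stage = c("T1", "T2", "T3", "T1", "T2"),
    n_stage = c("N0", "N0", "N1", "N0", "N0"),
    m_stage = rep("M0", 5),
    age = c(50, 60, 70, 55, 65)
  )
  X <- one_hot_encode(cl, stage_levels = list(t_stage = c("T1", "T2", "T3"),
                                              n_stage = c("N0", "N1"),
                                              m_stage = c("M0", "M1")))
  expect_equal(colnames(X), c("T2", "T3", "N1", "age"))  # M1 unobserved still encoded
  expect_equal(unname(X[2, "T2"]), 1)
  expect_equal(unname(X[3, c("T2", "T3")]), c(0, 1))
  expect_equal(unname(X[, "age"]), cl$age)
  # all-reference records leave only age (+ optional cluster flag)
  cl_ref <- dplyr::mutate(cl, t_stage = "T1", n_stage = "N0")
  X2 <- one_hot_encode(cl_ref, cluster1 = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(setdiff(colnames(X2), c("T2", "T3", "T4", "N1", "M1")),
               c("age", "is_cluster1"))
  expect_equal(unname(X2[, "is_cluster1"]), c(1, 0, 0, 1, 0))
  expect_error(one_hot_encode(dplyr::mutate(cl, t_stage = "T9")), "Unseen")
})

test_that("unassessable stages are dropped with a message", {
  cl <- tibble::tibble(sample_id = paste0("p", 1:4),
                       t_stage = c("T1", "TX", "T2", "T1"),
                       n_stage = c("N0", "N0", "NX", "N1"),
                       m_stage = rep("M0", 4), age = 60:63)
  expect_message(X <- one_hot_encode(cl), "Dropping 2")
  expect_equal(rownames(X), c("p1", "p4"))
  expect_equal(attr(X, "dropped"), c("p2", "p3"))
})

test_that("Cox fit matches survival::coxph for both tie corrections", {
  set.seed(33)
  n <- 120
  X <- cbind(z = rnorm(n), b = rbinom(n, 1, 0.4))
  t0 <- rexp(n, exp(0.4 * X[, 1] - 0.6 * X[, 2]))
  ev <- rbinom(n, 1, 0.75)
  tied <- round(t0, 1)
  for (ties in c("efron", "breslow")) {
    fit <- cox_fit(tied, ev, X, ties = ties)
    ref <- survival::coxph(survival::Surv(tied, ev) ~ X, ties = ties)
    expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-7)
  }
  # hazard_rate = exp(coefficient) identity
  fit <- cox_fit(tied, ev, X)
  expect_equal(fit$hazard_ratio, exp(fit$coefficients), tolerance = 1e-12)
})

test_that("Efron and Breslow agree exactly on tie-free data", {
  set.seed(44)
  n <- 60
  X <- cbind(x = rnorm(n))
  t0 <- rexp(n, exp(0.5 * X[, 1]))  # continuous, no ties
  ev <- rbinom(n, 1, 0.7)
  fe <- cox_fit(t0, ev, X, ties = "efron")
  fb <- cox_fit(t0, ev, X, ties = "breslow")
  expect_equal(fe$coefficients, fb$coefficients, tolerance = 1e-12)
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-12)
})

test_that("Cox coefficient is invariant to rescaling time (binary covariate, no ties)", {
  set.seed(55)
  n <- 80
  x <- rbinom(n, 1, 0.5)
  t0 <- rexp(n, exp(0.8 * x))
  ev <- rep(1L, n)
  f1 <- cox_fit(t0, ev, cbind(x = x))
  f2 <- cox_fit(t0 * 365.25, ev, cbind(x = x))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
})

test_that("degenerate Cox designs are rejected with diagnostics", {
  set.seed(66)
  t0 <- rexp(20); ev <- rep(1L, 20)
  expect_error(cox_fit(t0, ev, cbind(c = rep(1, 20))), "Constant covariate")
  X <- cbind(a = rnorm(20))
  expect_error(cox_fit(t0, ev, cbind(X, b = 2 * X[, 1])), "rank deficient")
  expect_error(cox_fit(t0, rep(0L, 20), X), "No events")
  # perfect separation: the covariate exactly orders the survival times
  xsep <- 1:20
  expect_error(cox_fit(sort(t0), ev, cbind(x = -xsep)), "separation")
})

test_that("null Cox coefficients stay within 3 SE of zero almost always", {
  inside <- vapply(1:60, function(seed) {
    set.seed(seed + 500)
    n <- 500
    x <- rnorm(n)
    t0 <- rexp(n)  # independent of x
    ev <- rbinom(n, 1, 0.7)
    fit <- cox_fit(t0, ev, cbind(x = x))
    abs(fit$coefficients[["x"]]) < 3 * fit$se[["x"]]
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})
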