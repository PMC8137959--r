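# Cox fitting, concordance, bootstrap optimism correction.

test_that("Cox preconditions are enforced", {
  set.seed(1)
  X <- cbind(x = rnorm(20))
  expect_error(fit_cox(X, rexp(20), rep(0, 20)), "no events")
  expect_error(fit_cox(cbind(x = rep(1, 20)), rexp(20), rbinom(20, 1, 0.5)),
               "zero-variance")
  Xna <- X; Xna[3] <- NA
  expect_error(fit_cox(Xna, rexp(20), rep(1, 20)), "missing values")
})

test_that("Cox fit recovers a known coefficient within 3 SE", {
  co <- gen_cohort(cohort_config(n_patients = 200, nuclei_per_patient = 0,
                                 beta = 0.8, seed = 31))
  fit <- fit_cox(as.matrix(co$clinical[, "cov_1", drop = FALSE]),
                 co$clinical$OS, co$clinical$FUS)
  expect_lt(abs(unname(fit$coefficients) - 0.8), 3 * unname(fit$se))
})

test_that("Cox fit maximizes the hand-written partial likelihood", {
  x <- c(-1.2, 0.4, 1.5, -0.3, 0.9, -2.0)
  time <- c(1.1, 2.3, 0.7, 4.8, 3.2, 5.5)   # no ties
  event <- rep(1, 6)
  fit <- fit_cox(cbind(x = x), time, event, tol = 1e-12)
  grid <- seq(-3, 3, by = 0.01)
  ll <- vapply(grid, cox_loglik_1d, numeric(1), x = x, time = time,
               event = event)
  opt <- stats::optimize(cox_loglik_1d, x = x, time = time, event = event,
                         interval = grid[which.max(ll)] + c(-0.02, 0.02),
                         maximum = TRUE, tol = 1e-12)
  expect_equal(unname(fit$coefficients), opt$maximum, tolerance = 1e-6)
  expect_equal(fit$loglik,
               cox_loglik_1d(unname(fit$coefficients), x, time, event),
               tolerance = 1e-9)
})

test_that("risk scores are linear predictors with matched columns", {
  set.seed(2)
  X <- cbind(a = rnorm(30), b = rnorm(30))
  fit <- fit_cox(X, rexp(30), rbinom(30, 1, 0.8))
  fit0 <- fit; fit0$coefficients[] <- 0
  expect_equal(risk_score(fit0, X), rep(0, 30))
  fit1 <- fit; fit1$coefficients[] <- c(1, 0)
  expect_equal(risk_score(fit1, X), unname(X[, "a"]))
  Xbad <- X; colnames(Xbad) <- c("a", "zz")
  expect_error(risk_score(fit, Xbad), "do not match")
  # shift invariance downstream: adding a constant changes no orderings
  t <- rexp(30); e <- rbinom(30, 1, 0.8)
  s <- risk_score(fit, X)
  expect_equal(harrell_c(s, t, e), harrell_c(s + 5, t, e))
})

test_that("concordance handles exact small cases", {
  expect_equal(harrell_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(harrell_c(c(2, 1, 3), c(1, 2, 3), c(1, 1, 1)), 1 / 3)
  expect_error(harrell_c(1, 1, 0), "no comparable pairs")
  expect_error(harrell_c(1:3, 1:2, 1:3), "equal length")
})

test_that("concordance matches exhaustive pair enumeration with ties", {
  for (seed in 1:50) {
    inst <- random_survival_instance(seed, n = sample(20:200, 1))
    expect_equal(harrell_c(inst$scores, inst$time, inst$event),
                 oracle_harrell(inst$scores, inst$time, inst$event),
                 tolerance = 1e-12)
  }
})

test_that("concordance is antisymmetric and cross-checks survival pkg", {
  set.seed(77)
  s <- rnorm(100); t <- rexp(100); e <- rbinom(100, 1, 0.7)
  expect_equal(harrell_c(s, t, e) + harrell_c(-s, t, e), 1)
  conc <- survival::concordance(survival::Surv(t, e) ~ s, reverse = TRUE)
  expect_equal(harrell_c(s, t, e), unname(conc$concordance),
               tolerance = 1e-10)
})

test_that("random scores concord at one half on a large cohort", {
  co <- gen_cohort(cohort_config(n_patients = 2000, nuclei_per_patient = 0,
                                 beta = c(0, 0), seed = 41))
  cs <- vapply(1:20, function(r) {
    set.seed(1000 + r)
    harrell_c(runif(2000), co$clinical$OS, co$clinical$FUS)
  }, numeric(1))
  mc_se <- sd(cs) / sqrt(20)
  expect_lt(abs(mean(cs) - 0.5), 3 * mc_se)
})

test_that("percentile CI uses interpolated quantiles", {
  expect_equal(percentile_ci(0:100), c(low = 2.5, high = 97.5))
  expect_equal(percentile_ci(rep(3.3, 25)), c(low = 3.3, high = 3.3))
  set.seed(5)
  ci <- percentile_ci(rnorm(1000))
  expect_lt(abs(ci[["low"]] - (-1.96)), 0.15)
  expect_lt(abs(ci[["high"]] - 1.96), 0.15)
  expect_error(percentile_ci(1:10), "too few")
})

test_that("optimism correction is deterministic and internally consistent", {
  set.seed(9)
  X <- cbind(a = rnorm(60), b = rnorm(60))
  t <- rexp(60, 0.2); e <- rbinom(60, 1, 0.7)
  r1 <- optimism_corrected_c(X, t, e, n_bootstrap = 40, seed = 123)
  r2 <- optimism_corrected_c(X, t, e, n_bootstrap = 40, seed = 123)
  expect_identical(r1, r2)
  expect_equal(r1$corrected_c, r1$apparent_c - r1$mean_optimism)
  expect_lte(r1$ci_low, r1$ci_high)
})

test_that("degenerate orderings are flagged, near-degenerate optimism is tiny", {
  # fully concordant data means monotone partial likelihood: the fit must
  # refuse rather than report an arbitrary coefficient
  x <- seq(-2, 2, length.out = 40)
  expect_error(fit_cox(cbind(x = x), exp(-3 * x), rep(1, 40)),
               "monotone|converge")
  # with overwhelming signal but convergent fits, resampling barely
  # perturbs the orderings and the optimism collapses toward zero
  set.seed(6)
  n <- 150
  xx <- rnorm(n)
  tt <- rexp(n, rate = 0.2 * exp(2.5 * xx))
  r <- optimism_corrected_c(cbind(x = xx), tt, rep(1, n),
                            n_bootstrap = 40, seed = 5)
  expect_lt(abs(r$mean_optimism), 0.02)
  expect_equal(r$corrected_c, r$apparent_c - r$mean_optimism)
})

test_that("optimism is positive on overfittable null data", {
  opts <- vapply(1:20, function(rep) {
    set.seed(500 + rep)
    n <- 50; p <- 10
    X <- matrix(rnorm(n * p), n, p)
    t <- rexp(n, 0.2); e <- rbinom(n, 1, 0.8)
    optimism_corrected_c(X, t, e, n_bootstrap = 25, seed = rep,
                         max_fail_frac = 0.4)$mean_optimism
  }, numeric(1))
  expect_gt(mean(opts), 0)
})

test_that("null cohorts give corrected C near one half end to end", {
  reps <- vapply(1:8, function(r) {
    co <- gen_cohort(cohort_config(n_patients = 100, nuclei_per_patient = 0,
                                   beta = c(0, 0), seed = 600 + r))
    optimism_corrected_c(as.matrix(co$clinical[, c("cov_1", "cov_2")]),
                         co$clinical$OS, co$clinical$FUS,
                         n_bootstrap = 50, seed = r)$corrected_c
  }, numeric(1))
  expect_lt(abs(mean(reps) - 0.5), 3 * sd(reps) / sqrt(8))
})

test_that("coefficient RMSE shrinks as the cohort grows", {
  rmse_at <- function(n) {
    errs <- vapply(1:10, function(r) {
      co <- gen_cohort(cohort_config(n_patients = n, nuclei_per_patient = 0,
                                     beta = c(0.8, 0.3), seed = 700 + r))
      fit <- fit_cox(as.matrix(co$clinical[, c("cov_1", "cov_2")]),
                     co$clinical$OS, co$clinical$FUS)
      sum((unname(fit$coefficients) - c(0.8, 0.3))^2)
    }, numeric(1))
    sqrt(mean(errs))
  }
  expect_lt(rmse_at(400), rmse_at(100))
})
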