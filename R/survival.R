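# Cox proportional-hazards fitting, Harrell's C-index, bootstrap optimism
# correction and percentile confidence intervals.

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with Efron tie correction by
#' Newton-Raphson (with step-halving), as provided by
#' [survival::coxph()]. Monotone likelihood (risk separation) and
#' non-convergence are turned into errors naming the offending column
#' rather than silent warnings, so bootstrap callers can count failures.
#'
#' @param X Numeric covariate matrix (standardized columns recommended)
#'   or a `design_matrix` from [assemble_design()].
#' @param time,event Survival time and event indicator vectors (ignored
#'   when `X` is a `design_matrix`).
#' @param max_iter Newton-Raphson iteration cap (default 100).
#' @param tol Convergence tolerance (default 1e-7).
#' @param ties Tie-handling method (default `"efron"`).
#' @return Object of class `cox_fit`: `coefficients`, `loglik` (at the
#'   optimum), `converged`, `iter`, `ties`, `columns`.
#' @export
fit_cox <- function(X, time = NULL, event = NULL, max_iter = 100,
                    tol = 1e-7, ties = "efron") {
  if (inherits(X, "design_matrix")) {
    time <- X$time; event <- X$event; X <- X$X
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(X) || anyNA(time) || anyNA(event))
    stop("missing values in Cox inputs")
  if (sum(event) < 2) stop("no events (need at least 2 observed events)")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance covariate column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  bad_fit <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(time, event) ~ X,
      ties = ties,
      control = survival::coxph.control(iter.max = max_iter, eps = tol)),
    warning = function(w) {
      if (grepl("infinite|converge|singular|beta may be",
                conditionMessage(w), ignore.case = TRUE))
        bad_fit <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- stats::coef(fit)
  if (bad_fit)
    stop("Cox fit failed to converge (monotone likelihood or singular ",
         "information); suspect column: ",
         colnames(X)[which.max(abs(ifelse(is.na(coefs), Inf, coefs)))])
  if (anyNA(coefs))
    stop("singular information matrix: column ",
         colnames(X)[which(is.na(coefs))[1]], " is aliased")
  names(coefs) <- colnames(X)
  se <- sqrt(diag(as.matrix(fit$var)))
  names(se) <- colnames(X)
  structure(list(coefficients = coefs,
                 se = se,
                 loglik = fit$loglik[2],
                 converged = !bad_fit,
                 iter = fit$iter,
                 ties = ties,
                 columns = colnames(X)),
            class = "cox_fit")
}

#' Linear risk scores from a Cox fit
#'
#' `score = X %*% coefficients`; a monotone transform of the predicted
#' hazard. Column names must match the training design.
#'
#' @param model A `cox_fit`.
#' @param X Covariate matrix with the training columns.
#' @return Numeric vector of linear predictors.
#' @export
risk_score <- function(model, X) {
  stopifnot(inherits(model, "cox_fit"))
  if (inherits(X, "design_matrix")) X <- X$X
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!identical(colnames(X), model$columns))
    stop("design columns do not match the fitted model: expected ",
         paste(model$columns, collapse = ", "))
  as.vector(X %*% model$coefficients)
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs whose risk ordering matches the observed
#' event ordering. Pair (i, j) is comparable when subject i has an
#' observed event and j's time is later — or equal with j censored.
#' Concordant pairs (higher score to the earlier event) count 1, score
#' ties count 0.5. Random scores give 0.5 in expectation.
#'
#' @param scores Risk scores (higher = earlier expected event).
#' @param time,event Survival times and event indicators.
#' @return Concordance in \[0, 1\].
#' @export
harrell_c <- function(scores, time, event) {
  n <- length(scores)
  if (length(time) != n || length(event) != n)
    stop("scores, time and event must have equal length")
  comp <- outer(event == 1, rep(TRUE, n), "&") &
    (outer(time, time, "<") |
     (outer(time, time, "==") & outer(event == 1, event == 0, "&")))
  diag(comp) <- FALSE
  npairs <- sum(comp)
  if (npairs == 0) stop("no comparable pairs")
  sdiff <- outer(scores, scores, "-")
  conc <- sum(comp & sdiff > 0) + 0.5 * sum(comp & sdiff == 0)
  conc / npairs
}

#' Percentile bootstrap confidence interval
#'
#' Empirical (alpha/2, 1 - alpha/2) quantiles with linear interpolation.
#'
#' @param samples Numeric vector of bootstrap statistics (>= 20).
#' @param alpha Two-sided miscoverage (default 0.05).
#' @return Named vector `c(low, high)`.
#' @export
percentile_ci <- function(samples, alpha = 0.05) {
  if (length(samples) < 20L)
    stop("too few bootstrap samples for a percentile CI (need >= 20)")
  q <- stats::quantile(samples, c(alpha / 2, 1 - alpha / 2),
                       names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Optimism-corrected C-index by bootstrap
#'
#' Fits the model on the full data (apparent C), then for each of
#' `n_bootstrap` with-replacement replicates fits on the replicate and
#' evaluates on both the replicate (`c_boot`) and the original data
#' (`c_orig`). The optimism `c_boot - c_orig`, averaged over replicates,
#' is subtracted from the apparent C. Replicates where the fit fails
#' (e.g. risk separation in a small resample) are skipped and counted;
#' more than `max_fail_frac` failures is an error. The 95% CI is the
#' percentile interval of the replicate-wise `c_orig` values (a single
#' bootstrap level; an exact CI of the corrected statistic would need a
#' double bootstrap — see the package vignette).
#'
#' Replicate r draws its indices from a seed derived deterministically
#' from `(seed, r)`, so results are reproducible regardless of execution
#' order.
#'
#' @param X Covariate matrix or `design_matrix`.
#' @param time,event Survival data (ignored for a `design_matrix`).
#' @param n_bootstrap Number of replicates (default 1000).
#' @param seed RNG seed.
#' @param alpha CI miscoverage (default 0.05).
#' @param max_fail_frac Tolerated fraction of failed replicates
#'   (default 0.1).
#' @param ... Passed to [fit_cox()].
#' @return Object of class `optimism_result`: `apparent_c`,
#'   `mean_optimism`, `corrected_c`, `ci_low`, `ci_high`, `n_bootstrap`,
#'   `n_failed`, `seed`, plus the per-replicate `optimism` and `c_orig`
#'   samples.
#' @export
optimism_corrected_c <- function(X, time = NULL, event = NULL,
                                 n_bootstrap = 1000, seed = 1L,
                                 alpha = 0.05, max_fail_frac = 0.1, ...) {
  if (inherits(X, "design_matrix")) {
    time <- X$time; event <- X$event; X <- X$X
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  full_fit <- fit_cox(X, time, event, ...)
  apparent <- harrell_c(risk_score(full_fit, X), time, event)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_bootstrap)
  optimism <- rep(NA_real_, n_bootstrap)
  c_orig <- rep(NA_real_, n_bootstrap)
  for (r in seq_len(n_bootstrap)) {
    set.seed(rep_seeds[r])
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch({
      bfit <- fit_cox(X[idx, , drop = FALSE], time[idx], event[idx], ...)
      cb <- harrell_c(risk_score(bfit, X[idx, , drop = FALSE]),
                      time[idx], event[idx])
      co <- harrell_c(risk_score(bfit, X), time, event)
      c(cb, co)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      optimism[r] <- res[1] - res[2]
      c_orig[r] <- res[2]
    }
  }
  ok <- !is.na(optimism)
  n_failed <- sum(!ok)
  if (n_failed > max_fail_frac * n_bootstrap)
    stop("too many failed bootstrap replicates: ", n_failed, " of ",
         n_bootstrap)
  ci <- percentile_ci(c_orig[ok], alpha = alpha)
  mean_opt <- mean(optimism[ok])
  structure(list(apparent_c = apparent,
                 mean_optimism = mean_opt,
                 corrected_c = apparent - mean_opt,
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 n_bootstrap = n_bootstrap, n_failed = n_failed,
                 seed = seed,
                 optimism = optimism[ok], c_orig = c_orig[ok]),
            class = "optimism_result")
}

#' @export
print.optimism_result <- function(x, ...) {
  cat(sprintf(
    "Optimism-corrected C-index: %.3f (95%% CI %.3f-%.3f)\n  apparent %.3f, mean optimism %.4f, %d bootstrap replicates (%d failed)\n",
    x$corrected_c, x$ci_low, x$ci_high, x$apparent_c, x$mean_optimism,
    x$n_bootstrap, x$n_failed))
  invisible(x)
}
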