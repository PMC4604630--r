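#' Target analyses for a completed dataset
#'
#' Computes one of the four target estimands with its standard error from a
#' complete (no missing values) outcome/covariate pair:
#' \describe{
#'   \item{`marginal_mean`}{sample mean of `y`; se \eqn{= s_y / \sqrt{n}}
#'     with the \eqn{n - 1} denominator in \eqn{s_y}.}
#'   \item{`marginal_proportion`}{sample proportion of `y = 1`; binomial
#'     plug-in se \eqn{\sqrt{p (1 - p) / n}}.}
#'   \item{`linear_slope`}{OLS slope of `y` on `x` with the conventional
#'     (unbiased residual variance) standard error.}
#'   \item{`logistic_slope`}{maximum-likelihood logistic slope with Wald
#'     standard error; requires both outcome classes.}
#' }
#'
#' @param y complete outcome vector (0/1 for the binary estimands).
#' @param x complete covariate vector of the same length (ignored by the
#'   marginal estimands).
#' @param estimand one of `"marginal_mean"`, `"marginal_proportion"`,
#'   `"linear_slope"`, `"logistic_slope"`.
#'
#' @return A list of class `mi_estimate` with elements `estimate`, `se`
#'   and `estimand`.
#' @seealso [complete_case()], [rubin_pool()]
#' @examples
#' analyze(c(1, 2, 3), estimand = "marginal_mean")
#' @export
analyze <- function(y, x = NULL,
                    estimand = c("marginal_mean", "marginal_proportion",
                                 "linear_slope", "logistic_slope")) {
  estimand <- match.arg(estimand)
  if (anyNA(y) || (!is.null(x) && anyNA(x)))
    stop("analyze() requires complete data; use complete_case() or impute")
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations")
  needs_x <- estimand %in% c("linear_slope", "logistic_slope")
  if (needs_x) {
    if (is.null(x)) stop("'x' is required for slope estimands")
    if (length(x) != n) stop("'x' and 'y' lengths differ")
  }
  res <- switch(estimand,
    marginal_mean = {
      list(estimate = mean(y), se = sd(y) / sqrt(n))
    },
    marginal_proportion = {
      if (!all(y %in% c(0, 1))) stop("'y' must be 0/1 for a proportion")
      p <- mean(y)
      if (p <= 0 || p >= 1)
        stop("degenerate proportion (all 0 or all 1): se undefined")
      list(estimate = p, se = sqrt(p * (1 - p) / n))
    },
    linear_slope = {
      sm <- summary(lm(y ~ x))$coefficients
      list(estimate = sm["x", 1L], se = sm["x", 2L])
    },
    logistic_slope = {
      if (!all(y %in% c(0, 1))) stop("'y' must be 0/1 for a logistic slope")
      if (length(unique(y)) < 2L)
        stop("logistic slope requires both outcome classes")
      fit <- glm(y ~ x, family = binomial())
      if (!fit$converged) stop("logistic fit did not converge")
      sm <- summary(fit)$coefficients
      list(estimate = sm["x", 1L], se = sm["x", 2L])
    })
  if (!is.finite(res$se) || res$se <= 0)
    stop("degenerate analysis: standard error is not a positive number")
  structure(c(res, list(estimand = estimand, n = n)), class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(x$estimand, ": ", format(x$estimate, digits = 4),
      " (se ", format(x$se, digits = 4), ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Complete-case analysis of an incomplete sample
#'
#' Restricts the sample to the rows with an observed outcome (`r = 1`) and
#' runs [analyze()] on the restriction.  Under MNAR this estimator is
#' biased, which is precisely why it serves as a benchmark.
#'
#' @param sample incomplete sample: data frame with columns `x`, `y` and
#'   optionally `r`.
#' @inheritParams analyze
#' @return An `mi_estimate`, as from [analyze()].
#' @export
complete_case <- function(sample, estimand = "marginal_mean") {
  s <- as_incomplete(sample)
  obs <- s$r == 1L
  if (sum(obs) < 3L) stop("fewer than 3 observed outcomes")
  analyze(s$y[obs], s$x[obs], estimand)
}

# Apply analyze() down the columns of an mi_set -> data.frame(estimate, se).
# Exported as the bridge between imputation and pooling.

#' Per-imputation estimates for an imputation set
#'
#' Runs the target analysis on each completed dataset of an `mi_set`,
#' yielding the \eqn{\hat\theta_j} and their standard errors that Rubin's
#' rules and the delta-weighted pooling combine.
#'
#' @param imps an `mi_set` from [impute_normal()] or [impute_logistic()].
#' @param x covariate vector (same length as the outcome).
#' @inheritParams analyze
#' @return A data frame with columns `estimate` and `se`, one row per
#'   imputation.
#' @export
analyze_imputations <- function(imps, x, estimand = "marginal_mean") {
  stopifnot(inherits(imps, "mi_set"))
  out <- vapply(seq_len(imps$m), function(j) {
    a <- analyze(imps$completed[, j], x, estimand)
    c(a$estimate, a$se)
  }, numeric(2L))
  data.frame(estimate = out[1L, ], se = out[2L, ])
}
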