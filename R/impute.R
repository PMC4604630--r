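# Coerce/validate an incomplete sample: data frame with complete x, a y
# column containing NAs, and an r indicator consistent with is.na(y).
as_incomplete <- function(sample) {
  stopifnot(is.data.frame(sample), all(c("x", "y") %in% names(sample)))
  if (anyNA(sample$x)) stop("covariate 'x' must be fully observed")
  r <- sample$r %||% as.integer(!is.na(sample$y))
  if (any((r == 0L) != is.na(sample$y)))
    stop("'y' must be missing exactly where r = 0")
  data.frame(x = sample$x, y = sample$y, r = as.integer(r))
}

new_mi_set <- function(completed, miss_idx, draws, type) {
  structure(
    list(m = ncol(completed), completed = completed,
         miss_idx = miss_idx,
         sums = colSums(completed[miss_idx, , drop = FALSE]),
         draws = draws, type = type),
    class = "mi_set")
}

#' Proper multiple imputation of a continuous outcome (normal-linear model)
#'
#' Imputes the missing entries of `y` under the Bayesian normal linear
#' regression of the outcome on the single covariate, fitted to the
#' \eqn{n_0} complete cases.  For each imputation \eqn{j} the parameters
#' are drawn from their joint posterior in two steps,
#' \deqn{\sigma_*^2 \sim \hat\sigma^2 (n_0 - q) / \chi^2_{n_0 - q}, \qquad
#'  \beta_* \mid \sigma_*^2 \sim N(\hat\beta,\
#'  \sigma_*^2 (X_o' X_o)^{-1}),}
#' with \eqn{q = 2} (intercept and slope), \eqn{\hat\sigma^2} the residual
#' sum of squares divided by \eqn{n_0 - q}, and \eqn{X_o} the complete-case
#' design matrix.  Missing values are then imputed as
#' \eqn{\beta_{*0} + \beta_{*1} x_i + N(0, \sigma_*^2)} noise.  Drawing the
#' parameters afresh for every imputation is what makes the imputation
#' "proper": the between-imputation spread reflects parameter uncertainty,
#' and the implied posterior-predictive distribution of the imputed values
#' is a (heavier-tailed) t, not a normal.
#'
#' The draw order is fixed per imputation (variance, then coefficients,
#' then residual noise), so a seed fully determines the result.
#'
#' @param sample incomplete sample: data frame with columns `x`, `y`
#'   (`NA` where missing) and optionally `r`.
#' @param m number of imputations (at least 1).
#' @param seed optional integer passed to `set.seed()`.
#'
#' @return An object of class `mi_set`: a list with elements `m`,
#'   `completed` (an \eqn{n \times m} matrix whose observed rows are
#'   identical across columns), `miss_idx` (indices of the imputed rows),
#'   `sums` (\eqn{S_j = \sum_{i \in I_Y} y_{ij}}, the per-imputation sums
#'   of imputed values that drive the delta-weights), `draws` (the
#'   parameter draws) and `type`.
#' @seealso [impute_logistic()], [delta_weights()]
#' @examples
#' d <- apply_mnar(sim_bivnorm(100, seed = 1), 0, 1, 0.5, seed = 2)
#' imp <- impute_normal(d, m = 5, seed = 3)
#' imp$sums
#' @export
impute_normal <- function(sample, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- as_incomplete(sample)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("'m' must be a positive integer")
  obs <- s$r == 1L
  miss_idx <- which(!obs)
  n0 <- sum(obs)
  q <- 2L
  if (n0 < q + 2L)
    stop("need at least ", q + 2L,
         " observed outcomes (chi-square df n0 - q >= 2), got ", n0)
  if (length(miss_idx) == 0L) {
    warning("no missing outcome values; returning m copies of 'y'")
    completed <- matrix(s$y, nrow(s), m)
    return(new_mi_set(completed, miss_idx,
                      list(beta = NULL, sigma2 = NULL), "normal"))
  }
  fit <- lm(y ~ x, data = s[obs, ])
  betahat <- coef(fit)
  sigma2hat <- sum(fit$residuals^2) / (n0 - q)
  XtXinv <- summary(fit)$cov.unscaled
  R <- chol(XtXinv)  # upper triangular, R'R = (Xo'Xo)^-1
  x_mis <- s$x[miss_idx]
  completed <- matrix(s$y, nrow(s), m)
  beta_draws <- matrix(NA_real_, m, q)
  sigma2_draws <- numeric(m)
  for (j in seq_len(m)) {
    sigma2 <- sigma2hat * (n0 - q) / rchisq(1L, df = n0 - q)
    beta <- betahat + sqrt(sigma2) * drop(crossprod(R, rnorm(q)))
    completed[miss_idx, j] <-
      beta[1L] + beta[2L] * x_mis + rnorm(length(miss_idx), 0, sqrt(sigma2))
    beta_draws[j, ] <- beta
    sigma2_draws[j] <- sigma2
  }
  new_mi_set(completed, miss_idx,
             list(beta = beta_draws, sigma2 = sigma2_draws), "normal")
}

#' Multiple imputation of a binary outcome (asymptotic-posterior logistic)
#'
#' Imputes the missing entries of a 0/1 outcome under logistic regression
#' on the single covariate.  For each imputation the coefficient vector is
#' drawn from the asymptotic normal approximation to its posterior,
#' \eqn{\beta_* \sim N(\hat\beta_{ML},\ I(\hat\beta_{ML})^{-1})} with the
#' inverse observed Fisher information as covariance, and missing values
#' are drawn as \eqn{\mathrm{Bernoulli}(\mathrm{expit}(\beta_{*0} +
#' \beta_{*1} x_i))} (realised as uniform-threshold draws).
#'
#' Complete or quasi-complete separation of the observed data, or
#' non-convergence of the maximum-likelihood fit, is an error: silently
#' imputing from a degenerate posterior would be meaningless.
#'
#' @inheritParams impute_normal
#' @return An object of class `mi_set` (see [impute_normal()]); `sums`
#'   here counts the imputed successes per imputation.
#' @export
impute_logistic <- function(sample, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- as_incomplete(sample)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("'m' must be a positive integer")
  obs <- s$r == 1L
  miss_idx <- which(!obs)
  yo <- s$y[obs]
  if (!all(yo %in% c(0, 1))) stop("binary imputation requires a 0/1 outcome")
  if (length(unique(yo)) < 2L)
    stop("observed outcomes are all one class (complete separation)")
  if (length(miss_idx) == 0L) {
    warning("no missing outcome values; returning m copies of 'y'")
    completed <- matrix(s$y, nrow(s), m)
    return(new_mi_set(completed, miss_idx,
                      list(beta = NULL, sigma2 = NULL), "logistic"))
  }
  fit <- glm(y ~ x, family = binomial(), data = s[obs, ])
  p_hat <- fitted(fit)
  if (!fit$converged || any(p_hat < 1e-10) || any(p_hat > 1 - 1e-10))
    stop("logistic imputation model did not converge ",
         "(complete or quasi-complete separation?)")
  betahat <- coef(fit)
  R <- chol(vcov(fit))  # inverse observed information
  x_mis <- s$x[miss_idx]
  completed <- matrix(s$y, nrow(s), m)
  beta_draws <- matrix(NA_real_, m, 2L)
  for (j in seq_len(m)) {
    beta <- betahat + drop(crossprod(R, rnorm(2L)))
    p <- expit(beta[1L] + beta[2L] * x_mis)
    completed[miss_idx, j] <- as.numeric(runif(length(miss_idx)) < p)
    beta_draws[j, ] <- beta
  }
  new_mi_set(completed, miss_idx, list(beta = beta_draws, sigma2 = NULL),
             "logistic")
}

#' @export
print.mi_set <- function(x, ...) {
  cat("Multiple-imputation set (", x$type, " model)\n", sep = "")
  cat("  m =", x$m, "imputations,", length(x$miss_idx), "of",
      nrow(x$completed), "outcome values imputed\n")
  if (length(x$miss_idx)) {
    cat("  sums of imputed values S_j: ")
    cat(format(head(round(x$sums, 3), 5)), sep = ", ")
    if (x$m > 5) cat(", ...")
    cat("\n")
  }
  invisible(x)
}

#' Long-format view of an imputation set
#'
#' @param x an `mi_set`.
#' @param row.names,optional,... unused, present for method compatibility.
#' @return A data frame with columns `imputation`, `row` and `y`, one row
#'   per (imputation, subject) pair, suitable for CSV export.
#' @export
as.data.frame.mi_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  n <- nrow(x$completed)
  data.frame(imputation = rep(seq_len(x$m), each = n),
             row = rep(seq_len(n), x$m),
             y = as.vector(x$completed))
}
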