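#' Simulate a bivariate-normal covariate/outcome pair
#'
#' Draws `n` independent pairs \eqn{(X, Y)} from a bivariate normal
#' distribution.  Under this model the regression of \eqn{Y} on \eqn{X} is
#' linear with slope \eqn{\beta_1 = \rho \sqrt{v_y / v_x}} and residual
#' variance \eqn{v_y (1 - \rho^2)}, which is how the sample is generated
#' (covariate first, then outcome given covariate).
#'
#' @param n sample size (at least 2).
#' @param mean_x,mean_y marginal means.
#' @param var_x,var_y marginal variances (positive).
#' @param rho correlation between `x` and `y`, in (-1, 1).
#' @param seed optional integer; when supplied, `set.seed(seed)` is called
#'   first so the sample is reproducible.
#'
#' @return A data frame with columns `x` and `y` and `n` rows.
#' @seealso [sim_binary()], [apply_mnar()]
#' @examples
#' d <- sim_bivnorm(1000, rho = 0.5, seed = 1)
#' cor(d$x, d$y)
#' @export
sim_bivnorm <- function(n, mean_x = 0, mean_y = 0, var_x = 1, var_y = 1,
                        rho = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("'n' must be an integer >= 2")
  if (!is.finite(var_x) || var_x <= 0 || !is.finite(var_y) || var_y <= 0)
    stop("variances must be positive and finite")
  if (!is.finite(rho) || abs(rho) >= 1)
    stop("'rho' must lie strictly between -1 and 1")
  x <- rnorm(n, mean_x, sqrt(var_x))
  slope <- rho * sqrt(var_y / var_x)
  resid_sd <- sqrt(var_y * (1 - rho^2))
  y <- mean_y + slope * (x - mean_x) + rnorm(n, 0, resid_sd)
  data.frame(x = x, y = y)
}

#' Simulate a normal covariate with a logistic binary outcome
#'
#' Draws \eqn{X \sim N(\mu_x, v_x)} and
#' \eqn{Y \sim \mathrm{Bernoulli}(\mathrm{expit}(\Phi_0 + \Phi_1 X))}.
#' With `phi0 = 0` and a symmetric covariate distribution the marginal
#' proportion \eqn{\Pr(Y = 1)} is exactly 0.5 for any slope, which makes
#' this the canonical binary scenario (true proportion 0.5, true slope
#' `phi1`).
#'
#' @param n sample size (at least 2).
#' @param phi0,phi1 intercept and slope on the logit scale.
#' @param mean_x,var_x covariate mean and variance.
#' @inheritParams sim_bivnorm
#'
#' @return A data frame with columns `x` (numeric) and `y` (0/1 integer).
#' @export
sim_binary <- function(n, phi0 = 0, phi1 = 0.5, mean_x = 0, var_x = 1,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("'n' must be an integer >= 2")
  if (!is.finite(var_x) || var_x <= 0) stop("'var_x' must be positive")
  x <- rnorm(n, mean_x, sqrt(var_x))
  y <- as.integer(runif(n) < expit(phi0 + phi1 * x))
  data.frame(x = x, y = y)
}

#' Impose MNAR missingness on the outcome via a logistic selection model
#'
#' Each outcome value is observed with probability
#' \deqn{\Pr(R_i = 1 \mid x_i, y_i) = \mathrm{expit}(\alpha + \gamma x_i +
#' \delta y_i),}
#' independently across subjects; `y` is set to `NA` where the indicator
#' draws \eqn{R_i = 0}.  `delta = 0` makes the mechanism MAR given `x`;
#' `delta != 0` makes missingness depend on the (possibly unobserved)
#' outcome itself, i.e. MNAR.  The Bernoulli draws are realised as
#' `runif(n) < p`, so for a fixed seed the mask can be reproduced from the
#' uniform stream.
#'
#' The realised missingness fraction is stochastic, not forced; degenerate
#' draws (no missing or no observed outcomes) are allowed and flagged via
#' the `"degenerate"` attribute so callers can guard downstream steps.
#'
#' @param data data frame with numeric columns `x` and `y` and no missing
#'   values.
#' @param alpha,gamma,delta selection-model intercept, covariate
#'   coefficient and outcome coefficient (the MNAR parameter).
#' @inheritParams sim_bivnorm
#'
#' @return A data frame with columns `x`, `y` (`NA` where unobserved) and
#'   `r` (1 = observed, 0 = missing), plus attributes `y_full` (the
#'   pre-deletion outcome) and `degenerate` (TRUE if `r` is single-class).
#' @examples
#' d <- sim_bivnorm(200, seed = 1)
#' di <- apply_mnar(d, alpha = 0, gamma = 1, delta = 1, seed = 2)
#' mean(di$r)
#' @export
apply_mnar <- function(data, alpha, gamma, delta, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.data.frame(data), all(c("x", "y") %in% names(data)))
  if (anyNA(data$x) || anyNA(data$y))
    stop("'data' must be a complete sample (no missing x or y)")
  if (!all(is.finite(c(alpha, gamma, delta))))
    stop("selection-model parameters must be finite")
  p <- expit(alpha + gamma * data$x + delta * data$y)
  r <- as.integer(runif(nrow(data)) < p)
  out <- data.frame(x = data$x, y = ifelse(r == 1L, data$y, NA_real_), r = r)
  attr(out, "y_full") <- data$y
  attr(out, "degenerate") <- all(r == 1L) || all(r == 0L)
  out
}

#' Rank-based AUROC of missingness on covariate and outcome
#'
#' Quantifies how strongly the pair \eqn{(X, Y)} predicts the observation
#' indicator \eqn{R}: a logistic regression of `r` on `x` and `y` is fitted
#' to the pre-deletion sample, and the area under the ROC curve of its
#' fitted probabilities against `r` is returned.  The AUROC is computed by
#' the Mann-Whitney rank statistic with midrank tie-averaging, so it is
#' invariant to any strictly increasing transform of the scores.  0.5 means
#' missingness is unpredictable from \eqn{(X, Y)} (MCAR-like); 1 means it
#' is fully determined.
#'
#' @param data complete pre-deletion sample: data frame with columns `x`
#'   and `y` (no missing values).
#' @param r 0/1 observation indicator of the same length (1 = observed).
#'
#' @return A single number in \[0, 1\].
#' @examples
#' d <- sim_bivnorm(500, seed = 1)
#' di <- apply_mnar(d, 0, 1, 1, seed = 2)
#' missingness_auroc(d, di$r)
#' @export
missingness_auroc <- function(data, r) {
  stopifnot(is.data.frame(data), all(c("x", "y") %in% names(data)))
  r <- as.integer(r)
  if (length(r) != nrow(data)) stop("'r' must have one entry per row")
  if (length(unique(r)) < 2L)
    stop("AUROC undefined: 'r' has a single class")
  fit <- glm(r ~ x + y, family = binomial(), data = data)
  auroc(fitted(fit), r)
}

# Mann-Whitney AUROC with midrank ties: P(score_1 > score_0) + P(=)/2.
auroc <- function(score, label) {
  rk <- rank(score)
  n1 <- sum(label == 1L)
  n0 <- length(label) - n1
  (sum(rk[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Read and write incomplete samples as CSV
#'
#' Samples travel as three-column CSV files with header `x,y,r`; a missing
#' outcome is an empty field and `r` is 1 where `y` is observed.
#' `write_sample_csv()` enforces the consistency of `y` and `r`;
#' `read_sample_csv()` reconstructs `r` from the missingness pattern when
#' the column is absent.
#'
#' @param sample data frame with columns `x`, `y` and optionally `r`.
#' @param path file path.
#' @return `read_sample_csv()` returns a data frame with columns `x`, `y`,
#'   `r`; `write_sample_csv()` returns `path` invisibly.
#' @export
write_sample_csv <- function(sample, path) {
  stopifnot(all(c("x", "y") %in% names(sample)))
  r <- sample$r %||% as.integer(!is.na(sample$y))
  if (any((r == 0L) != is.na(sample$y)))
    stop("'y' must be missing exactly where r = 0")
  write.csv(data.frame(x = sample$x, y = sample$y, r = r),
            path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_sample_csv
#' @export
read_sample_csv <- function(path) {
  d <- read.csv(path, colClasses = c(x = "numeric", y = "numeric"))
  if (!all(c("x", "y") %in% names(d)))
    stop("sample CSV must have columns 'x' and 'y'")
  if (is.null(d$r)) d$r <- as.integer(!is.na(d$y))
  if (any((d$r == 0L) != is.na(d$y)))
    stop("inconsistent sample CSV: 'y' must be missing exactly where r = 0")
  d[c("x", "y", "r")]
}
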