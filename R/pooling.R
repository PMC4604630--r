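# Validate a per-imputation estimates table: columns estimate, se.
as_estimates <- function(estimates) {
  if (inherits(estimates, "mi_estimate"))
    estimates <- data.frame(estimate = estimates$estimate, se = estimates$se)
  stopifnot(is.data.frame(estimates),
            all(c("estimate", "se") %in% names(estimates)))
  if (!all(is.finite(estimates$estimate)) || !all(is.finite(estimates$se)))
    stop("estimates and standard errors must be finite")
  estimates
}

new_pooled <- function(estimate, within, between, m, mechanism,
                       delta = NA_real_) {
  structure(
    list(estimate = estimate,
         within = within, between = between,
         variance = within + (1 + 1 / m) * between,
         m = m, mechanism = mechanism, delta = delta),
    class = "pooled_mi")
}

#' Rubin's-rules pooling of per-imputation estimates (MAR)
#'
#' Combines \eqn{m \ge 2} per-imputation estimates into the standard MI
#' estimate: the point estimate is the mean of the \eqn{\hat\theta_j}, and
#' its variance is the within-imputation variance (mean squared standard
#' error) plus \eqn{(1 + 1/m)} times the between-imputation variance
#' \eqn{\sum_j (\hat\theta_j - \bar\theta)^2 / (m - 1)}.
#'
#' @param estimates data frame with columns `estimate` and `se`, one row
#'   per imputation (as from [analyze_imputations()]).
#'
#' @return An object of class `pooled_mi` with elements `estimate`,
#'   `within`, `between`, `variance`, `m`, `mechanism` (`"MAR"`).
#' @seealso [mnar_pool()], [delta_weights()]
#' @examples
#' rubin_pool(data.frame(estimate = c(1, 3), se = c(1, 1)))
#' @export
rubin_pool <- function(estimates) {
  est <- as_estimates(estimates)
  m <- nrow(est)
  if (m < 2L) stop("Rubin pooling needs m >= 2 imputations")
  point <- mean(est$estimate)
  within <- mean(est$se^2)
  between <- sum((est$estimate - point)^2) / (m - 1)
  new_pooled(point, within, between, m, "MAR")
}

#' Importance weights for the MNAR sensitivity analysis
#'
#' Computes the per-imputation weights of the selection-model reweighting:
#' the raw weight of imputation \eqn{j} is
#' \eqn{\tilde w_j(\delta) = \exp(-\delta S_j)} with
#' \eqn{S_j = \sum_{i \in I_Y} y_{ij}} the sum of that imputation's imputed
#' values, normalised to \eqn{w_j(\delta) = \tilde w_j / \sum_k \tilde w_k}.
#' For \eqn{\delta > 0} the imputation with the smallest sum of imputed
#' values is up-weighted; for \eqn{\delta < 0} the largest.  Weights are
#' computed in log space with max-subtraction, so arbitrarily large
#' \eqn{|\delta S_j|} cannot overflow; the raw weights are therefore
#' reported up to a common positive factor (only their ratios are defined).
#'
#' @param imps an `mi_set`, or directly the numeric vector of sums
#'   \eqn{S_j}.
#' @param delta sensitivity parameter \eqn{\delta}: log-odds change in the
#'   probability of observing the outcome per unit of outcome.  `delta = 0`
#'   (MAR) gives uniform weights.
#'
#' @return An object of class `delta_weights`: list with `delta`, `sums`,
#'   `raw` (up to a common factor) and `normalized` (summing to 1).
#' @examples
#' delta_weights(c(1, 2), delta = 1)$normalized  # c(0.731..., 0.268...)
#' @export
delta_weights <- function(imps, delta) {
  sums <- if (inherits(imps, "mi_set")) imps$sums else as.numeric(imps)
  if (length(sums) < 1L) stop("need at least one imputation")
  if (!all(is.finite(sums))) stop("sums of imputed values must be finite")
  if (!is.finite(delta)) stop("'delta' must be finite")
  lw <- -delta * sums
  lw <- lw - max(lw)
  raw <- exp(lw)
  structure(
    list(delta = delta, sums = sums, raw = raw,
         normalized = raw / sum(raw)),
    class = "delta_weights")
}

#' @export
print.delta_weights <- function(x, ...) {
  m <- length(x$normalized)
  cat("delta-weights: delta =", x$delta, ", m =", m, "\n")
  cat("  max normalized weight:", format(max(x$normalized), digits = 4),
      "(uniform would be", format(1 / m, digits = 4), ")\n")
  invisible(x)
}

#' Delta-weighted pooling of per-imputation estimates (MNAR)
#'
#' The MNAR estimate is the weighted average
#' \eqn{\hat\theta^{MNAR}(\delta) = \sum_j w_j(\delta) \hat\theta_j},
#' with variance approximated by the weighted within-imputation variance
#' \eqn{\sum_j w_j \cdot se_j^2} plus \eqn{(1 + 1/m)} times the weighted
#' between-imputation variance
#' \eqn{\sum_j w_j (\hat\theta_j - \hat\theta^{MNAR})^2}.  The weighted
#' between-variance is used as is (no \eqn{m/(m-1)} correction), so at
#' \eqn{\delta = 0} it equals \eqn{(m-1)/m} times the Rubin
#' between-variance while the point estimate matches Rubin's exactly.
#'
#' @inheritParams rubin_pool
#' @param weights a `delta_weights` object of matching length.
#' @return An object of class `pooled_mi` with `mechanism = "MNAR"` and
#'   the `delta` used.
#' @examples
#' est <- data.frame(estimate = c(1, 3), se = c(1, 1))
#' mnar_pool(est, delta_weights(c(1, 2), delta = 0))
#' @export
mnar_pool <- function(estimates, weights) {
  est <- as_estimates(estimates)
  stopifnot(inherits(weights, "delta_weights"))
  m <- nrow(est)
  if (m < 2L) stop("MNAR pooling needs m >= 2 imputations")
  w <- weights$normalized
  if (length(w) != m)
    stop("weights and estimates refer to different numbers of imputations")
  point <- sum(w * est$estimate)
  within <- sum(w * est$se^2)
  between <- sum(w * (est$estimate - point)^2)
  new_pooled(point, within, between, m, "MNAR", weights$delta)
}

#' @export
print.pooled_mi <- function(x, digits = 4, ...) {
  cat("Pooled MI estimate (", x$mechanism, sep = "")
  if (x$mechanism == "MNAR") cat(", delta = ", format(x$delta), sep = "")
  cat("), m = ", x$m, "\n", sep = "")
  cat("  estimate: ", format(x$estimate, digits = digits),
      "  se: ", format(sqrt(x$variance), digits = digits), "\n", sep = "")
  cat("  variance components: within ", format(x$within, digits = digits),
      ", between ", format(x$between, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Serialise a pooled estimate to JSON
#'
#' @param x a `pooled_mi` object.
#' @param estimand optional estimand label to embed.
#' @param path optional file; when omitted the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
pooled_json <- function(x, estimand = NULL, path = NULL) {
  stopifnot(inherits(x, "pooled_mi"))
  obj <- list(estimand = estimand, mechanism = x$mechanism, m = x$m,
              delta = if (x$mechanism == "MNAR") x$delta else NULL,
              estimate = x$estimate, se = sqrt(x$variance),
              variance = x$variance, within = x$within, between = x$between)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
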