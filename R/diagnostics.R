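#' Weight-versus-estimate diagnostic for the delta-weighted pooling
#'
#' Pairs each imputation's normalised weight with its MAR estimate
#' \eqn{\hat\theta_j}.  A healthy reweighting spreads the weight over many
#' imputations (all near the uniform reference \eqn{1/m}); one or two
#' imputations carrying most of the weight signal that the importance
#' weights are effectively unbounded and the MNAR estimate is driven by a
#' single extreme imputed dataset.
#'
#' @param imps an `mi_set` (or a `delta_weights` object).
#' @param estimates per-imputation estimates (data frame with `estimate`,
#'   `se`).
#' @param delta sensitivity parameter at which to compute the weights
#'   (ignored when `imps` is already a `delta_weights`).
#'
#' @return An object of class `weight_diagnostic`: data frame with columns
#'   `imputation`, `weight`, `estimate`, and attributes `reference`
#'   (\eqn{1/m}), `mar` (the Rubin-pooled estimate) and `delta`.
#' @seealso [running_mnar()], [plot.weight_diagnostic()]
#' @export
weight_diagnostic <- function(imps, estimates, delta = 0) {
  w <- if (inherits(imps, "delta_weights")) imps else delta_weights(imps, delta)
  est <- as_estimates(estimates)
  m <- length(w$normalized)
  if (nrow(est) != m)
    stop("weights and estimates refer to different numbers of imputations")
  out <- data.frame(imputation = seq_len(m), weight = w$normalized,
                    estimate = est$estimate)
  attr(out, "reference") <- 1 / m
  attr(out, "mar") <- mean(est$estimate)
  attr(out, "delta") <- w$delta
  class(out) <- c("weight_diagnostic", "data.frame")
  out
}

#' Running MNAR estimate over the first k imputations
#'
#' Recomputes the delta-weighted estimate cumulatively: the k-th element
#' uses the raw weights of the first k imputations only, renormalised,
#' \eqn{\sum_{j \le k} \tilde w_j \hat\theta_j / \sum_{j \le k} \tilde w_j}.
#' Large vertical steps late in the sequence, or a drift towards the edge
#' of the range of the per-imputation estimates, indicate that single
#' imputations dominate the weighting.
#'
#' @param estimates per-imputation estimates (data frame with `estimate`,
#'   `se`).
#' @param weights a `delta_weights` object of matching length.
#' @return An object of class `running_mnar`: data frame with columns
#'   `imputation` and `estimate` (the running weighted estimate), with the
#'   per-imputation estimates kept as attribute `mar_estimates`.
#' @export
running_mnar <- function(estimates, weights) {
  est <- as_estimates(estimates)
  stopifnot(inherits(weights, "delta_weights"))
  m <- nrow(est)
  if (length(weights$raw) != m)
    stop("weights and estimates refer to different numbers of imputations")
  run <- cumsum(weights$raw * est$estimate) / cumsum(weights$raw)
  out <- data.frame(imputation = seq_len(m), estimate = run)
  attr(out, "mar_estimates") <- est$estimate
  attr(out, "delta") <- weights$delta
  class(out) <- c("running_mnar", "data.frame")
  out
}

#' Graphical selection of a plausible range for delta
#'
#' Scans a grid of candidate sensitivity parameters and applies the two
#' weight-based rules for a usable delta: the maximum normalised weight
#' should not exceed `max_weight_cap` (default 0.5), and at least
#' `min_count` normalised weights (default 5) should lie at or above the
#' uniform level \eqn{1/m}.  The selected range is the contiguous run of
#' passing grid values containing \eqn{\delta = 0} when 0 passes,
#' otherwise the widest passing run; the passing set may be empty.
#'
#' "At or above \eqn{1/m}" is read with tolerance `tol` (non-strict),
#' since at \eqn{\delta = 0} every weight equals \eqn{1/m} exactly and the
#' MAR point must be selectable.
#'
#' @param imps an `mi_set`, or the numeric vector of per-imputation sums
#'   of imputed values.
#' @param grid sorted vector of candidate delta values.
#' @param max_weight_cap cap on the maximum normalised weight.
#' @param min_count minimum number of weights at or above \eqn{1/m}.
#' @param tol tolerance for the \eqn{1/m} comparison.
#'
#' @return An object of class `delta_range`: list with the `grid`, per-grid
#'   `max_weight` and `n_above` (count of weights \eqn{\ge 1/m}), logical
#'   `pass`, and the selected interval `lo`, `hi` (both `NA` when no grid
#'   point passes).
#' @examples
#' s <- rnorm(100)
#' select_delta_range(s, grid = seq(-1, 1, by = 0.05))
#' @export
select_delta_range <- function(imps, grid = seq(-2, 2, by = 0.01),
                               max_weight_cap = 0.5, min_count = 5L,
                               tol = 1e-12) {
  sums <- if (inherits(imps, "mi_set")) imps$sums else as.numeric(imps)
  m <- length(sums)
  if (m < min_count)
    stop("need at least 'min_count' (", min_count, ") imputations, got ", m)
  if (length(grid) == 0L || is.unsorted(grid))
    stop("'grid' must be a nonempty sorted vector")
  max_w <- n_above <- numeric(length(grid))
  for (k in seq_along(grid)) {
    w <- delta_weights(sums, grid[k])$normalized
    max_w[k] <- max(w)
    n_above[k] <- sum(w >= 1 / m - tol)
  }
  pass <- max_w <= max_weight_cap + tol & n_above >= min_count
  lo <- hi <- NA_real_
  if (any(pass)) {
    runs <- rle(pass)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- which(runs$values)
    # prefer the run containing delta = 0 when 0 itself passes
    zero_k <- which(pass & abs(grid) <= tol)
    pick <- if (length(zero_k)) {
      keep[starts[keep] <= zero_k[1L] & ends[keep] >= zero_k[1L]][1L]
    } else {
      keep[which.max(grid[ends[keep]] - grid[starts[keep]])]
    }
    lo <- grid[starts[pick]]
    hi <- grid[ends[pick]]
  }
  structure(list(grid = grid, max_weight = max_w, n_above = n_above,
                 pass = pass, lo = lo, hi = hi, m = m,
                 max_weight_cap = max_weight_cap, min_count = min_count),
            class = "delta_range")
}

#' @export
print.delta_range <- function(x, ...) {
  cat("delta-range selection (m = ", x$m, ", max weight <= ",
      x$max_weight_cap, ", >= ", x$min_count, " weights above 1/m)\n",
      sep = "")
  if (is.na(x$lo)) {
    cat("  no delta on the grid satisfies both criteria\n")
  } else {
    cat("  selected range: [", format(x$lo), ", ", format(x$hi), "]\n",
        sep = "")
  }
  invisible(x)
}

#' Plot the weight-versus-estimate diagnostic
#'
#' Normalised weights against per-imputation MAR estimates, with a
#' horizontal reference at the uniform weight \eqn{1/m} and a dashed
#' vertical line at the pooled MAR estimate.
#'
#' @param x a `weight_diagnostic`.
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.weight_diagnostic <- function(x, ...) {
  plot(x$estimate, x$weight,
       xlab = "per-imputation estimate (MAR)",
       ylab = "normalised weight",
       main = sprintf("delta = %g", attr(x, "delta")),
       ylim = c(0, max(x$weight, 2 * attr(x, "reference"))), ...)
  abline(h = attr(x, "reference"), lty = 3)
  abline(v = attr(x, "mar"), lty = 2)
  invisible(x)
}

#' Plot the running MNAR estimate
#'
#' Running weighted estimate against the number of imputations, with the
#' per-imputation MAR estimates marked as a rug on the right axis and a
#' dashed horizontal line at the pooled MAR estimate.
#'
#' @param x a `running_mnar`.
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.running_mnar <- function(x, ...) {
  mar_est <- attr(x, "mar_estimates")
  ylim <- range(x$estimate, mar_est)
  plot(x$imputation, x$estimate, type = "l",
       xlab = "number of imputations",
       ylab = "running MNAR estimate", ylim = ylim,
       main = sprintf("delta = %g", attr(x, "delta")), ...)
  abline(h = mean(mar_est), lty = 2)
  axis(4, at = pretty(ylim), labels = FALSE)
  rug(mar_est, side = 4)
  mtext("per-imputation MAR estimates", side = 4, line = 0.5, cex = 0.8)
  invisible(x)
}

#' Plot the delta-range selection scan
#'
#' Maximum normalised weight against delta with the cap as a horizontal
#' line and the selected range as vertical dashed lines.
#'
#' @param x a `delta_range`.
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.delta_range <- function(x, ...) {
  plot(x$grid, x$max_weight, type = "l", xlab = expression(delta),
       ylab = "maximum normalised weight", ylim = c(0, 1), ...)
  abline(h = x$max_weight_cap, lty = 3)
  abline(h = 1 / x$m, lty = 3, col = "grey")
  if (!is.na(x$lo)) abline(v = c(x$lo, x$hi), lty = 2)
  invisible(x)
}
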