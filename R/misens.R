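#' Fit the delta-weighting MNAR sensitivity analysis
#'
#' One-stop model interface: given a dataset with a partially observed
#' outcome and one fully observed covariate, `misens()` imputes the missing
#' outcomes `m` times under MAR (proper Bayesian draws; normal-linear for a
#' continuous outcome, asymptotic-posterior logistic for a binary one),
#' analyses each completed dataset for the marginal estimand (mean or
#' proportion) and the outcome-on-covariate slope, pools under MAR by
#' Rubin's rules, and reweights the per-imputation estimates by
#' \eqn{w_j(\delta) \propto \exp(-\delta S_j)} to obtain the MNAR estimate
#' at the supplied sensitivity parameter.
#'
#' @param formula model formula `y ~ x` with exactly one covariate; the
#'   response may contain `NA`, the covariate may not.
#' @param data data frame containing the variables.
#' @param m number of imputations (at least 2).
#' @param delta sensitivity parameter \eqn{\delta} for the MNAR analysis;
#'   0 reproduces the MAR analysis.
#' @param family `"gaussian"` or `"binomial"`; by default inferred from
#'   the observed response (0/1 implies binomial).
#' @param seed optional integer seed making the imputations reproducible.
#'
#' @return An object of class `misens`: list with the `mi_set`
#'   (`$imputations`), per-imputation estimate tables (`$estimates`, one
#'   per estimand), the `delta_weights` (`$weights`), and pooled results
#'   (`$mar`, `$mnar`, each a list of `pooled_mi` per estimand).  Methods:
#'   [print.misens()], [summary.misens()], [coef.misens()],
#'   [confint.misens()], [plot.misens()].
#' @examples
#' d <- apply_mnar(sim_bivnorm(300, seed = 1), alpha = 0.12, gamma = 1,
#'                 delta = 0.2, seed = 2)
#' fit <- misens(y ~ x, d, m = 30, delta = 0.2, seed = 3)
#' summary(fit)
#' @export
misens <- function(formula, data, m = 50, delta = 0,
                   family = c("auto", "gaussian", "binomial"),
                   seed = NULL) {
  family <- match.arg(family)
  mf <- model.frame(formula, data, na.action = NULL)
  if (ncol(mf) != 2L)
    stop("'formula' must have exactly one covariate (y ~ x)")
  y <- model.response(mf)
  x <- mf[[2L]]
  if (anyNA(x)) stop("the covariate must be fully observed")
  if (!anyNA(y)) stop("no missing outcome values: nothing to impute")
  sample <- data.frame(x = x, y = y, r = as.integer(!is.na(y)))
  if (family == "auto")
    family <- if (all(y[!is.na(y)] %in% c(0, 1))) "binomial" else "gaussian"
  imps <- if (family == "binomial") {
    impute_logistic(sample, m, seed = seed)
  } else {
    impute_normal(sample, m, seed = seed)
  }
  estimands <- if (family == "binomial") {
    c("marginal_proportion", "logistic_slope")
  } else {
    c("marginal_mean", "linear_slope")
  }
  estimates <- lapply(setNames(estimands, estimands), function(e)
    analyze_imputations(imps, x, e))
  w <- delta_weights(imps, delta)
  structure(
    list(call = match.call(), formula = formula, family = family,
         m = as.integer(m), delta = delta,
         n = nrow(sample), n_missing = sum(sample$r == 0L),
         sample = sample, imputations = imps, estimates = estimates,
         weights = w,
         mar = lapply(estimates, rubin_pool),
         mnar = lapply(estimates, mnar_pool, weights = w)),
    class = "misens")
}

#' @export
print.misens <- function(x, digits = 4, ...) {
  cat("Delta-weighting sensitivity analysis after multiple imputation\n")
  cat("  outcome: ", x$family, "; n = ", x$n, " (", x$n_missing,
      " missing); m = ", x$m, "; delta = ", format(x$delta), "\n\n",
      sep = "")
  tab <- do.call(rbind, lapply(names(x$estimates), function(e)
    data.frame(estimand = e,
               MAR = x$mar[[e]]$estimate,
               MNAR = x$mnar[[e]]$estimate)))
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Summarise a fitted sensitivity analysis
#'
#' @param object a `misens` fit.
#' @param level confidence level for the normal-reference intervals.
#' @param ... unused.
#' @return A data frame of class `summary.misens` with one row per
#'   estimand and mechanism: estimate, standard error, confidence limits,
#'   variance components, and the maximum normalised weight.
#' @export
summary.misens <- function(object, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  rows <- lapply(names(object$estimates), function(e) {
    do.call(rbind, lapply(c("mar", "mnar"), function(mech) {
      p <- object[[mech]][[e]]
      se <- sqrt(p$variance)
      data.frame(estimand = e, mechanism = p$mechanism,
                 estimate = p$estimate, se = se,
                 lower = p$estimate - z * se, upper = p$estimate + z * se,
                 within = p$within, between = p$between)
    }))
  })
  out <- do.call(rbind, rows)
  attr(out, "m") <- object$m
  attr(out, "delta") <- object$delta
  attr(out, "level") <- level
  attr(out, "max_weight") <- max(object$weights$normalized)
  class(out) <- c("summary.misens", "data.frame")
  out
}

#' @export
print.summary.misens <- function(x, digits = 4, ...) {
  cat("m = ", attr(x, "m"), " imputations; MNAR delta = ",
      format(attr(x, "delta")), "; max normalised weight = ",
      format(attr(x, "max_weight"), digits = 3), "\n", sep = "")
  df <- as.data.frame(x)
  df[-(1:2)] <- lapply(df[-(1:2)], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.misens <- function(object, mechanism = c("MNAR", "MAR"), ...) {
  mechanism <- match.arg(mechanism)
  src <- if (mechanism == "MNAR") object$mnar else object$mar
  vapply(src, function(p) p$estimate, numeric(1))
}

#' @export
confint.misens <- function(object, parm, level = 0.95,
                           mechanism = c("MNAR", "MAR"), ...) {
  mechanism <- match.arg(mechanism)
  src <- if (mechanism == "MNAR") object$mnar else object$mar
  if (missing(parm)) parm <- names(src)
  z <- qnorm(1 - (1 - level) / 2)
  t(vapply(src[parm], function(p) {
    se <- sqrt(p$variance)
    c(p$estimate - z * se, p$estimate + z * se)
  }, numeric(2)))
}

#' Diagnostic plots for a fitted sensitivity analysis
#'
#' `which = 1` draws the normalised-weight versus per-imputation-estimate
#' diagnostic, `which = 2` the running MNAR estimate against the number of
#' imputations; both by default, side by side.
#'
#' @param x a `misens` fit.
#' @param which subset of `1:2`.
#' @param estimand which estimand's per-imputation estimates to show
#'   (default: the first, the marginal one).
#' @param ... further arguments passed to the panel plots.
#' @return `x`, invisibly.
#' @export
plot.misens <- function(x, which = 1:2, estimand = names(x$estimates)[1L],
                        ...) {
  est <- x$estimates[[estimand]]
  if (is.null(est)) stop("unknown estimand: ", estimand)
  if (length(which) > 1L) {
    op <- par(mfrow = c(1, length(which)))
    on.exit(par(op))
  }
  if (1L %in% which)
    plot(weight_diagnostic(x$weights, est), ...)
  if (2L %in% which)
    plot(running_mnar(est, x$weights), ...)
  invisible(x)
}

#' Scan the sensitivity parameter for a fitted analysis
#'
#' Convenience wrapper: applies [select_delta_range()] to the fit's
#' imputation set.
#'
#' @param object a `misens` fit.
#' @param ... passed to [select_delta_range()].
#' @return A `delta_range` object.
#' @export
delta_range <- function(object, ...) {
  stopifnot(inherits(object, "misens"))
  select_delta_range(object$imputations, ...)
}
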