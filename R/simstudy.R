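#' Define a Monte-Carlo scenario
#'
#' A scenario bundles the generative model, the MNAR deletion mechanism,
#' the analysis settings and the replication plan for a simulation study.
#' The defaults encode the canonical study conditions: datasets of
#' `n = 100`, a standard bivariate-normal pair with correlation 0.5 for a
#' continuous outcome (or \eqn{X \sim N(0,1)} with
#' \eqn{\mathrm{logit}\,\Pr(Y=1) = 0.5 X} for a binary one), logistic MNAR
#' deletion targeting roughly 50\% missingness, and the sensitivity
#' analysis run at the generating delta (the known-delta setting).
#'
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param n observations per replicate dataset.
#' @param alpha,gamma,delta_gen selection-model parameters of the deletion
#'   mechanism \eqn{\mathrm{logit}\Pr(R=1) = \alpha + \gamma x + \delta y}.
#' @param delta_analysis delta used in the MNAR reweighting (defaults to
#'   `delta_gen`).
#' @param m_list imputation counts to evaluate (each at least 2), or
#'   `NULL` to skip imputation entirely (full-data, complete-case and
#'   AUROC results only).
#' @param n_sims number of replicate datasets.
#' @param seed master seed; replicate `i` uses the derived seed
#'   `(seed + 1000003 * i) mod 2147483647`, so any replicate is
#'   regenerable on its own.
#' @param rho correlation of the bivariate-normal model (continuous).
#' @param phi0,phi1 logit intercept and slope of the binary outcome model.
#' @param estimands estimands to track; defaults to the marginal estimand
#'   and the slope appropriate to the outcome type.
#'
#' @return An object of class `misens_scenario`.
#' @seealso [run_scenario()], [read_scenario()]
#' @export
scenario <- function(outcome_type = c("continuous", "binary"),
                     n = 100, alpha = 0, gamma = 1, delta_gen = 1,
                     delta_analysis = delta_gen,
                     m_list = c(5, 10, 50), n_sims = 200, seed = 1,
                     rho = 0.5, phi0 = 0, phi1 = 0.5,
                     estimands = NULL) {
  outcome_type <- match.arg(outcome_type)
  if (is.null(estimands))
    estimands <- if (outcome_type == "continuous") {
      c("marginal_mean", "linear_slope")
    } else {
      c("marginal_proportion", "logistic_slope")
    }
  if (!is.null(m_list)) {
    m_list <- as.integer(m_list)
    if (any(m_list < 2L)) stop("all 'm_list' values must be >= 2")
  }
  if (n_sims < 1L) stop("'n_sims' must be positive")
  structure(list(outcome_type = outcome_type, n = as.integer(n),
                 alpha = alpha, gamma = gamma, delta_gen = delta_gen,
                 delta_analysis = delta_analysis, m_list = m_list,
                 n_sims = as.integer(n_sims), seed = as.integer(seed),
                 rho = rho, phi0 = phi0, phi1 = phi1,
                 estimands = estimands),
            class = "misens_scenario")
}

#' @export
print.misens_scenario <- function(x, ...) {
  cat("Monte-Carlo scenario: ", x$outcome_type, " outcome, n = ", x$n,
      ", ", x$n_sims, " replicates (seed ", x$seed, ")\n", sep = "")
  cat("  deletion: logit Pr(R=1) = ", x$alpha, " + ", x$gamma, " x + ",
      x$delta_gen, " y;  analysis delta = ", x$delta_analysis, "\n",
      sep = "")
  cat("  imputations m:",
      if (is.null(x$m_list)) "none (no-imputation run)" else x$m_list, "\n")
  invisible(x)
}

#' Read a scenario from a YAML or JSON configuration file
#'
#' Recognised keys are the arguments of [scenario()] (at minimum
#' `outcome_type`, `n`, `alpha`, `gamma`, `delta_gen`, `seed`); unknown
#' keys are an error.  The file format is chosen by extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path configuration file path.
#' @return A `misens_scenario`.
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unrecognised config format (expect .yaml, .yml or .json): ", path)
  }
  unknown <- setdiff(names(cfg), names(formals(scenario)))
  if (length(unknown))
    stop("unknown scenario keys: ", paste(unknown, collapse = ", "))
  do.call(scenario, cfg)
}

# Derived per-replicate seed: documented counter scheme, < 2^31.
replicate_seed <- function(master, replicate_id) {
  as.integer((as.double(master) + 1000003 * replicate_id) %% 2147483647)
}

#' Run one replicate of a scenario
#'
#' Executes the full pipeline for replicate `replicate_id`: generate a
#' complete sample, analyse it (full-data benchmark), delete outcomes via
#' the MNAR mechanism, record the missingness AUROC, run the complete-case
#' analysis, and for each `m` in the scenario's `m_list` impute, analyse
#' each completed dataset, pool by Rubin's rules and by the delta-weighted
#' MNAR rule.  All randomness derives from the replicate seed
#' `(seed + 1000003 * replicate_id) mod 2147483647`, so replicates are
#' mutually independent and individually regenerable.
#'
#' Degenerate draws (a single-class observation indicator, separation in
#' the binary imputation model, a degenerate complete-case analysis)
#' raise an error here; [run_scenario()] catches these and records the
#' replicate as failed.
#'
#' @param sc a `misens_scenario`.
#' @param replicate_id positive integer.
#' @return A list with elements `estimates` (data frame: `method`, `m`,
#'   `estimand`, `estimate`, `se`), `auroc`, `max_weight` (data frame:
#'   `m`, `max_weight`), and `frac_observed`.
#' @export
run_replicate <- function(sc, replicate_id) {
  stopifnot(inherits(sc, "misens_scenario"))
  set.seed(replicate_seed(sc$seed, replicate_id))
  complete <- if (sc$outcome_type == "continuous") {
    sim_bivnorm(sc$n, rho = sc$rho)
  } else {
    sim_binary(sc$n, phi0 = sc$phi0, phi1 = sc$phi1)
  }
  incomplete <- apply_mnar(complete, sc$alpha, sc$gamma, sc$delta_gen)
  if (attr(incomplete, "degenerate"))
    stop("degenerate missingness draw: observation indicator single-class")
  auc <- missingness_auroc(complete, incomplete$r)

  rows <- list()
  add <- function(method, m, estimand, estimate, se) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, m = m, estimand = estimand,
      estimate = estimate, se = se)
  }
  for (e in sc$estimands) {
    a <- analyze(complete$y, complete$x, e)
    add("full", NA_integer_, e, a$estimate, a$se)
    cc <- complete_case(incomplete, e)
    add("complete_case", NA_integer_, e, cc$estimate, cc$se)
  }
  maxw <- list()
  for (m in sc$m_list) {
    imps <- if (sc$outcome_type == "continuous") {
      impute_normal(incomplete, m)
    } else {
      impute_logistic(incomplete, m)
    }
    w <- delta_weights(imps, sc$delta_analysis)
    maxw[[length(maxw) + 1L]] <-
      data.frame(m = m, max_weight = max(w$normalized))
    for (e in sc$estimands) {
      est <- analyze_imputations(imps, incomplete$x, e)
      mar <- rubin_pool(est)
      mnar <- mnar_pool(est, w)
      add("mi_mar", m, e, mar$estimate, sqrt(mar$variance))
      add("mnar_weighted", m, e, mnar$estimate, sqrt(mnar$variance))
    }
  }
  list(estimates = do.call(rbind, rows), auroc = auc,
       max_weight = if (length(maxw)) do.call(rbind, maxw) else NULL,
       frac_observed = mean(incomplete$r))
}

#' Run a full Monte-Carlo scenario
#'
#' Repeats [run_replicate()] over `n_sims` replicates, catching failed
#' replicates (degenerate missingness draws, separation in the binary
#' imputation model), and aggregates: per method x m x estimand the mean
#' estimate across replicates and its Monte-Carlo standard error (the
#' standard deviation of the replicate estimates divided by the square
#' root of the number of successful replicates), the mean missingness
#' AUROC, and the mean of the per-replicate maximum normalised weight.
#'
#' @param sc a `misens_scenario`.
#' @param progress print a progress dot every 100 replicates.
#' @return An object of class `scenario_results`: list with `summary`
#'   (data frame: `method`, `m`, `estimand`, `mean_estimate`, `mc_se`,
#'   `n_reps`), `mean_auroc`, `max_weight` (mean per m), `replicates`
#'   (the replicate-level estimate table), `aurocs`, `n_failed`,
#'   `failures` (messages), and the scenario itself.
#' @examples
#' \donttest{
#' sc <- scenario("continuous", n_sims = 20, m_list = c(5, 10), seed = 1)
#' res <- run_scenario(sc)
#' res$summary
#' }
#' @export
run_scenario <- function(sc, progress = FALSE) {
  stopifnot(inherits(sc, "misens_scenario"))
  if (sc$n_sims < 2L) stop("'n_sims' must be at least 2")
  reps <- vector("list", sc$n_sims)
  failures <- character()
  for (i in seq_len(sc$n_sims)) {
    reps[[i]] <- tryCatch(run_replicate(sc, i), error = function(e) {
      failures <<- c(failures,
                     sprintf("replicate %d: %s", i, conditionMessage(e)))
      NULL
    })
    if (progress && i %% 100L == 0L) message("  replicate ", i)
  }
  ok <- !vapply(reps, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > 0.1 * sc$n_sims)
    stop("more than 10% of replicates failed (", n_failed, "/", sc$n_sims,
         "); first failures:\n  ",
         paste(head(failures, 5), collapse = "\n  "))
  reps <- reps[ok]
  ids <- which(ok)
  est <- do.call(rbind, Map(function(r, id)
    cbind(replicate = id, r$estimates), reps, ids))
  aurocs <- vapply(reps, `[[`, numeric(1), "auroc")
  key <- paste(est$method, ifelse(is.na(est$m), "none", est$m), est$estimand)
  summary_df <- do.call(rbind, lapply(split(est, key), function(d)
    data.frame(method = d$method[1L], m = d$m[1L], estimand = d$estimand[1L],
               mean_estimate = mean(d$estimate),
               mc_se = sd(d$estimate) / sqrt(nrow(d)),
               n_reps = nrow(d))))
  summary_df <- summary_df[order(summary_df$estimand, summary_df$method,
                                 summary_df$m), ]
  rownames(summary_df) <- NULL
  mw <- NULL
  if (!is.null(sc$m_list)) {
    mwall <- do.call(rbind, lapply(reps, `[[`, "max_weight"))
    mw <- stats::aggregate(max_weight ~ m, data = mwall, FUN = mean)
  }
  structure(list(summary = summary_df, mean_auroc = mean(aurocs),
                 max_weight = mw, replicates = est, aurocs = aurocs,
                 n_failed = n_failed, failures = failures, scenario = sc),
            class = "scenario_results")
}

#' @export
print.scenario_results <- function(x, digits = 3, ...) {
  sc <- x$scenario
  cat("Scenario results: ", sc$outcome_type, " outcome, n = ", sc$n,
      ", ", length(x$aurocs), " replicates",
      if (x$n_failed) paste0(" (", x$n_failed, " failed)"), "\n", sep = "")
  cat("  mean missingness AUROC: ", round(x$mean_auroc, digits), "\n\n",
      sep = "")
  for (e in unique(x$summary$estimand)) {
    cat(e, ":\n", sep = "")
    sub <- x$summary[x$summary$estimand == e, ]
    wide <- lapply(split(sub, sub$method), function(d) {
      if (all(is.na(d$m))) round(d$mean_estimate, digits)
      else setNames(round(d$mean_estimate, digits), paste0("m=", d$m))
    })
    for (meth in intersect(c("full", "complete_case", "mi_mar",
                             "mnar_weighted"), names(wide))) {
      cat(sprintf("  %-14s", meth))
      print(wide[[meth]])
    }
    cat("\n")
  }
  invisible(x)
}

#' Write scenario results as tidy CSV plus a JSON run manifest
#'
#' Writes `results.csv` (method, m, estimand, mean_estimate, mc_se,
#' n_reps), `replicates.csv` (the raw replicate-level estimates), and
#' `manifest.json` (scenario configuration, seed scheme, failed-replicate
#' count, package version) into `dir`.
#'
#' @param res a `scenario_results`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario_results <- function(res, dir) {
  stopifnot(inherits(res, "scenario_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$summary, file.path(dir, "results.csv"), row.names = FALSE)
  write.csv(res$replicates, file.path(dir, "replicates.csv"),
            row.names = FALSE)
  manifest <- list(
    scenario = unclass(res$scenario),
    seed_scheme = "replicate i: (seed + 1000003*i) mod 2147483647",
    mean_auroc = res$mean_auroc,
    n_failed = res$n_failed,
    package_version = as.character(utils::packageVersion("misens")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
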