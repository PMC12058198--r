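#' Mean estimation error over replications
#'
#' Squared estimation error per estimated coefficient, averaged over
#' replications: `mean over reps of (1/n_coef) * sum_j (est_j - true_j)^2`.
#' `n_coef` is the number of coefficients the method actually estimates --
#' for an oracle fit restricted to the true support, its support size, with
#' the structurally excluded coefficients contributing zero error; for all
#' other methods the full coefficient count (the default).  This
#' per-estimated-coefficient scaling is what makes relative errors of
#' methods with different model sizes comparable.
#'
#' @param estimates matrix of estimates, one row per replication.
#' @param truth true coefficient vector.
#' @param n_coef divisor: coefficients estimated by the method.
#' @return nonnegative scalar, 0 iff every replication recovered the truth
#'   exactly.
#' @export
mee <- function(estimates, truth, n_coef = length(truth)) {
  estimates <- rbind(estimates)
  if (ncol(estimates) != length(truth))
    stop("dimension mismatch between estimates and truth")
  mean(rowSums(sweep(estimates, 2, truth)^2)) / n_coef
}

#' Mean relative estimation error
#'
#' Ratio of a method's MEE to the reference (FULL-model) MEE; the reference
#' method itself scores exactly 1.
#'
#' @param method_mee method MEE.
#' @param full_mee reference MEE, > 0.
#' @return ratio.
#' @export
mree <- function(method_mee, full_mee) {
  if (full_mee <= 0) stop("reference MEE must be positive")
  method_mee / full_mee
}

#' Correct and incorrect zero counts
#'
#' `C0` counts truly-zero coefficients estimated (exactly, up to `tol`)
#' zero; `IC0` counts truly-nonzero coefficients estimated zero.  The
#' caller excludes the intercept.
#'
#' @param estimate estimated coefficient vector.
#' @param truth true coefficient vector, same length.
#' @param tol zero threshold on the estimates.
#' @return named numeric vector `c(C0 = ..., IC0 = ...)`.
#' @export
count_zeros <- function(estimate, truth, tol = 1e-8) {
  if (length(estimate) != length(truth))
    stop("estimate and truth differ in length")
  z <- abs(estimate) <= tol
  c(C0 = sum(z & truth == 0), IC0 = sum(z & truth != 0))
}

#' Fit one comparator method to a dataset
#'
#' The simulation-study comparators: `FULL` is the unpenalized mixture cure
#' model on all covariates; `ORACLE` the unpenalized model on the true
#' nonzero support only (excluded coefficients reported as exact zeros);
#' `LASSO` is BIC-tuned with the alpha grid fixed at 0; `EN` BIC-tuned over
#' the full alpha grid; `COX` an ordinary Cox proportional-hazards fit
#' ignoring the cure structure (latency only; incidence entries `NA`).
#'
#' @param data a [cp_data()].
#' @param truth_support list with logical vectors `beta` (slopes) and
#'   `gamma` marking the truly nonzero coefficients (ORACLE only).
#' @param method one of `"FULL"`, `"ORACLE"`, `"LASSO"`, `"EN"`, `"COX"`.
#' @param grid a [tune_grid()] for the penalized methods.
#' @param ... passed to [em_fit()].
#' @return list with `beta` (slopes, no intercept; `NA` for COX),
#'   `gamma`, and `fit` (the underlying fit object).
#' @export
fit_method <- function(data, truth_support = NULL,
                       method = c("FULL", "ORACLE", "LASSO", "EN", "COX"),
                       grid = default_grid(), ...) {
  method <- match.arg(method)
  p <- length(data$x_cols); q <- length(data$z_cols)
  if (method == "FULL") {
    fit <- em_fit(data, ...)
    list(beta = unname(fit$params$beta[-1L]), gamma = unname(fit$params$gamma),
         fit = fit, n_est_beta = p, n_est_gamma = q)
  } else if (method == "ORACLE") {
    stopifnot(!is.null(truth_support))
    sub <- data
    sub$x_cols <- data$x_cols[truth_support$beta]
    sub$z_cols <- data$z_cols[truth_support$gamma]
    fit <- em_fit(sub, ...)
    beta <- numeric(p); gamma <- numeric(q)
    beta[truth_support$beta] <- unname(fit$params$beta[-1L])
    gamma[truth_support$gamma] <- unname(fit$params$gamma)
    list(beta = beta, gamma = gamma, fit = fit,
         n_est_beta = sum(truth_support$beta),
         n_est_gamma = sum(truth_support$gamma))
  } else if (method %in% c("LASSO", "EN")) {
    g <- grid
    if (method == "LASSO") { g$cure_alphas <- 0; g$surv_alphas <- 0 }
    tuned <- tune_bic(data, g, ...)
    list(beta = unname(tuned$fit$params$beta[-1L]),
         gamma = unname(tuned$fit$params$gamma), fit = tuned$fit,
         n_est_beta = p, n_est_gamma = q)
  } else {
    r <- data$records
    fml <- stats::as.formula(paste(
      "survival::Surv(tstart, tstop, status) ~",
      paste(data$z_cols, collapse = " + ")))
    fit <- survival::coxph(fml, data = r, ties = "breslow")
    list(beta = rep(NA_real_, p), gamma = unname(stats::coef(fit)),
         fit = fit, n_est_beta = NA_integer_, n_est_gamma = q)
  }
}

#' Run one simulation-study scenario
#'
#' Per replication: simulate a dataset from the scenario (replication seeds
#' derived deterministically from the master seed so all methods see
#' identical data), fit each requested method, and accumulate coefficient
#' estimates.  Aggregates MEE, MREE (reference FULL), and average
#' correct/incorrect zero counts per component.  The incidence intercept is
#' excluded from all metrics.
#'
#' @param scenario a [scenario_config()].
#' @param n_reps number of replications.
#' @param methods character vector of comparators, see [fit_method()].
#' @param seed master seed.
#' @param grid tuning grid for the penalized methods.
#' @param ... passed to [em_fit()].
#' @return a `benchmark_table` data.frame with one row per method:
#'   `scenario`, `N`, `method`, incidence and latency `mee`, `mree`, `c0`,
#'   `ic0`, plus `n_reps` and the count of failed replications.  The raw
#'   per-replication estimates are attached as attribute `"estimates"`.
#' @export
run_scenario <- function(scenario, n_reps, methods = c("FULL", "ORACLE"),
                         seed = 1, grid = default_grid(), ...) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  support <- list(beta = scenario$beta_true != 0,
                  gamma = scenario$gamma_true != 0)
  est <- lapply(methods, function(m)
    list(beta = NULL, gamma = NULL, failed = 0L,
         n_est_beta = NA_integer_, n_est_gamma = NA_integer_))
  names(est) <- methods
  for (r in seq_len(n_reps)) {
    sim <- simulate_dataset(scenario, seed = rep_seeds[r])
    for (m in methods) {
      res <- tryCatch(
        fit_method(sim$data, truth_support = support, method = m,
                   grid = grid, ...),
        error = function(e) e)
      if (inherits(res, "error")) {
        est[[m]]$failed <- est[[m]]$failed + 1L
      } else {
        est[[m]]$beta <- rbind(est[[m]]$beta, res$beta)
        est[[m]]$gamma <- rbind(est[[m]]$gamma, res$gamma)
        est[[m]]$n_est_beta <- res$n_est_beta
        est[[m]]$n_est_gamma <- res$n_est_gamma
      }
    }
  }
  full_inc <- full_lat <- NA_real_
  if ("FULL" %in% methods) {
    full_inc <- mee(est$FULL$beta, scenario$beta_true, est$FULL$n_est_beta)
    full_lat <- mee(est$FULL$gamma, scenario$gamma_true, est$FULL$n_est_gamma)
  }
  rows <- lapply(methods, function(m) {
    eb <- est[[m]]$beta; eg <- est[[m]]$gamma
    has_inc <- !is.null(eb) && !anyNA(eb)
    inc_mee <- if (has_inc) mee(eb, scenario$beta_true, est[[m]]$n_est_beta)
    else NA_real_
    lat_mee <- mee(eg, scenario$gamma_true, est[[m]]$n_est_gamma)
    zb <- if (has_inc)
      rowMeans(apply(eb, 1, count_zeros, truth = scenario$beta_true))
    else c(C0 = NA_real_, IC0 = NA_real_)
    zg <- rowMeans(apply(eg, 1, count_zeros, truth = scenario$gamma_true))
    data.frame(scenario = scenario$name, N = scenario$N, method = m,
               inc_mee = inc_mee,
               inc_mree = if (has_inc && !is.na(full_inc))
                 mree(inc_mee, full_inc) else NA_real_,
               inc_c0 = zb[["C0"]], inc_ic0 = zb[["IC0"]],
               lat_mee = lat_mee,
               lat_mree = if (!is.na(full_lat)) mree(lat_mee, full_lat)
               else NA_real_,
               lat_c0 = zg[["C0"]], lat_ic0 = zg[["IC0"]],
               n_reps = n_reps, n_failed = est[[m]]$failed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("benchmark_table", class(out))
  attr(out, "estimates") <- est
  attr(out, "seed") <- seed
  out
}
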