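#' Tuning grid for the elastic-net penalties
#'
#' @param cure_lams,surv_lams lambda sequences for the incidence and latency
#'   penalties.
#' @param cure_alphas,surv_alphas mixing sequences in [0, 1].
#' @param strategy `"sequential"` (tune the incidence penalty with the
#'   latency penalty held at its mid-grid value, then the latency penalty
#'   holding the incidence winner) or `"cartesian"` (exhaustive).
#' @return a `tune_grid` list.
#' @export
tune_grid <- function(cure_lams, cure_alphas, surv_lams, surv_alphas,
                      strategy = c("sequential", "cartesian")) {
  strategy <- match.arg(strategy)
  stopifnot(all(cure_lams >= 0), all(surv_lams >= 0),
            all(cure_alphas >= 0), all(cure_alphas <= 1),
            all(surv_alphas >= 0), all(surv_alphas <= 1))
  structure(list(cure_lams = cure_lams, cure_alphas = cure_alphas,
                 surv_lams = surv_lams, surv_alphas = surv_alphas,
                 strategy = strategy),
            class = "tune_grid")
}

#' Default tuning grid
#'
#' Per component: 10 lambda values, `exp` of an equispaced sequence on
#' [-7, -2] (so the endpoints are `exp(-7) ~ 9.119e-4` and
#' `exp(-2) = 0.1353353`), and 5 alpha values `0.1, 0.3, 0.5, 0.7, 0.9`.
#'
#' @param strategy search strategy, see [tune_grid()].
#' @return a [tune_grid()].
#' @export
default_grid <- function(strategy = "sequential") {
  lams <- exp(seq(-7, -2, length.out = 10))
  alphas <- seq(0.1, 0.9, length.out = 5)
  tune_grid(lams, alphas, lams, alphas, strategy = strategy)
}

## mid-grid penalty used for the held component in the sequential strategy
mid_spec <- function(lams, alphas) {
  penalty_spec("en", lam = lams[ceiling(length(lams) / 2)],
               alpha = alphas[ceiling(length(alphas) / 2)])
}

#' BIC-driven tuning of the elastic-net mixture cure model
#'
#' Fits [em_fit()] over the tuning grid and returns the minimum-BIC fit.
#' Under the sequential strategy the incidence penalty is tuned first with
#' the latency penalty held at its mid-grid value, then the latency penalty
#' is tuned holding the incidence winner; the cartesian strategy searches
#' the full product.  Along each alpha's lambda path (ascending lambda)
#' fits are warm-started from the previous solution; since a coefficient
#' zeroed by the local quadratic approximation stays zero under a warm
#' start, the active sets are non-increasing along each path.  Tuning is
#' deterministic given the data and grid.
#'
#' @param data a [cp_data()].
#' @param grid a [tune_grid()], default [default_grid()].
#' @param ... passed to [em_fit()] (e.g. `tol`, `max_iter`).
#' @return list with `fit` (the winning `encure_fit`), `best_beta` and
#'   `best_gamma` ([penalty_spec()]s), and `trace` (a data.frame with one
#'   row per evaluated cell: component, lam, alpha, bic, loglik, df,
#'   converged, error flag).
#' @export
tune_bic <- function(data, grid = default_grid(), ...) {
  stopifnot(inherits(grid, "tune_grid"))
  trace <- list()
  best <- list(bic = Inf, fit = NULL, spec_beta = NULL, spec_gamma = NULL)

  eval_cell <- function(component, spec_beta, spec_gamma, warm) {
    fit <- tryCatch(
      em_fit(data, spec_beta = spec_beta, spec_gamma = spec_gamma,
             init = warm, ...),
      error = function(e) e)
    failed <- inherits(fit, "error")
    cell_spec <- if (component == "cure") spec_beta else spec_gamma
    trace[[length(trace) + 1L]] <<- data.frame(
      component = component, lam = cell_spec$lam, alpha = cell_spec$alpha,
      bic = if (failed) NA_real_ else fit$bic,
      loglik = if (failed) NA_real_ else fit$loglik_observed,
      df = if (failed) NA_integer_ else fit$df,
      converged = if (failed) NA else fit$converged,
      error = failed)
    if (failed) return(NULL)
    if (fit$bic < best$bic)
      best <<- list(bic = fit$bic, fit = fit, spec_beta = spec_beta,
                    spec_gamma = spec_gamma)
    fit
  }

  sweep_component <- function(component, lams, alphas, other_spec) {
    comp_best <- list(bic = Inf, spec = NULL)
    for (a in alphas) {
      warm <- NULL
      for (lam in sort(lams)) {
        spec <- penalty_spec("en", lam = lam, alpha = a)
        fit <- if (component == "cure")
          eval_cell("cure", spec, other_spec, warm)
        else eval_cell("surv", other_spec, spec, warm)
        if (!is.null(fit)) {
          warm <- fit$params
          if (fit$bic < comp_best$bic)
            comp_best <- list(bic = fit$bic, spec = spec)
        }
      }
    }
    comp_best$spec
  }

  if (grid$strategy == "sequential") {
    hold_surv <- mid_spec(grid$surv_lams, grid$surv_alphas)
    cure_win <- sweep_component("cure", grid$cure_lams, grid$cure_alphas,
                                hold_surv)
    if (is.null(cure_win)) stop("all incidence tuning fits failed")
    ## reset: BICs from the first phase used a held latency penalty
    best <- list(bic = Inf, fit = NULL, spec_beta = NULL, spec_gamma = NULL)
    sweep_component("surv", grid$surv_lams, grid$surv_alphas, cure_win)
  } else {
    for (la in grid$cure_lams) for (aa in grid$cure_alphas) {
      spec_b <- penalty_spec("en", lam = la, alpha = aa)
      warm <- NULL
      for (a2 in grid$surv_alphas)
        for (l2 in sort(grid$surv_lams)) {
          f <- eval_cell("surv", spec_b,
                         penalty_spec("en", lam = l2, alpha = a2), warm)
          if (!is.null(f)) warm <- f$params
        }
    }
  }
  if (is.null(best$fit)) stop("all tuning fits failed")
  list(fit = best$fit, best_beta = best$fit$penalty_beta,
       best_gamma = best$fit$penalty_gamma,
       trace = do.call(rbind, trace))
}
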