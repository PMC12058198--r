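#' Elastic-net penalty specification
#'
#' Penalty convention: `penalty(b) = lam * ((1 - alpha) * sum|b_j| +
#' alpha * sum b_j^2)`, so `alpha = 0` is the LASSO and `alpha = 1` ridge.
#'
#' @param family one of `"none"`, `"lasso"`, `"ridge"`, `"en"`.
#' @param lam tuning parameter, >= 0.
#' @param alpha mixing parameter in [0, 1]; forced to 0 for `"lasso"`,
#'   1 for `"ridge"`, ignored for `"none"`.
#' @return a `penalty_spec` list.
#' @export
penalty_spec <- function(family = c("none", "lasso", "ridge", "en"),
                         lam = 0, alpha = 0.5) {
  family <- match.arg(family)
  stopifnot(lam >= 0, alpha >= 0, alpha <= 1)
  if (family == "none") { lam <- 0; alpha <- 0 }
  if (family == "lasso") alpha <- 0
  if (family == "ridge") alpha <- 1
  structure(list(family = family, lam = lam, alpha = alpha),
            class = "penalty_spec")
}

#' Evaluate the elastic-net penalty
#' @param spec a [penalty_spec()].
#' @param coefs coefficient vector (the caller excludes any intercept).
#' @return nonnegative penalty value.
#' @export
penalty_value <- function(spec, coefs) {
  spec$lam * ((1 - spec$alpha) * sum(abs(coefs)) +
                spec$alpha * sum(coefs^2))
}

#' Local quadratic approximation of the penalty
#'
#' Diagonal of the matrix `D` such that the penalty is locally approximated
#' (up to a constant) by `0.5 * b' D b` at the current coefficients:
#' `d_j = lam * ((1 - alpha) / (|b_j| + eps) + 2 * alpha)`.  With a leading
#' intercept (`intercept = TRUE`) the first entry is 0 (never penalized).
#'
#' @param spec a [penalty_spec()].
#' @param current_coefs current coefficient vector (including the intercept
#'   slot if `intercept = TRUE`).
#' @param eps perturbation guarding the absolute value at 0.
#' @param intercept logical; is the first entry an unpenalized intercept?
#' @return numeric vector of diagonal entries.
#' @export
lqa_penalty_matrix <- function(spec, current_coefs, eps = 1e-8,
                               intercept = FALSE) {
  stopifnot(eps > 0)
  d <- spec$lam * ((1 - spec$alpha) / (abs(current_coefs) + eps) +
                     2 * spec$alpha)
  if (intercept) d[1L] <- 0
  d
}

## hard zero threshold applied to penalized coefficients (standardized scale)
.zero_tol <- 1e-6

scale_spec <- function(spec, n) {
  spec$lam <- spec$lam * n
  spec
}

#' Penalized weighted logistic M-step
#'
#' Maximizes `sum_i [w_i * b'x_i - log(1 + exp(b'x_i))] - penalty(slopes)`
#' by Newton iterations on the locally quadratic (LQA) penalized system,
#' with step halving on the exact penalized objective.  Coefficients with
#' absolute value below the zero threshold are set exactly to 0; the
#' intercept is never penalized or zeroed.
#'
#' @param design `n x (p + 1)` matrix, intercept column first.
#' @param targets per-subject responses in [0, 1] (posterior weights).
#' @param spec a [penalty_spec()] applied to the slopes.
#' @param init starting coefficients (default 0).
#' @param tol,max_iter inner Newton control.
#' @return coefficient vector (intercept first), with attribute
#'   `"converged"`.
#' @export
logistic_mstep <- function(design, targets, spec = penalty_spec("none"),
                           init = NULL, tol = 1e-8, max_iter = 50) {
  n <- nrow(design); p1 <- ncol(design)
  stopifnot(length(targets) == n, all(targets >= 0), all(targets <= 1))
  b <- if (is.null(init)) numeric(p1) else init
  ## overflow-safe log(1 + e^eta) = max(eta, 0) + log1p(exp(-|eta|))
  loglik <- function(b) {
    eta <- drop(design %*% b)
    sum(targets * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  pen_obj <- function(b) loglik(b) - penalty_value(spec, b[-1L])
  f_cur <- pen_obj(b)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(design %*% b)
    mu <- stats::plogis(eta)
    Dv <- lqa_penalty_matrix(spec, b, intercept = TRUE)
    score <- drop(crossprod(design, targets - mu)) - Dv * b
    Wv <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(design * Wv, design)
    diag(H) <- diag(H) + Dv
    step <- solve(H, score)
    ## step halving on the exact penalized objective
    s <- 1
    repeat {
      b_new <- b + s * step
      f_new <- pen_obj(b_new)
      if (is.finite(f_new) && f_new >= f_cur - 1e-12) break
      s <- s / 2
      if (s < 1e-8) { b_new <- b; f_new <- f_cur; break }
    }
    delta <- max(abs(b_new - b))
    b <- b_new; f_cur <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!is.finite(f_cur)) stop("non-finite penalized logistic objective")
  if (spec$lam > 0) b[-1L][abs(b[-1L]) < .zero_tol] <- 0
  attr(b, "converged") <- converged
  b
}

## ---- weighted penalized Cox partial likelihood ---------------------------
##
## All three pieces (value, score, Hessian) on the precomputed risk
## structure; Breslow tie handling; weights enter multiplicatively in the
## risk sums (events all carry weight 1 in the EM).

cox_pl_pieces <- function(rs, gamma, weights, want_hessian = TRUE) {
  eta <- drop(rs$Z %*% gamma)
  wexp <- weights[rs$subj] * exp(eta)
  S0 <- ksum(wexp, rs$ends)
  if (any(S0 <= 0))
    stop("zero risk-set denominator at event time ",
         rs$event_times[which(S0 <= 0)[1]])
  ll <- sum(eta[rs$event_rows]) - sum(rs$d * log(S0))
  if (!want_hessian) return(list(loglik = ll))
  Zev <- rs$Z[rs$event_rows, , drop = FALSE]
  M <- ksum_mat(rs$Z * wexp, rs$ends) / S0            # K x p means
  score <- colSums(Zev) - colSums(rs$d * M)
  cr <- wexp * (rs$d / S0)[rs$k]
  H <- crossprod(rs$Z * sqrt(cr)) - crossprod(M * sqrt(rs$d))
  list(loglik = ll, score = score, hessian = H)
}

#' Penalized weighted Cox M-step with profiled Breslow baseline
#'
#' Maximizes the weighted Cox partial likelihood (Breslow ties, risk sets
#' from the counting-process rows, per-subject weights) minus the
#' elastic-net penalty, via Newton iterations on the LQA-penalized score
#' with step halving; then computes the weighted Breslow baseline at the
#' maximizer.  Profiling the baseline out of the joint latency objective
#' makes this equivalent to alternating baseline and coefficient updates to
#' convergence.
#'
#' @param data a [cp_data()] (or a prebuilt internal risk structure).
#' @param weights per-subject weights, ordered by id.
#' @param spec a [penalty_spec()].
#' @param init starting coefficients (default 0).
#' @param tol,max_iter inner Newton control.
#' @return list with `gamma`, `baseline` (a [step_cumhaz()]) and
#'   `converged`.
#' @export
cox_mstep <- function(data, weights, spec = penalty_spec("none"),
                      init = NULL, tol = 1e-8, max_iter = 50) {
  rs <- if (inherits(data, "cp_data")) risk_structure(data) else data
  if (rs$K == 0) stop("no events: cannot estimate the latency component")
  weights <- rep_len(weights, rs$n)
  p <- ncol(rs$Z)
  g <- if (is.null(init)) numeric(p) else init
  pen_obj <- function(g, ll) ll - penalty_value(spec, g)
  pieces <- cox_pl_pieces(rs, g, weights)
  f_cur <- pen_obj(g, pieces$loglik)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Dv <- lqa_penalty_matrix(spec, g)
    score <- pieces$score - Dv * g
    H <- pieces$hessian
    diag(H) <- diag(H) + Dv + 1e-10
    step <- solve(H, score)
    s <- 1
    repeat {
      g_new <- g + s * step
      ll_new <- cox_pl_pieces(rs, g_new, weights, want_hessian = FALSE)$loglik
      f_new <- pen_obj(g_new, ll_new)
      if (is.finite(f_new) && f_new >= f_cur - 1e-12) break
      s <- s / 2
      if (s < 1e-8) { g_new <- g; f_new <- f_cur; break }
    }
    delta <- max(abs(g_new - g))
    g <- g_new; f_cur <- f_new
    if (delta < tol) { converged <- TRUE; break }
    if (it < max_iter) pieces <- cox_pl_pieces(rs, g, weights)
  }
  if (spec$lam > 0) g[abs(g) < .zero_tol] <- 0
  bc <- breslow_core(rs, g, weights)
  list(gamma = as.vector(g), baseline = step_cumhaz(rs$event_times, bc$dL),
       converged = converged)
}

#' Mixture cure model parameters
#'
#' @param beta incidence coefficients, intercept first.
#' @param gamma latency coefficients (no intercept).
#' @param baseline a [step_cumhaz()].
#' @return a `cure_model_params` list.
#' @export
cure_model_params <- function(beta, gamma, baseline = step_cumhaz()) {
  stopifnot(inherits(baseline, "step_cumhaz"))
  structure(list(beta = beta, gamma = gamma, baseline = baseline),
            class = "cure_model_params")
}

## Internal: per-subject incidence probabilities and conditional survivals
## given params.  Uses the fast risk-structure path; zero_tail sets survival
## to 0 for subjects censored strictly after the last event time.
subject_quantities <- function(params, data, rs = NULL,
                               incidence_at = "entry", zero_tail = TRUE) {
  if (is.null(rs)) rs <- risk_structure(data)
  x <- covariate_at_entry(data, "incidence", at = incidence_at)
  p_i <- incidence_probability(params$beta, x)
  ## cumulative hazard A_i at the fitted baseline, then S_u = exp(-A)
  if (rs$K > 0) {
    dL_at <- cumhaz_increments_at(params$baseline, rs$event_times)
    eta <- exp(drop(rs$Z %*% params$gamma))
    A <- rowsum_vec(eta * dL_at[rs$k], rs$subj, rs$n)
  } else A <- numeric(rs$n)
  S <- exp(-A)
  if (zero_tail && rs$K > 0) {
    late <- rs$si$status == 0 & rs$si$time > max(rs$event_times)
    S[late] <- 0
  }
  list(p = p_i, S = S, si = rs$si, rs = rs)
}

## increments of `cumhaz` at the requested times (0 where no jump)
cumhaz_increments_at <- function(cumhaz, times) {
  m <- match(times, cumhaz$times)
  out <- numeric(length(times))
  out[!is.na(m)] <- cumhaz$increments[m[!is.na(m)]]
  out
}

#' E-step posterior susceptibility probabilities
#'
#' For an event (`status = 1`) the posterior is exactly 1.  For a censored
#' subject, `p_hat = p * S_u(t) / (1 - p * (1 - S_u(t)))` with `p` the
#' incidence probability at the subject's incidence design vector and `S_u`
#' the conditional survival under the current latency parameters (zero-tail
#' adjusted by default).
#'
#' @param params a [cure_model_params()].
#' @param data a [cp_data()].
#' @param incidence_at `"entry"` or `"last"`, see [covariate_at_entry()].
#' @param zero_tail apply the zero-tail constraint.
#' @return per-subject posterior weights in [0, 1], ordered by id.
#' @export
estep <- function(params, data, incidence_at = "entry", zero_tail = TRUE) {
  q <- subject_quantities(params, data, incidence_at = incidence_at,
                          zero_tail = zero_tail)
  unname(estep_core(q$p, q$S, q$si$status))
}

estep_core <- function(p, S, status) {
  ph <- p * S / (1 - p * (1 - S))
  ph[!is.finite(ph)] <- 0   # p -> 1 with S = 0: posterior limit taken as 0
  ph[status == 1] <- 1
  pmin(pmax(ph, 0), 1)
}

#' Observed-data log-likelihood of the mixture cure model
#'
#' `sum_i delta_i * log[p_i * lambda_i(t_i) * S_u(t_i)] +
#' (1 - delta_i) * log[(1 - p_i) + p_i * S_u(t_i)]`, where the hazard at an
#' event time is the baseline increment there times `exp(z_i(t_i)' gamma)`.
#' Zero probabilities yield `-Inf` (flagged via attribute `"finite"`).
#'
#' @inheritParams estep
#' @return log-likelihood value.
#' @export
observed_loglik <- function(params, data, incidence_at = "entry",
                            zero_tail = TRUE) {
  q <- subject_quantities(params, data, incidence_at = incidence_at,
                          zero_tail = zero_tail)
  observed_loglik_core(params, q)
}

observed_loglik_core <- function(params, q) {
  rs <- q$rs; si <- q$si
  ev <- si$status == 1
  ll_cens <- sum(log((1 - q$p[!ev]) + q$p[!ev] * q$S[!ev]))
  if (any(ev)) {
    dL_at <- cumhaz_increments_at(params$baseline, rs$event_times)
    ## z at own event time = covariates on the final row; use event rows
    Zev <- rs$Z[rs$event_rows, , drop = FALSE]
    kev <- rs$k[rs$event_rows]
    subj_ev <- rs$subj[rs$event_rows]
    haz <- log(dL_at[kev]) + drop(Zev %*% params$gamma)
    ## order event rows by subject to align with q vectors
    ll_ev <- sum(log(q$p[subj_ev]) + haz + log(pmax(q$S[subj_ev], 0)))
  } else ll_ev <- 0
  ll <- ll_ev + ll_cens
  attr(ll, "finite") <- is.finite(ll)
  ll
}

#' BIC score from a log-likelihood
#'
#' `-2 * loglik + df * log(n)`.
#'
#' @param loglik observed-data log-likelihood.
#' @param df number of free coefficients (nonzero slopes in both components
#'   plus the incidence intercept).
#' @param n number of subjects.
#' @return BIC value.
#' @export
bic_score <- function(loglik, df, n) -2 * loglik + df * log(n)

count_df <- function(beta, gamma)
  sum(beta[-1L] != 0) + sum(gamma != 0) + 1L

#' Fit the penalized mixture cure model by EM
#'
#' Iterates the E-step (posterior susceptibility weights), the penalized
#' weighted logistic incidence update, and the penalized weighted Cox
#' latency update with profiled Breslow baseline, until the sup-norm
#' parameter change falls below `tol`.  Covariates are internally
#' standardized to unit variance before penalization (incidence: over the
#' per-subject design rows; latency: pooled over person-intervals) and
#' coefficients are returned on the original scale; the intercept is never
#' penalized.  Default initial values are the unpenalized logistic fit of
#' the event indicator and the unpenalized unit-weight Cox fit.
#'
#' @param data a [cp_data()] with at least one event and one censored
#'   subject.
#' @param spec_beta,spec_gamma [penalty_spec()] for the incidence and
#'   latency coefficients.
#' @param init optional [cure_model_params()] warm start (original scale).
#' @param tol EM convergence threshold on the sup-norm coefficient change.
#' @param max_iter maximum EM iterations.
#' @param mstep_iter Newton updates per component per EM iteration (default
#'   1, a generalized EM: each sweep performs one safeguarded Newton update
#'   of each component; the fixed point is the same penalized solution).
#' @param incidence_at which interval's covariates feed the single
#'   per-subject incidence design vector (`"entry"` or `"last"`).
#' @param zero_tail apply the zero-tail identifiability constraint.
#' @param standardize standardize covariates internally before penalizing.
#' @return an `encure_fit` list: `params` ([cure_model_params()]),
#'   `posteriors`, `loglik_observed`, `bic`, `df`, `n_iter`, `converged`,
#'   `penalty_beta`, `penalty_gamma`, `loglik_trace` (penalized observed
#'   log-likelihood per EM iteration), `n` (subjects).
#' @export
em_fit <- function(data, spec_beta = penalty_spec("none"),
                   spec_gamma = penalty_spec("none"), init = NULL,
                   tol = 1e-6, max_iter = 500, mstep_iter = 1,
                   incidence_at = "entry", zero_tail = TRUE,
                   standardize = TRUE) {
  stopifnot(inherits(data, "cp_data"))
  rs <- risk_structure(data)
  si <- rs$si
  n <- rs$n
  if (rs$K == 0) stop("degenerate data: no events")
  if (all(si$status == 1)) stop("degenerate data: all subjects have events")

  ## Penalized-likelihood convention: the objective is loglik - n * penalty,
  ## so the tuning parameter lives on the per-subject scale of the usual
  ## lambda grids.  Realized by scaling lam by n before the M-steps.
  spec_beta_user <- spec_beta; spec_gamma_user <- spec_gamma
  spec_beta <- scale_spec(spec_beta, n)
  spec_gamma <- scale_spec(spec_gamma, n)

  x <- covariate_at_entry(data, "incidence", at = incidence_at)
  sx <- if (standardize) pmax(apply(x, 2, stats::sd), 1e-12) else rep(1, ncol(x))
  X <- cbind(`(Intercept)` = 1, sweep(x, 2, sx, "/"))
  sz <- if (standardize) pmax(apply(rs$Z, 2, stats::sd), 1e-12) else rep(1, ncol(rs$Z))
  rs$Z <- sweep(rs$Z, 2, sz, "/")

  ## initial values (standardized scale)
  if (is.null(init)) {
    beta <- logistic_mstep(X, si$status)
    cm <- cox_mstep(rs, weights = rep(1, n))
    gamma <- cm$gamma
  } else {
    beta <- init$beta * c(1, sx)
    gamma <- init$gamma * sz
  }

  ## initial baseline: unit-weight Breslow at the initial gamma
  baseline <- step_cumhaz(rs$event_times,
                          breslow_core(rs, gamma, rep(1, n))$dL)

  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0
  ph <- rep(1, n)
  cm <- list(baseline = baseline)
  repeat {
    it <- it + 1
    ## E-step at the current (beta, gamma, baseline)
    S <- subject_surv_std(rs, gamma, cm$baseline, si, zero_tail)
    p_i <- stats::plogis(drop(X %*% beta))
    ph <- estep_core(p_i, S, si$status)

    ## M-step: penalized logistic and penalized Cox with profiled baseline
    ## (one safeguarded Newton update per component per EM sweep by default)
    beta_new <- logistic_mstep(X, ph, spec_beta, init = beta,
                               max_iter = mstep_iter)
    cm <- cox_mstep(rs, weights = ph, spec = spec_gamma, init = gamma,
                    max_iter = mstep_iter)
    gamma_new <- cm$gamma

    ## penalized observed log-likelihood at the updated parameters
    params_std <- cure_model_params(beta_new, gamma_new, cm$baseline)
    q <- list(p = stats::plogis(drop(X %*% beta_new)),
              S = subject_surv_std(rs, gamma_new, cm$baseline, si,
                                   zero_tail),
              si = si, rs = rs)
    ll <- observed_loglik_core(params_std, q)
    ll_trace <- c(ll_trace, as.numeric(ll) -
                    penalty_value(spec_beta, beta_new[-1L]) -
                    penalty_value(spec_gamma, gamma_new))

    delta <- max(abs(c(beta_new - beta, gamma_new - gamma)))
    beta <- beta_new; gamma <- gamma_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }

  ## back to original scale
  beta_orig <- as.vector(beta) / c(1, sx)
  gamma_orig <- as.vector(gamma) / sz
  baseline <- cm$baseline
  params <- cure_model_params(beta_orig, gamma_orig, baseline)
  names(params$beta) <- c("(Intercept)", data$x_cols)
  names(params$gamma) <- data$z_cols
  ll_obs <- ll_trace[length(ll_trace)] +
    penalty_value(spec_beta, beta[-1L]) + penalty_value(spec_gamma, gamma)
  df <- count_df(beta, gamma)
  structure(list(params = params, posteriors = ph,
                 loglik_observed = ll_obs,
                 bic = bic_score(ll_obs, df, n), df = df,
                 n_iter = it, converged = converged,
                 penalty_beta = spec_beta_user, penalty_gamma = spec_gamma_user,
                 loglik_trace = ll_trace, n = n),
            class = "encure_fit")
}

## survival vector at standardized scale given rs (already standardized)
subject_surv_std <- function(rs, gamma, baseline, si, zero_tail) {
  dL_at <- cumhaz_increments_at(baseline, rs$event_times)
  eta <- exp(drop(rs$Z %*% gamma))
  A <- rowsum_vec(eta * dL_at[rs$k], rs$subj, rs$n)
  S <- exp(-A)
  if (zero_tail) {
    late <- si$status == 0 & si$time > max(rs$event_times)
    S[late] <- 0
  }
  S
}

#' @export
print.encure_fit <- function(x, ...) {
  cat("<encure_fit> n =", x$n, " iterations =", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  loglik =", format(x$loglik_observed), " df =", x$df,
      " BIC =", format(x$bic), "\n")
  cat("  incidence:", paste(format(round(x$params$beta, 4)), collapse = " "),
      "\n")
  cat("  latency:  ", paste(format(round(x$params$gamma, 4)), collapse = " "),
      "\n")
  invisible(x)
}
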