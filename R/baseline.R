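#' Step-function cumulative hazard
#'
#' A nonparametric baseline cumulative hazard stored as jump times and
#' nonnegative increments; evaluation is right-continuous,
#' `Lambda0(t) = sum of increments at times <= t`.
#'
#' @param times strictly increasing jump times.
#' @param increments nonnegative increments, same length.
#' @return object of class `step_cumhaz`.
#' @export
step_cumhaz <- function(times = numeric(0), increments = numeric(0)) {
  stopifnot(length(times) == length(increments))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("jump times must be strictly increasing")
  if (any(increments < 0)) stop("negative increments")
  structure(list(times = as.numeric(times),
                 increments = as.numeric(increments)),
            class = "step_cumhaz")
}

#' Evaluate a step cumulative hazard
#' @param cumhaz a [step_cumhaz()].
#' @param t evaluation times (vector).
#' @return `Lambda0(t)`, right-continuous.
#' @export
cumhaz_at <- function(cumhaz, t) {
  k <- findInterval(t, cumhaz$times)
  c(0, cumsum(cumhaz$increments))[k + 1L]
}

#' @export
print.step_cumhaz <- function(x, ...) {
  cat("<step_cumhaz> ", length(x$times), " jumps",
      if (length(x$times))
        sprintf(", Lambda0(max) = %.4g", sum(x$increments)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Nelson-Aalen estimator
#'
#' `dLambda(t_k) = d_k / n_k` at each distinct event time, with `d_k` the
#' number of events at `t_k` and `n_k = #\{j : t_j >= t_k\}` the size of the
#' risk set.  Tied events are pooled into one increment (Breslow handling).
#'
#' @param times observed times (> 0).
#' @param events 0/1 event indicators.
#' @return a [step_cumhaz()].
#' @export
nelson_aalen <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) > 0)
  et <- sort(unique(times[events == 1]))
  if (!length(et)) return(step_cumhaz())
  d <- vapply(et, function(t) sum(times == t & events == 1), numeric(1))
  n_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  step_cumhaz(et, d / n_risk)
}

## ---- risk structure -------------------------------------------------------
##
## Precomputed long representation of the counting-process risk sets used by
## the Breslow estimator, the Cox M-step and the E-step survival: one row per
## (event time k, at-risk subject j) pair, with the latency covariates in
## force for j on the interval containing t_(k).  Subject j is at risk at t
## iff some record has tstart < t <= tstop.  Built once per dataset.
risk_structure <- function(data) {
  r <- data$records
  si <- subject_index(data)
  et <- sort(unique(si$time[si$status == 1]))
  K <- length(et)
  Zall <- as.matrix(r[, data$z_cols, drop = FALSE])
  if (K == 0) {
    return(list(event_times = et, K = 0L, n = nrow(si), si = si,
                k = integer(0), subj = integer(0),
                Z = Zall[integer(0), , drop = FALSE],
                d = numeric(0), event_rows = integer(0)))
  }
  lo <- findInterval(r$tstart, et)            # event times <= tstart excluded
  hi <- findInterval(r$tstop, et)             # event times <= tstop included
  cnt <- hi - lo
  keep <- cnt > 0
  rows <- rep(which(keep), cnt[keep])
  k <- sequence(cnt[keep]) + rep(lo[keep], cnt[keep])
  subj_of_row <- match(r$id, si$id)
  subj <- subj_of_row[rows]
  d <- vapply(et, function(t) sum(si$time == t & si$status == 1), numeric(1))
  ## expanded rows where the at-risk subject has its own event at t_(k)
  ev_subj <- si$status[subj] == 1 & si$time[subj] == et[k]
  ord <- order(k)
  k <- k[ord]
  ## group boundaries of the (sorted) event-time index, for O(n) group sums
  ends <- cumsum(tabulate(k, K))
  list(event_times = et, K = K, n = nrow(si), si = si,
       k = k, subj = subj[ord], Z = Zall[rows[ord], , drop = FALSE],
       d = d, event_rows = which(ev_subj[ord]), ends = ends)
}

## fast group sums over the sorted event-time index using precomputed ends
ksum <- function(x, ends) {
  cs <- cumsum(x)
  c(cs[ends[1]], diff(cs[ends]))
}

ksum_mat <- function(X, ends) {
  out <- matrix(0, length(ends), ncol(X))
  for (j in seq_len(ncol(X))) out[, j] <- ksum(X[, j], ends)
  out
}

## Breslow increments and per-subject latency cumulative hazards from a risk
## structure, given gamma and per-subject weights.  Returns list(dL, A) with
## dL the K increments and A the n-vector  sum_{k: j at risk} e^{z_j(t_k)'g} dL_k.
breslow_core <- function(rs, gamma, weights) {
  eta <- exp(drop(rs$Z %*% gamma))
  denom <- ksum(weights[rs$subj] * eta, rs$ends)
  if (any(denom <= 0))
    stop("zero risk-set denominator at event time ",
         rs$event_times[which(denom <= 0)[1]])
  dL <- rs$d / denom
  A <- rowsum_vec(eta * dL[rs$k], rs$subj, rs$n)
  list(dL = dL, A = A, eta = eta)
}

## rowsum into a dense vector of known length
rowsum_vec <- function(x, g, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

#' Weighted Breslow baseline estimator
#'
#' At each distinct event time `t_(k)`,
#' `dLambda0 = d_k / sum_{j at risk} w_j exp(z_j(t_(k))' gamma)`,
#' with the risk set read off the counting-process rows (`tstart < t <=
#' tstop`) and `z_j(t_(k))` the covariates in force on the interval
#' containing `t_(k)`.  With `gamma = 0` and unit weights this reduces
#' exactly to [nelson_aalen()] on the per-subject observed times.
#'
#' @param data a [cp_data()].
#' @param gamma latency coefficients.
#' @param weights per-subject weights (posterior susceptibility
#'   probabilities in the EM), ordered by subject id; recycled if scalar.
#' @return a [step_cumhaz()].
#' @export
breslow <- function(data, gamma, weights = 1) {
  rs <- risk_structure(data)
  weights <- rep_len(weights, rs$n)
  if (rs$K == 0) return(step_cumhaz())
  bc <- breslow_core(rs, gamma, weights)
  step_cumhaz(rs$event_times, bc$dL)
}

#' Conditional survival of one subject under time-varying covariates
#'
#' `S_u(t_i) = exp(- sum_{t_(k) <= t_i} exp(z_i(t_(k))' gamma) *
#' dLambda0(t_(k)))`, where `z_i(t_(k))` is the covariate row of the
#' subject's interval containing `t_(k)`.  This product-over-increments form
#' is the counting-process generalization of `S0(t)^{exp(gamma'z)}` to
#' piecewise-constant covariates.
#'
#' @param rows data.frame of one subject's counting-process records
#'   (columns `tstart`, `tstop` plus covariates).
#' @param z_cols latency covariate column names.
#' @param gamma latency coefficients.
#' @param cumhaz a [step_cumhaz()] (possibly tail-adjusted, see
#'   [zero_tail_adjust()]).
#' @return survival probability in [0, 1].
#' @export
subject_survival <- function(rows, z_cols, gamma, cumhaz) {
  t_i <- max(rows$tstop)
  keep <- cumhaz$times <= t_i
  if (!any(keep)) return(1)
  tk <- cumhaz$times[keep]; dL <- cumhaz$increments[keep]
  j <- findInterval(tk, rows$tstart, left.open = TRUE)   # tstart < tk
  j <- pmin(pmax(j, 1L), nrow(rows))
  Zi <- as.matrix(rows[j, z_cols, drop = FALSE])
  exp(-sum(exp(drop(Zi %*% gamma)) * dL))
}

#' Zero-tail (Sy-Taylor) adjustment of a baseline cumulative hazard
#'
#' Appends an effectively infinite increment just beyond the last event
#' time, so that conditional survival is 0 for any time strictly beyond it.
#' Censored subjects past the last event then receive posterior weight 0 in
#' the E-step, which makes the cure fraction identifiable under a
#' nonparametric baseline.
#'
#' @param cumhaz a [step_cumhaz()].
#' @param last_event_time largest observed event time.
#' @return adjusted [step_cumhaz()].
#' @export
zero_tail_adjust <- function(cumhaz, last_event_time) {
  tail_t <- last_event_time + max(abs(last_event_time), 1) * 1e-12
  step_cumhaz(c(cumhaz$times[cumhaz$times <= last_event_time], tail_t),
              c(cumhaz$increments[cumhaz$times <= last_event_time], Inf))
}
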