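#' Kaplan-Meier estimator
#'
#' Product-limit estimator of the population survival function, computed
#' via [survival::survfit()].  In cure-rate settings a terminal plateau at
#' a positive level is the visual signature of a cured fraction.
#'
#' @param times observed times.
#' @param events 0/1 event indicators.
#' @return a `surv_curve` list: `times` (distinct observed times),
#'   `surv` (right-continuous step values), `n_risk`.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(times = sf$time, surv = sf$surv, n_risk = sf$n.risk),
            class = "surv_curve")
}

#' @export
print.surv_curve <- function(x, ...) {
  cat("<surv_curve> ", length(x$times), " time points, final S = ",
      format(x$surv[length(x$surv)], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Maller-Zhou test of sufficient follow-up
#'
#' Nonparametric check that follow-up extends far enough past the bulk of
#' the event times for a cure fraction to be identifiable.  With `t_n` the
#' largest observed time and `t*_n` the largest uncensored time, the
#' statistic counts the uncensored times in the closed interval
#' `[2 t*_n - t_n, t*_n]`, `q_n = N_n / n`, with approximate p-value
#' `(1 - q_n)^n`.  The longer observation extends beyond the last event,
#' the wider the interval and the more events it captures, so a small
#' p-value indicates sufficient follow-up for a plateau.  (The interval is
#' closed so that with no censoring beyond the last event it still counts
#' the events tied at `t*_n`.)
#'
#' @param times observed times, n >= 2.
#' @param events 0/1 event indicators.
#' @return list with `q_n`, `N_n`, `p_value`.
#' @export
maller_zhou <- function(times, events) {
  n <- length(times)
  stopifnot(n >= 2, length(events) == n)
  if (!any(events == 1))
    return(list(q_n = 0, N_n = 0L, p_value = 1))
  t_n <- max(times)
  t_star <- max(times[events == 1])
  lo <- 2 * t_star - t_n
  N_n <- sum(events == 1 & times >= lo & times <= t_star)
  q_n <- N_n / n
  list(q_n = q_n, N_n = as.integer(N_n), p_value = (1 - q_n)^n)
}
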