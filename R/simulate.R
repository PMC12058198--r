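#' Equally spaced partition of the time scale
#'
#' Builds the boundary sequence `s_1 < ... < s_J` of the piecewise-constant
#' covariate grid (with `s_0 = 0` implicit), `J` equally spaced boundaries
#' from `s1` to `sJ`.  The default simulation design uses 30 intervals with
#' `s1 = 0.2` and `sJ = 6`.
#'
#' @param J number of boundaries (intervals).
#' @param s1 first boundary, > 0.
#' @param sJ last boundary, >= s1 (equal only when `J = 1`).
#' @return numeric vector of boundaries, class `partition`.
#' @export
make_partition <- function(J, s1, sJ) {
  stopifnot(J >= 1, s1 > 0)
  if (J == 1) {
    if (s1 != sJ) stop("J = 1 requires s1 == sJ")
    return(structure(s1, class = "partition"))
  }
  if (sJ <= s1) stop("sJ must exceed s1")
  structure(seq(s1, sJ, length.out = J), class = "partition")
}

#' Draw piecewise-constant covariate paths
#'
#' For each of `n` subjects and each of `J` intervals, draws a `p`-vector
#' from N(0, Sigma) with AR(1)-type cross-sectional covariance
#' `Sigma[p, q] = rho^|p - q|`, independently across intervals and subjects.
#'
#' @param n subjects.
#' @param J intervals.
#' @param p covariates.
#' @param rho correlation base, |rho| < 1.
#' @return array of dimension `c(n, J, p)`.
#' @export
draw_covariate_paths <- function(n, J, p, rho = 0.5) {
  stopifnot(n >= 1, J >= 1, p >= 1, abs(rho) < 1)
  m <- matrix(stats::rnorm(n * J * p), n * J, p)
  if (p > 1 && rho != 0) {
    Sigma <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
    m <- m %*% chol(Sigma)
  }
  array(m, dim = c(n, J, p))
}

#' Logistic incidence probability
#'
#' Probability of being uncured (susceptible),
#' `p(x) = exp(beta'x) / (1 + exp(beta'x))`, computed overflow-safely.
#'
#' @param beta coefficient vector, intercept first.
#' @param x covariate vector or matrix (rows = subjects) *without* the
#'   intercept column; a leading 1 is supplied internally.
#' @return probability (vector), strictly inside (0, 1) in floating point
#'   except at extreme saturation.
#' @export
incidence_probability <- function(beta, x) {
  x <- rbind(x)  # vector -> 1-row matrix
  if (ncol(x) + 1L != length(beta))
    stop("dimension mismatch: beta has ", length(beta), " entries, x has ",
         ncol(x), " columns (+ intercept)")
  unname(stats::plogis(beta[1L] + drop(x %*% beta[-1L])))
}

## V-scale boundaries of the partition under g(t) = t^{1/shape}:
## g^{-1}(s) = s^shape.
vscale_boundaries <- function(partition, shape) c(0, unclass(partition))^shape

## Vectorized piecewise-exponential sampler.  `log_hazards` is an n x J
## matrix of log interval hazards z_j'gamma; returns n event times T on the
## original scale.  The last interval's hazard extends beyond s_J so the
## inverse-CDF always terminates.
sample_event_times_matrix <- function(log_hazards, partition, shape) {
  n <- nrow(log_hazards); J <- ncol(log_hazards)
  stopifnot(J == length(partition), shape > 0)
  u <- vscale_boundaries(partition, shape)       # length J + 1
  lam <- exp(log_hazards)
  dH <- sweep(lam, 2, diff(u), "*")
  ## n x (J + 1) cumulative hazard at the interval boundaries
  H <- if (J == 1) cbind(0, dH) else cbind(0, t(apply(dH, 1, cumsum)))
  E <- stats::rexp(n)
  V <- numeric(n)
  for (i in seq_len(n)) {
    k <- findInterval(E[i], H[i, ], left.open = TRUE)
    if (k > J) k <- J                            # extend final hazard
    V[i] <- u[k] + (E[i] - H[i, k]) / lam[i, k]
  }
  V^(1 / shape)
}

#' Sample one event time from the piecewise-exponential latency model
#'
#' Draws `V` from the piecewise-exponential law with constant hazard
#' `exp(z_j' gamma)` on the transformed interval
#' `(g^{-1}(s_{j-1}), g^{-1}(s_j)]`, `g(t) = t^{1/shape}`, by inversion of
#' the piecewise-linear cumulative hazard, and returns `T = g(V)`.  The
#' resulting `T` follows a Cox proportional-hazards model with
#' piecewise-constant covariates `z_j` on the partition and baseline hazard
#' `h0(t) = shape * t^(shape - 1)` (so `shape = 3` gives the cubic design
#' baseline `3 t^2`).  Beyond the final boundary the last hazard is
#' extended, making the sampler total.
#'
#' @param z_path `J x p` matrix of latency covariates per interval.
#' @param gamma latency coefficients (length p, no intercept).
#' @param partition a [make_partition()] object (length J).
#' @param shape transformation exponent, > 0.
#' @return one event time.
#' @export
sample_event_time <- function(z_path, gamma, partition, shape) {
  z_path <- rbind(z_path)
  lh <- matrix(drop(z_path %*% gamma), nrow = 1)
  sample_event_times_matrix(lh, partition, shape)
}

#' Simulation scenario configuration
#'
#' Bundles the full generating design: sample size, incidence truth
#' (intercept `b0` plus slopes), latency truth, exponential censoring rate,
#' administrative cap, covariate grid and correlation, and the
#' transformation exponent of the latency baseline.
#'
#' @param N sample size.
#' @param b0 incidence intercept.
#' @param beta_true incidence slope vector (no intercept).
#' @param gamma_true latency coefficient vector.
#' @param censoring_rate rate of the exponential censoring law (0 = none).
#' @param admin_cap administrative censoring time; must equal the last
#'   partition boundary.
#' @param partition covariate-interval boundaries, see [make_partition()].
#' @param rho covariate correlation base.
#' @param shape baseline transformation exponent (`3` gives baseline `3t^2`).
#' @param name optional scenario label.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(N, b0, beta_true, gamma_true, censoring_rate,
                            admin_cap = 6,
                            partition = make_partition(30, 0.2, 6),
                            rho = 0.5, shape = 3, name = "custom") {
  stopifnot(N >= 1, censoring_rate >= 0, shape > 0)
  if (abs(admin_cap - max(partition)) > 1e-12)
    stop("admin_cap must equal the last partition boundary")
  structure(list(N = as.integer(N), b0 = b0, beta_true = beta_true,
                 gamma_true = gamma_true, censoring_rate = censoring_rate,
                 admin_cap = admin_cap, partition = partition, rho = rho,
                 shape = shape, name = name),
            class = "scenario_config")
}

## True coefficient vectors of the 8-covariate simulation design.
design_beta_true <- function() c(1.5, 0, -0.75, 0, -1.5, 0, 0.75, 0)
design_gamma_true <- function() c(-0.7, 0, 1, 0, -0.5, 0.75, 0, 0)

#' Built-in simulation scenarios
#'
#' The six study designs, named `censXX_cureYY` after their nominal
#' censoring and cure levels, all sharing the 8-covariate truths
#' `beta = (1.5, 0, -0.75, 0, -1.5, 0, 0.75, 0)` (plus intercept `b0`) and
#' `gamma = (-0.7, 0, 1, 0, -0.5, 0.75, 0, 0)`, the 30-interval partition on
#' (0.2, 6], covariate correlation base 0.5 and cubic baseline `3t^2`.  The
#' pair `(b0, censoring_rate)` varies by scenario.  Note the names carry the
#' design labels; the realized censoring proportion depends on the event-time
#' law and can differ from the label (see the package vignette).
#'
#' @param name one of `cens40_cure30`, `cens30_cure20`, `cens50_cure30`,
#'   `cens60_cure30`, `cens70_cure60`, `cens70_cure30`.
#' @param N sample size (default 250).
#' @return a [scenario_config()].
#' @export
builtin_scenario <- function(name, N = 250) {
  tab <- list(
    cens40_cure30 = c(b0 = 1.45, lamC = 0.02),
    cens30_cure20 = c(b0 = 2.45, lamC = 0.10),
    cens50_cure30 = c(b0 = 1.40, lamC = 0.40),
    cens60_cure30 = c(b0 = 1.50, lamC = 0.95),
    cens70_cure60 = c(b0 = 0.50, lamC = 0.90),
    cens70_cure30 = c(b0 = -0.70, lamC = 0.40))
  if (!name %in% names(tab))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  v <- tab[[name]]
  scenario_config(N = N, b0 = v[["b0"]],
                  beta_true = design_beta_true(),
                  gamma_true = design_gamma_true(),
                  censoring_rate = v[["lamC"]], name = name)
}

#' Names of the built-in scenarios
#' @return character vector.
#' @export
builtin_scenario_names <- function()
  c("cens40_cure30", "cens30_cure20", "cens50_cure30",
    "cens60_cure30", "cens70_cure60", "cens70_cure30")

#' Simulate a mixture cure dataset with time-varying covariates
#'
#' Generation per subject: draw the incidence covariate path `x`; draw the
#' susceptibility indicator `y ~ Bernoulli(p(x at entry))`; draw the latency
#' covariate path `z`; draw the latent event time `w` from the
#' piecewise-exponential proportional-hazards law (see
#' [sample_event_time()]); draw the censoring time
#' `c = min(Exp(censoring_rate), admin_cap)`.  If `y = 0` (cured) or
#' `w > c`, the subject is censored at `c`; otherwise the event is observed
#' at `w`.  Covariate rows are emitted truncated at the observed time.
#'
#' @param config a [scenario_config()].
#' @param seed optional integer; if given, `set.seed(seed)` is called first
#'   so identical seeds give bit-identical datasets.
#' @return list with elements `data` (a [cp_data()] with covariates
#'   `x1..xp` and `z1..zq`) and `truth` (per-subject `y`, `w`, `c`, the
#'   observed `time`/`status`, and the generating parameter vectors).
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$N
  s <- unclass(config$partition); J <- length(s)
  p <- length(config$beta_true); q <- length(config$gamma_true)

  X <- draw_covariate_paths(n, J, p, config$rho)
  x_entry <- matrix(X[, 1L, ], n, p)
  pr <- incidence_probability(c(config$b0, config$beta_true), x_entry)
  y <- stats::rbinom(n, 1L, pr)
  Z <- draw_covariate_paths(n, J, q, config$rho)
  lh <- matrix(0, n, J)
  for (j in seq_len(J)) lh[, j] <- matrix(Z[, j, ], n, q) %*% config$gamma_true
  w <- sample_event_times_matrix(lh, config$partition, config$shape)
  cens <- if (config$censoring_rate > 0)
    pmin(stats::rexp(n, config$censoring_rate), config$admin_cap)
  else rep(config$admin_cap, n)
  event <- y == 1L & w <= cens
  t_obs <- ifelse(event, w, cens)
  delta <- as.integer(event)

  ## counting-process rows truncated at t_obs
  bounds <- c(0, s)
  n_rows <- pmin(findInterval(t_obs, bounds, left.open = TRUE), J)
  n_rows[t_obs > s[J]] <- J     # safety; t_obs <= admin_cap = s_J by design
  total <- sum(n_rows)
  subj <- rep(seq_len(n), n_rows)
  intv <- sequence(n_rows)
  tstart <- bounds[intv]
  tstop <- pmin(bounds[intv + 1L], t_obs[subj])
  status <- as.integer(delta[subj] == 1L & intv == n_rows[subj])
  xm <- matrix(0, total, p); zm <- matrix(0, total, q)
  flatX <- matrix(X, n * J, p); flatZ <- matrix(Z, n * J, q)
  flat_idx <- (intv - 1L) * n + subj
  xm <- flatX[flat_idx, , drop = FALSE]
  zm <- flatZ[flat_idx, , drop = FALSE]
  colnames(xm) <- paste0("x", seq_len(p))
  colnames(zm) <- paste0("z", seq_len(q))
  df <- data.frame(id = subj, tstart = tstart, tstop = tstop, status = status)
  df <- cbind(df, xm, zm)
  data <- cp_data(df, x_cols = colnames(xm), z_cols = colnames(zm))
  truth <- list(y = y, w = w, c = cens, time = t_obs, status = delta,
                b0 = config$b0, beta_true = config$beta_true,
                gamma_true = config$gamma_true, scenario = config$name)
  list(data = data, truth = truth)
}
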