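test_that("penalty value follows the elastic-net convention", {
  expect_equal(penalty_value(penalty_spec("en", 1, 0.5), numeric(0)), 0)
  expect_equal(penalty_value(penalty_spec("en", 1, 0.5), c(0, 0)), 0)
  # alpha = 0 is pure LASSO
  expect_equal(penalty_value(penalty_spec("en", 1, 0), c(1, -2)), 3)
  expect_equal(penalty_value(penalty_spec("en", 1, 0.5), c(1, -2)),
               0.5 * 3 + 0.5 * 5)
  # family constraints
  expect_equal(penalty_spec("lasso", 2, alpha = 0.7)$alpha, 0)
  expect_equal(penalty_spec("ridge", 2)$alpha, 1)
  expect_equal(penalty_spec("none", 5)$lam, 0)
  expect_error(penalty_spec("en", -1), "lam")
})

test_that("the local quadratic approximation has the stated diagonal", {
  expect_equal(lqa_penalty_matrix(penalty_spec("ridge", 3), c(0.2, -5)),
               c(6, 6))
  expect_equal(lqa_penalty_matrix(penalty_spec("none"), c(1, 2)), c(0, 0))
  expect_equal(lqa_penalty_matrix(penalty_spec("lasso", 1), 0.5, eps = 1e-8),
               2, tolerance = 1e-6)
  # intercept slot is never penalized
  expect_equal(lqa_penalty_matrix(penalty_spec("ridge", 3), c(9, 1),
                                  intercept = TRUE)[1], 0)
})

test_that("E-step posteriors match the closed form", {
  # subject 1: event at t = 1; subject 2: censored at t = 1.5
  df <- data.frame(id = 1:2, tstart = 0, tstop = c(1, 1.5),
                   status = c(1, 0), x1 = 0, z1 = 0)
  d <- cp_data(df, "x1", "z1")
  # gamma = 0, Lambda0(1.5) = log 2 => S_u = 0.5; p = 0.8 for everyone
  pars <- cure_model_params(c(qlogis(0.8), 0), 0, step_cumhaz(1, log(2)))
  ph <- estep(pars, d, zero_tail = FALSE)
  expect_equal(ph[1], 1)                       # events are susceptible
  expect_equal(ph[2], 0.4 / 0.6, tolerance = 1e-12)
  # with survival 1 the posterior is the prior incidence probability
  pars1 <- cure_model_params(c(qlogis(0.5), 0), 0, step_cumhaz())
  expect_equal(estep(pars1, d, zero_tail = FALSE)[2], 0.5)
  # zero-tail: censored strictly after the last event gets weight 0
  expect_equal(estep(pars, d, zero_tail = TRUE)[2], 0)
})

test_that("logistic M-step matches an unpenalized weighted-logistic oracle", {
  set.seed(21)
  X <- cbind(1, matrix(rnorm(150), 50, 3))
  ph <- runif(50)
  ours <- logistic_mstep(X, ph)
  oracle <- stats::coef(stats::glm(ph ~ X[, -1], family = quasibinomial()))
  expect_equal(unname(ours[1:4]), unname(oracle), tolerance = 1e-6)
  # intercept-only closed form
  b0 <- logistic_mstep(matrix(1, 20, 1), rep(0.5, 20))
  expect_equal(unname(b0[1]), 0, tolerance = 1e-8)
})

test_that("full shrinkage zeroes every slope and leaves the mean intercept", {
  set.seed(22)
  X <- cbind(1, matrix(rnorm(200), 50, 4))
  ph <- runif(50)
  b <- logistic_mstep(X, ph, penalty_spec("lasso", 1e6))
  expect_equal(unname(b[-1]), rep(0, 4))
  expect_equal(unname(b[1]), qlogis(mean(ph)), tolerance = 1e-6)
})

test_that("Cox M-step matches coxph on unit weights", {
  sim <- sim_cache(N = 200, seed = 3)
  cm <- cox_mstep(sim$data, weights = 1)
  fml <- survival::Surv(tstart, tstop, status) ~ z1 + z2 + z3 + z4 +
    z5 + z6 + z7 + z8
  oracle <- survival::coxph(fml, data = sim$data$records, ties = "breslow")
  expect_equal(unname(cm$gamma[1:8]), unname(stats::coef(oracle)),
               tolerance = 1e-4)
})

test_that("Cox M-step matches a bisection root on a hand-sized problem", {
  # 4 subjects, single time-fixed covariate, no ties
  df <- data.frame(id = 1:4, tstart = 0, tstop = c(1, 2, 3, 4),
                   status = c(1, 1, 1, 0), x1 = 0,
                   z1 = c(0.5, -0.3, 0.8, 0.1))
  d <- cp_data(df, "x1", "z1")
  z <- df$z1
  # partial-likelihood score by direct enumeration of the three risk sets
  score <- function(g) {
    risk <- list(1:4, 2:4, 3:4)
    ev <- c(1, 2, 3)
    sum(vapply(seq_along(ev), function(k) {
      w <- exp(g * z[risk[[k]]])
      z[ev[k]] - sum(z[risk[[k]]] * w) / sum(w)
    }, numeric(1)))
  }
  root <- stats::uniroot(score, c(-10, 10), tol = 1e-12)$root
  cm <- cox_mstep(d, weights = 1)
  expect_equal(unname(cm$gamma[1]), root, tolerance = 1e-6)
})

test_that("heavy Cox shrinkage returns the weighted Nelson-Aalen baseline", {
  sim <- sim_cache(N = 100, seed = 8)
  w <- rep(c(1, 0.6), 50)
  si <- encure:::subject_index(sim$data)
  w[si$status == 1] <- 1
  cm <- cox_mstep(sim$data, weights = w, spec = penalty_spec("lasso", 1e6))
  expect_equal(unname(cm$gamma), rep(0, 8))
  expect_equal(cm$baseline$increments,
               breslow(sim$data, rep(0, 8), weights = w)$increments)
})

test_that("observed log-likelihood matches hand evaluations", {
  # all censored, empty baseline: survival 1 everywhere, loglik 0
  df <- data.frame(id = 1:2, tstart = 0, tstop = c(1, 2), status = 0,
                   x1 = 0, z1 = 0)
  d <- cp_data(df, "x1", "z1")
  pars <- cure_model_params(c(0.3, 0), 0, step_cumhaz())
  expect_equal(as.numeric(observed_loglik(pars, d)), 0)

  # one uncensored subject, p ~ 1, unit increment at its event time
  df1 <- data.frame(id = 1, tstart = 0, tstop = 1, status = 1, x1 = 0, z1 = 0)
  d1 <- cp_data(df1, "x1", "z1")
  pars1 <- cure_model_params(c(40, 0), 0, step_cumhaz(1, 1))
  expect_equal(as.numeric(observed_loglik(pars1, d1)), -1, tolerance = 1e-8)
})

test_that("BIC arithmetic and monotonicity in df", {
  expect_equal(bic_score(-100, 5, 250), 200 + 5 * log(250))
  expect_equal(bic_score(-100, 5, 250), 227.6073, tolerance = 1e-4)
  expect_equal(bic_score(0, 0, 100), 0)
  expect_lt(bic_score(-50, 2, 100), bic_score(-50, 3, 100))
})

test_that("EM fit is deterministic and penalty family none equals lam 0", {
  sim <- sim_cache(N = 100, seed = 8)
  f1 <- em_fit(sim$data)
  f2 <- em_fit(sim$data)
  expect_identical(f1$params$beta, f2$params$beta)
  expect_identical(f1$params$gamma, f2$params$gamma)
  f3 <- em_fit(sim$data, penalty_spec("en", 0, 0.5), penalty_spec("en", 0, 0.5))
  expect_equal(f1$params$beta, f3$params$beta)
  expect_equal(f1$params$gamma, f3$params$gamma)
})

test_that("the penalized observed log-likelihood ascends over EM iterations", {
  sim <- sim_cache(N = 250, seed = 42)
  fit <- em_fit(sim$data, penalty_spec("en", 0.01, 0.5),
                penalty_spec("en", 0.01, 0.5))
  expect_gte(min(diff(fit$loglik_trace)), -1e-6)
  fit0 <- em_fit(sim$data)
  expect_gte(min(diff(fit0$loglik_trace)), -1e-6)
})

test_that("posteriors are probabilities and exactly 1 on events", {
  sim <- sim_cache(N = 250, seed = 42)
  fit <- em_fit(sim$data)
  si <- encure:::subject_index(sim$data)
  expect_true(all(fit$posteriors >= 0 & fit$posteriors <= 1))
  expect_true(all(fit$posteriors[si$status == 1] == 1))
})

test_that("unpenalized EM recovers the generating coefficients at N = 1000", {
  sim <- sim_cache(N = 1000, seed = 101)
  fit <- em_fit(sim$data)
  # deviations bounded by ~3 Monte-Carlo standard errors at this size
  expect_lt(max(abs(unname(fit$params$beta) -
                      c(1.45, design_truth_beta))), 0.45)
  expect_lt(max(abs(unname(fit$params$gamma) - design_truth_gamma)), 0.25)
})

test_that("degenerate datasets are refused", {
  df <- data.frame(id = 1:2, tstart = 0, tstop = c(1, 2), status = 0,
                   x1 = c(0, 1), z1 = c(1, 0))
  expect_error(em_fit(cp_data(df, "x1", "z1")), "no events")
  df2 <- df; df2$status <- 1
  expect_error(em_fit(cp_data(df2, "x1", "z1")), "all subjects")
})

test_that("nonzero counts shrink monotonically along an ascending lambda path", {
  sim <- sim_cache(N = 150, seed = 77)
  lams <- exp(seq(-7, -2, length.out = 10))
  warm <- NULL
  nz <- integer(0)
  for (lam in lams) {
    f <- em_fit(sim$data, penalty_spec("en", lam, 0.1),
                penalty_spec("en", lam, 0.1), init = warm)
    warm <- f$params
    nz <- c(nz, sum(unname(f$params$beta[-1]) != 0) +
              sum(unname(f$params$gamma) != 0))
  }
  expect_true(all(diff(nz) <= 0))
  expect_lt(nz[10], nz[1])  # the strongest penalty actually removes terms
})
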