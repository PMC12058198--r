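# Shared fixtures, all built in code.

# Hand-sized counting-process dataset: 4 subjects, 1 covariate in each
# component, known risk sets.
tiny_cp <- function() {
  df <- data.frame(
    id     = c(1, 1, 2, 3, 3, 4),
    tstart = c(0, 0.5, 0, 0, 0.5, 0),
    tstop  = c(0.5, 1.0, 0.8, 0.5, 1.5, 2.0),
    status = c(0, 1, 0, 0, 1, 0),
    x1     = c(1, 1, 0, 1, 1, 0),
    z1     = c(0, 1, 1, 0, 0, 1))
  cp_data(df, x_cols = "x1", z_cols = "z1")
}

# Cached medium simulated dataset (one per session) for estimator tests.
sim_cache <- local({
  store <- list()
  function(N = 250, seed = 42) {
    key <- paste(N, seed)
    if (is.null(store[[key]]))
      store[[key]] <<- simulate_dataset(builtin_scenario("cens40_cure30",
                                                         N = N), seed = seed)
    store[[key]]
  }
})

design_truth_beta <- c(1.5, 0, -0.75, 0, -1.5, 0, 0.75, 0)
design_truth_gamma <- c(-0.7, 0, 1, 0, -0.5, 0.75, 0, 0)

expect_no_condition <- function(expr) expect_error(expr, NA)
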