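# Shared fixtures for the test suite. Everything is built in code; sizes are
# kept small enough for a default run while preserving the statistical
# structure the assertions rely on.

default_thresholds <- c(R1 = 4.0, L1 = 4.3, R2 = 3.2, L2 = 3.6)

small_config <- function(seed = 1L) session_config(n_blocks = 1L, seed = seed)

# observer whose true 79.4% threshold sits at the staircase starting level,
# i.e. the stationary regime of the estimator
convergence_observer <- function(slope = 1.5) {
  observer_model(threshold79 = stats::setNames(rep(6, 4), gabor_locations()),
                 slope = slope)
}

p_fun <- function(observer) {
  function(loc, level) observer_p_correct(observer, loc, level)
}

# quiet wrappers: occasional singular fits are expected at n = 12
fit_quiet <- function(...) {
  suppressWarnings(suppressMessages(fit_random_intercept_model(...)))
}
select_quiet <- function(...) suppressWarnings(select_model(...))

# one simulated replicate of the response->score->fit path (no traces)
simulate_delta_table <- function(seed, n_participants = 12L,
                                 observer = observer_model(), ...) {
  co <- simulate_cohort(n_participants = n_participants, observer = observer,
                        seed = seed, ...)
  compute_change_scores(bin_and_score(co$responses))
}

# balanced gaussian change-score table with configurable true effects
make_delta_data <- function(seed, n_participants = 12L, intercept_sd = 2.5,
                            resid_sd = 4.6, cell_means = c(0, 0, 0, 0)) {
  set.seed(seed)
  g <- tidyr::expand_grid(
    participant = sprintf("P%02d", seq_len(n_participants)),
    relevance = c("stepping", "non_stepping"),
    step = c("step1", "step2")
  )
  mu <- stats::setNames(cell_means,
                        c("stepping.step1", "stepping.step2",
                          "non_stepping.step1", "non_stepping.step2"))
  b <- stats::rnorm(n_participants, 0, intercept_sd)
  names(b) <- sprintf("P%02d", seq_len(n_participants))
  g$y <- mu[paste(g$relevance, g$step, sep = ".")] + b[g$participant] +
    stats::rnorm(nrow(g), 0, resid_sd)
  g
}
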