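# Shared fixtures: everything is generated in code under fixed seeds.

small_design <- function(J = 5) toj_design("exp1", n_participants = J)

# short-chain fit for structural tests; convergence warnings are expected
# at these lengths and not the property under test
quick_fit <- function(data, chains = 2, warmup = 600, draws = 600,
                      adapt = 300, seed = 42, ...) {
  suppressWarnings(fit_toj(data, chains = chains, warmup = warmup,
                           draws = draws, adapt = adapt, seed = seed, ...))
}

# one moderately sized fit reused across test files
.fixture_cache <- new.env(parent = emptyenv())
shared_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    dat <- simulate_toj(small_design(6), toj_truth(0.6, 0.05, 40, 5),
                        seed = 3)
    .fixture_cache$fit <- quick_fit(dat, warmup = 800, draws = 800)
    .fixture_cache$data <- dat
  }
  .fixture_cache$fit
}
shared_data <- function() {
  shared_fit()
  .fixture_cache$data
}

# random valid race parameters for property tests
random_race_params <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    v_p = stats::runif(n, 1, 80),
    v_r = stats::runif(n, 1, 80),
    dt = stats::runif(n, -0.15, 0.15)))
}
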