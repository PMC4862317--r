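# Monte-Carlo simulator of the two-stimulus exponential encoding race.
# Serves as an independent brute-force check of the closed-form psychometric
# function and as an optional trial-level data generator.

#' Simulate exponential encoding races
#'
#' Draws trial-level outcomes of the race to visual short-term memory. The
#' probe's encoding stage starts at `t0_probe`; the reference appears `-soa`
#' later (negative SOA: probe leads), so its stage starts at
#' `-soa + t0_reference`. Each stage lasts an exponential time with the
#' stimulus' rate; the stimulus finishing first is reported. Exact ties —
#' a measure-zero event in continuous time — count for the reference.
#'
#' @param v_p,v_r Probe and reference processing rates in Hz.
#' @param soa_ms Signed SOA in milliseconds (negative: probe leads).
#' @param n Number of independent races to simulate.
#' @param t0_probe_ms,t0_reference_ms Ineffective exposure durations, ms.
#' @param seed Integer seed; the same seed reproduces the same races.
#' @return A tibble with one row per race: `trial`, `finish_probe`,
#'   `finish_reference` (seconds since probe onset) and logical `probe_first`.
#' @examples
#' simulate_race(20, 20, soa_ms = 0, n = 5, seed = 1)
#' @export
simulate_race <- function(v_p, v_r, soa_ms = 0, n = 1,
                          t0_probe_ms = 0, t0_reference_ms = 0, seed = 1) {
  assert_rates(v_p, v_r)
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a single count >= 1", call. = FALSE)
  }
  if (!is.finite(soa_ms)) stop("`soa_ms` must be finite", call. = FALSE)
  n <- as.integer(n)
  start_p <- t0_probe_ms / 1000
  start_r <- -soa_ms / 1000 + t0_reference_ms / 1000
  withr::with_seed(seed, {
    finish_p <- start_p + stats::rexp(n, rate = v_p)
    finish_r <- start_r + stats::rexp(n, rate = v_r)
  })
  tibble::tibble(trial = seq_len(n),
                 finish_probe = finish_p,
                 finish_reference = finish_r,
                 probe_first = finish_p < finish_r)
}

#' Monte-Carlo estimate of the probe-first probability
#'
#' Aggregates [simulate_race()] outcomes into a proportion with its binomial
#' standard error. Used as an independent oracle for [p_probe_first()].
#'
#' @inheritParams simulate_race
#' @param n_draws Number of simulated races (`>= 1`).
#' @return A tibble with columns `estimate`, `se`, `n_draws`.
#' @examples
#' estimate_race_prob(27.5, 13.2, soa_ms = -50, n_draws = 1e4, seed = 1)
#' @export
estimate_race_prob <- function(v_p, v_r, soa_ms = 0, n_draws = 1e5,
                               t0_probe_ms = 0, t0_reference_ms = 0,
                               seed = 1) {
  if (!is.numeric(n_draws) || length(n_draws) != 1 || n_draws < 1) {
    stop("`n_draws` must be >= 1", call. = FALSE)
  }
  races <- simulate_race(v_p, v_r, soa_ms = soa_ms, n = n_draws,
                         t0_probe_ms = t0_probe_ms,
                         t0_reference_ms = t0_reference_ms, seed = seed)
  p_hat <- mean(races$probe_first)
  tibble::tibble(estimate = p_hat,
                 se = sqrt(p_hat * (1 - p_hat) / nrow(races)),
                 n_draws = nrow(races))
}
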