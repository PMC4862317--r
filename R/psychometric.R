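# Closed-form TVA psychometric model for two-alternative temporal-order
# judgments. Core math works in seconds and Hz; user-facing grids are in ms.

PROB_EPS <- 1e-9

assert_rates <- function(v_p, v_r) {
  if (!is.numeric(v_p) || !is.numeric(v_r) ||
      any(!is.finite(v_p)) || any(!is.finite(v_r)) ||
      any(v_p <= 0) || any(v_r <= 0)) {
    stop("processing rates `v_p` and `v_r` must be finite and strictly positive (Hz)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Effective onset asynchrony of the encoding race
#'
#' The race between probe and reference towards visual short-term memory does
#' not start at the physical onsets: each stimulus has a maximal ineffective
#' exposure duration `t0` before its exponential encoding stage begins. The
#' effective asynchrony is `delta_t = soa + t0_probe - t0_reference`. Negative
#' values mean the probe's race starts first. With equal `t0` (the default,
#' appropriate when both stimuli are of the same kind), `delta_t` equals the
#' SOA.
#'
#' @param soa Signed stimulus onset asynchrony in seconds; negative means the
#'   probe leads.
#' @param t0_probe,t0_reference Maximal ineffective exposure durations in
#'   seconds, both `>= 0`.
#' @return Signed effective asynchrony in seconds, vectorised over inputs.
#' @examples
#' toj_delta_t(-0.02)
#' toj_delta_t(0, t0_probe = 0.01, t0_reference = 0.03)
#' @export
toj_delta_t <- function(soa, t0_probe = 0, t0_reference = 0) {
  if (any(!is.finite(soa)) || any(!is.finite(t0_probe)) ||
      any(!is.finite(t0_reference))) {
    stop("`soa` and t0 values must be finite", call. = FALSE)
  }
  if (any(t0_probe < 0) || any(t0_reference < 0)) {
    stop("t0 values must be >= 0", call. = FALSE)
  }
  soa + t0_probe - t0_reference
}

#' Probability that the probe is encoded first
#'
#' Closed-form solution of the two-stimulus exponential race. Both stimuli
#' race towards visual short-term memory with exponentially distributed
#' encoding latencies (rates `v_p`, `v_r` in Hz); the observer reports
#' whichever finishes first. For `dt < 0` (probe race starts `|dt|` s early)
#' the probe either completes before the reference starts, with probability
#' `1 - exp(-v_p |dt|)`, or the race becomes simultaneous and the probe wins
#' with probability `v_p / (v_p + v_r)` (Luce's choice rule for competing
#' exponentials). For `dt >= 0` the roles reverse. The function is continuous
#' at `dt = 0`, where it equals the attentional weight `v_p / (v_p + v_r)`.
#'
#' @param v_p,v_r Probe and reference processing rates in Hz (`> 0`).
#' @param dt Signed effective onset asynchrony in seconds (see
#'   [toj_delta_t()]); negative means the probe leads.
#' @return Probability of a "probe first" judgment, vectorised over inputs.
#' @examples
#' p_probe_first(20, 20, 0)      # symmetric simultaneous race: 0.5
#' p_probe_first(27.5, 13.2, -0.05)
#' @export
p_probe_first <- function(v_p, v_r, dt) {
  assert_rates(v_p, v_r)
  if (!is.numeric(dt) || any(!is.finite(dt))) {
    stop("`dt` must be finite (seconds)", call. = FALSE)
  }
  n <- max(length(v_p), length(v_r), length(dt))
  v_p <- rep_len(v_p, n)
  v_r <- rep_len(v_r, n)
  dt <- rep_len(dt, n)
  w <- v_p / (v_p + v_r)
  ifelse(dt < 0,
         1 - exp(v_p * dt) + exp(v_p * dt) * w,
         exp(-v_r * dt) * w)
}

clamp_prob <- function(p, eps = PROB_EPS) {
  pmin(pmax(p, eps), 1 - eps)
}

#' Psychometric curve over an SOA grid
#'
#' Evaluates [p_probe_first()] over a grid of SOAs given in milliseconds, the
#' unit in which TOJ designs are specified. The resulting curve is strictly
#' decreasing in SOA: the later the probe, the fewer "probe first" reports.
#'
#' @param v_p,v_r Probe and reference processing rates in Hz.
#' @param soa_ms Vector of signed SOAs in milliseconds (negative: probe
#'   leads).
#' @param t0_probe_ms,t0_reference_ms Ineffective exposure durations in ms.
#' @return A tibble with columns `soa_ms` and `p_probe_first`.
#' @examples
#' p_curve(20, 20, seq(-100, 100, 20))
#' @export
p_curve <- function(v_p, v_r, soa_ms, t0_probe_ms = 0, t0_reference_ms = 0) {
  if (length(soa_ms) == 0) {
    stop("`soa_ms` must be a nonempty numeric vector", call. = FALSE)
  }
  dt <- toj_delta_t(soa_ms / 1000, t0_probe_ms / 1000, t0_reference_ms / 1000)
  tibble::tibble(soa_ms = soa_ms,
                 p_probe_first = p_probe_first(v_p, v_r, dt))
}

#' Attentional weight and processing capacity of a rate pair
#'
#' TVA decomposes the two race rates into the total processing capacity
#' `C = v_p + v_r` (Hz) and the probe's attentional weight
#' `w = v_p / (v_p + v_r)`, the share of capacity allocated to the probe.
#'
#' @param v_p,v_r Processing rates in Hz.
#' @return A tibble with columns `v_p`, `v_r`, `weight`, `capacity`.
#' @export
rates_to_params <- function(v_p, v_r) {
  assert_rates(v_p, v_r)
  tibble::tibble(v_p = v_p, v_r = v_r,
                 weight = v_p / (v_p + v_r),
                 capacity = v_p + v_r)
}
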