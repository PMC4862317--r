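# Posterior summarisation: kernel-density modes, highest density intervals,
# condition contrasts, the temporal-expectation weight correction, posterior
# predictive curves, and a classical logistic psychometric fit.

#' Highest density interval of a set of draws
#'
#' The shortest contiguous interval containing at least `mass` of the draws:
#' over the sorted draws, every window of `ceiling(mass * N)` consecutive
#' values is a candidate and the narrowest wins.
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @param mass Credibility mass in (0, 1); default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @examples
#' hdi(rnorm(10000))
#' @export
hdi <- function(draws, mass = 0.95) {
  if (!is.numeric(draws) || length(draws) < 100) {
    stop("`draws` must be numeric with at least 100 values", call. = FALSE)
  }
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1) {
    stop("`mass` must lie strictly in (0, 1)", call. = FALSE)
  }
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  starts <- seq_len(n - k + 1)
  widths <- x[starts + k - 1] - x[starts]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k - 1])
}

#' Kernel-density mode of a set of draws
#'
#' The reported point estimate of every parameter: the argmax of a Gaussian
#' kernel density estimate with Silverman's rule-of-thumb bandwidth,
#' evaluated on a 512-point grid spanning the range of the draws. Constant
#' draws return that constant.
#'
#' @param draws Numeric vector of at least 100 draws.
#' @return The mode (scalar).
#' @examples
#' mode_estimate(rbeta(10000, 2, 5))
#' @export
mode_estimate <- function(draws) {
  if (!is.numeric(draws) || length(draws) < 100) {
    stop("`draws` must be numeric with at least 100 values", call. = FALSE)
  }
  if (diff(range(draws)) == 0) {
    return(draws[1])
  }
  d <- stats::density(draws, bw = "nrd0", n = 512,
                      from = min(draws), to = max(draws))
  d$x[which.max(d$y)]
}

#' Mode and HDI of a set of draws
#'
#' @inheritParams hdi
#' @return A one-row tibble: `mode`, `hdi_low`, `hdi_high`, `mass`.
#' @export
posterior_summary <- function(draws, mass = 0.95) {
  h <- hdi(draws, mass)
  tibble::tibble(mode = mode_estimate(draws),
                 hdi_low = h[["lower"]], hdi_high = h[["upper"]],
                 mass = mass)
}

# Accept either a toj_fit (extract one parameter) or a raw draw vector.
as_param_draws <- function(x, parameter) {
  if (inherits(x, "toj_fit")) {
    if (!x$converged) {
      warning("using draws from a fit flagged non-converged", call. = FALSE)
    }
    param_draws(x, parameter)
  } else if (is.numeric(x)) {
    x
  } else {
    stop("expected a toj_fit or a numeric draw vector", call. = FALSE)
  }
}

new_contrast <- function(draws, type, seed, mass = 0.95) {
  s <- posterior_summary(draws, mass)
  structure(list(draws = draws, summary = s,
                 contains_zero = s$hdi_low <= 0 && 0 <= s$hdi_high,
                 type = type, seed = seed),
            class = "toj_contrast")
}

#' Temporal-expectation correction of the salience-condition weight
#'
#' In the neutral condition both targets are visually identical, so the probe
#' weight should be 0.5; any deviation reflects temporal expectation (the
#' probe event always follows the display onset at a fixed interval). The
#' corrected salience weight removes that shared bias at the draw level:
#' `w_clean = w_salience - (w_neutral - 0.5)`, computed over pairs formed by
#' a seeded random permutation of the neutral draws (the two conditions are
#' fit independently, so any pairing is valid; permuting avoids spurious
#' within-chain correlation).
#'
#' @param salience,neutral `toj_fit` objects (or raw draw vectors) for the
#'   salience and neutral condition.
#' @param parameter Weight parameter to correct; default the group mean
#'   weight `"w_m"`.
#' @param seed Seed for the pairing permutation.
#' @param mass HDI mass for the summary.
#' @return A `toj_contrast` with the corrected draws, their mode/HDI summary,
#'   and a `contains_zero` flag (here: whether 0 is credible for the
#'   *corrected weight*, rarely of interest).
#' @examples
#' w_s <- rnorm(1000, 0.658, 0.01)
#' w_n <- rnorm(1000, 0.518, 0.01)
#' weight_correction(w_s, w_n, seed = 1)$summary
#' @export
weight_correction <- function(salience, neutral, parameter = "w_m", seed = 1,
                              mass = 0.95) {
  w_s <- as_param_draws(salience, parameter)
  w_n <- as_param_draws(neutral, parameter)
  if (length(w_s) != length(w_n)) {
    stop("draw counts differ (", length(w_s), " vs ", length(w_n),
         "); thin to a common count first", call. = FALSE)
  }
  perm <- withr::with_seed(seed, sample.int(length(w_n)))
  new_contrast(w_s - (w_n[perm] - 0.5), "weight_correction", seed, mass)
}

#' Posterior difference between two conditions
#'
#' Draw-level difference `a - b` of one group parameter across two
#' independently fitted conditions, paired by a seeded permutation. The
#' `contains_zero` flag reports whether 0 lies inside the 95% HDI of the
#' difference — the criterion used to declare, e.g., processing capacity
#' equal across conditions.
#'
#' @param a,b `toj_fit` objects or raw draw vectors.
#' @param parameter Group parameter to compare (default capacity `"C_m"`).
#' @inheritParams weight_correction
#' @return A `toj_contrast` object.
#' @export
posterior_difference <- function(a, b, parameter = "C_m", seed = 1,
                                 mass = 0.95) {
  d_a <- as_param_draws(a, parameter)
  d_b <- as_param_draws(b, parameter)
  if (length(d_a) != length(d_b)) {
    stop("draw counts differ (", length(d_a), " vs ", length(d_b),
         "); thin to a common count first", call. = FALSE)
  }
  perm <- withr::with_seed(seed, sample.int(length(d_b)))
  new_contrast(d_a - d_b[perm], paste0("difference_", parameter), seed, mass)
}

#' @export
print.toj_contrast <- function(x, ...) {
  cat("<toj_contrast> ", x$type, "\n", sep = "")
  print(x$summary)
  cat("  0 in ", x$summary$mass * 100, "% HDI: ", x$contains_zero, "\n",
      sep = "")
  invisible(x)
}

#' Posterior predictive judgment curves
#'
#' For each retained posterior draw, simulates new binomial counts for every
#' (participant, SOA) cell of the fitted design using the closed-form race
#' probability at that draw's participant rates, pools them into a per-SOA
#' "probe first" proportion, and summarises the proportions across draws by
#' quantiles. A plausibility check: the observed pooled proportions should
#' fall inside the predictive band.
#'
#' @param fit A `toj_fit`.
#' @param seed Seed for the predictive simulation.
#' @param probs Quantiles of the predictive distribution; default
#'   2.5/50/97.5%.
#' @param max_draws Cap on the number of posterior draws used.
#' @return A `toj_ppc`: tibble with `condition`, `soa_ms`, `q025`, `q50`,
#'   `q975` (names follow `probs`) and the observed pooled proportion
#'   `observed`.
#' @export
posterior_predictive <- function(fit, seed = 1,
                                 probs = c(0.025, 0.5, 0.975),
                                 max_draws = 500) {
  stopifnot(inherits(fit, "toj_fit"))
  data <- fit$data
  J <- nrow(fit$participants)
  wide <- fit$draws |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "value")
  n_total <- nrow(wide)
  keep <- if (n_total > max_draws) {
    round(seq(1, n_total, length.out = max_draws))
  } else {
    seq_len(n_total)
  }
  w_mat <- as.matrix(wide[keep, paste0("w[", seq_len(J), "]")])
  C_mat <- as.matrix(wide[keep, paste0("C[", seq_len(J), "]")])
  pid <- match(data$participant, fit$participants$participant)
  dt <- data$soa_ms / 1000
  props <- withr::with_seed(seed, {
    t(vapply(seq_along(keep), function(d) {
      v_p <- C_mat[d, pid] * w_mat[d, pid]
      v_r <- C_mat[d, pid] - v_p
      theta <- p_probe_first(v_p, v_r, dt)
      y <- stats::rbinom(length(theta), data$n_trials, theta)
      tapply(y, data$soa_ms, sum) / tapply(data$n_trials, data$soa_ms, sum)
    }, numeric(dplyr::n_distinct(data$soa_ms))))
  })
  soa_sorted <- sort(unique(data$soa_ms))
  qs <- apply(props, 2, stats::quantile, probs = probs)
  out <- tibble::as_tibble(t(qs), .name_repair = "minimal")
  names(out) <- prob_colname(probs)
  obs <- data |>
    dplyr::group_by(.data$soa_ms) |>
    dplyr::summarise(observed = sum(.data$n_probe_first) / sum(.data$n_trials),
                     .groups = "drop") |>
    dplyr::arrange(.data$soa_ms)
  out <- dplyr::bind_cols(
    tibble::tibble(condition = unique(data$condition), soa_ms = soa_sorted),
    out)
  out$observed <- obs$observed
  class(out) <- c("toj_ppc", class(out))
  out
}

# "q025", "q50", "q975" style column names for quantile levels
prob_colname <- function(p) {
  s <- sub("^0\\.", "", sprintf("%.3f", p))
  s <- sub("0+$", "", s)
  s[nchar(s) < 2] <- paste0(s[nchar(s) < 2], "0")
  paste0("q", s)
}

#' Fraction of observed pooled proportions inside the predictive band
#'
#' @param ppc A `toj_ppc` from [posterior_predictive()].
#' @return Scalar in `[0, 1]`.
#' @export
ppc_coverage <- function(ppc) {
  stopifnot(inherits(ppc, "toj_ppc"))
  lo <- ppc[[grep("^q", names(ppc))[1]]]
  hi <- ppc[[rev(grep("^q", names(ppc)))[1]]]
  mean(ppc$observed >= lo & ppc$observed <= hi)
}

#' Classical logistic psychometric fit
#'
#' The conventional analysis of TOJ data: a maximum-likelihood logistic
#' regression of the "probe first" proportion on SOA, per participant and
#' pooled over participants. The point of subjective simultaneity (PSS) is
#' the SOA at which both orders are equally likely; the slope is the
#' derivative of the fitted probability at the PSS (per ms, negative because
#' "probe first" reports fall as the probe is delayed). Fits with complete
#' separation or a flat response are flagged rather than dropped.
#'
#' @param data A single-condition dataset with at least 3 distinct SOAs with
#'   nonzero trials.
#' @return A tibble with one row per participant plus one `"pooled"` row:
#'   `condition`, `participant`, `pss_ms`, `slope_per_ms`, `flagged`.
#' @export
fit_logistic <- function(data) {
  data <- validate_toj_data(data)
  if (dplyr::n_distinct(data$condition) > 1) {
    stop("`data` contains multiple conditions; fit each separately",
         call. = FALSE)
  }
  if (dplyr::n_distinct(data$soa_ms[data$n_trials > 0]) < 3) {
    stop("need at least 3 distinct SOAs with nonzero trials", call. = FALSE)
  }
  fit_one <- function(d, who) {
    flagged <- FALSE
    fit <- withCallingHandlers(
      stats::glm(cbind(n_probe_first, n_trials - n_probe_first) ~ soa_ms,
                 family = stats::binomial(), data = d),
      warning = function(w) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      })
    b <- stats::coef(fit)
    if (!is.finite(b[2]) || b[2] == 0) {
      flagged <- TRUE
      pss <- NA_real_
      slope <- NA_real_
    } else {
      pss <- -b[1] / b[2]
      slope <- b[2] / 4
    }
    tibble::tibble(condition = unique(d$condition), participant = who,
                   pss_ms = unname(pss), slope_per_ms = unname(slope),
                   flagged = flagged)
  }
  per_part <- data |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(d) fit_one(d, as.character(d$participant[1])))
  dplyr::bind_rows(per_part, fit_one(data, "pooled"))
}
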