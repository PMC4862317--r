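test_that("HDI matches analytic intervals and is the shortest window", {
  expect_error(hdi(rnorm(50)), "at least 100")
  expect_error(hdi(rnorm(200), mass = 1.2), "in \\(0, 1\\)")
  expect_equal(hdi(rep(3.2, 500)), c(lower = 3.2, upper = 3.2))
  z <- withr::with_seed(1, rnorm(1e6))
  h <- hdi(z)
  expect_lt(max(abs(unname(h) - c(-1.96, 1.96))), 0.02)
  u <- withr::with_seed(2, runif(1e6))
  expect_lt(abs(unname(diff(hdi(u))) - 0.95), 0.01)
  # shortest-window property, checked against an exhaustive scan
  x <- sort(withr::with_seed(3, rexp(500)))
  h <- hdi(x, 0.9)
  k <- ceiling(0.9 * length(x))
  widths <- x[k:length(x)] - x[1:(length(x) - k + 1)]
  expect_equal(unname(diff(h)), min(widths))
  expect_gte(mean(x >= h[1] & x <= h[2]), 0.9)
})

test_that("kernel-density mode matches analytic modes", {
  expect_error(mode_estimate(rnorm(10)), "at least 100")
  expect_equal(mode_estimate(rep(0.7, 200)), 0.7)
  b <- withr::with_seed(4, rbeta(1e6, 2, 5))
  expect_lt(abs(mode_estimate(b) - 0.2), 0.02)  # (a-1)/(a+b-2)
  z <- withr::with_seed(5, rnorm(1e5, 3, 1))
  expect_lt(abs(mode_estimate(z) - mean(z)), 0.05)
})

test_that("temporal-expectation correction operates on paired draws", {
  w_s <- rep(0.658, 1000)
  w_n <- rep(0.518, 1000)
  wc <- weight_correction(w_s, w_n, seed = 1)
  expect_equal(unique(wc$draws), 0.640)
  # a neutral condition exactly at 0.5 leaves the salience draws untouched
  wc0 <- weight_correction(w_s, rep(0.5, 1000), seed = 1)
  expect_equal(wc0$draws, w_s)
  # commutes with affine shifts of the neutral draws: +delta shifts -delta
  w_s2 <- withr::with_seed(6, rnorm(1000, 0.66, 0.02))
  w_n2 <- withr::with_seed(7, rnorm(1000, 0.52, 0.02))
  base <- weight_correction(w_s2, w_n2, seed = 9)
  shifted <- weight_correction(w_s2, w_n2 + 0.03, seed = 9)
  expect_equal(shifted$draws, base$draws - 0.03)
  expect_error(weight_correction(w_s, w_n[1:500], seed = 1),
               "draw counts differ")
})

test_that("posterior differences flag whether zero is credible", {
  x <- withr::with_seed(8, rnorm(2000, 10, 0.1))
  y <- withr::with_seed(9, rnorm(2000, 20, 0.1))
  apart <- posterior_difference(x, y, seed = 1)
  expect_false(apart$contains_zero)
  expect_lt(apart$summary$mode, 0)
  same <- posterior_difference(x, x, seed = 2)
  expect_true(same$contains_zero)
  expect_lt(abs(same$summary$mode), 0.05)
  # symmetric under argument exchange
  expect_identical(posterior_difference(x, y, seed = 3)$contains_zero,
                   posterior_difference(y, x, seed = 3)$contains_zero)
  # point masses subtract exactly
  d <- posterior_difference(rep(49.4, 500), rep(48.1, 500), seed = 1)
  expect_equal(unique(d$draws), 1.3)
  expect_s3_class(tidy(d), "tbl_df")
})

test_that("posterior predictive bands cover the data that produced the fit", {
  fit <- shared_fit()
  ppc <- posterior_predictive(fit, seed = 14)
  expect_named(ppc, c("condition", "soa_ms", "q025", "q50", "q975",
                      "observed"))
  expect_true(all(ppc$q025 <= ppc$q50 & ppc$q50 <= ppc$q975))
  expect_true(all(ppc$q025 >= 0 & ppc$q975 <= 1))
  # medians inherit the monotone decrease of the race model
  expect_true(all(diff(ppc$q50) < 0))
  # self-consistency: the observed pooled proportions sit in the band
  expect_gte(ppc_coverage(ppc), 0.9)
})

test_that("a balanced observer predicts chance performance at SOA zero", {
  dat <- simulate_toj(small_design(4), toj_truth(0.5, 0.01, 40, 3),
                      seed = 15)
  fit <- quick_fit(dat, warmup = 400, draws = 400)
  ppc <- posterior_predictive(fit, seed = 16)
  expect_lt(abs(ppc$q50[ppc$soa_ms == 0] - 0.5), 0.06)
})

test_that("logistic psychometric fit recovers PSS and its sign", {
  # symmetric observer: PSS at zero
  design <- small_design(4)
  sym <- simulate_toj(design, toj_truth(0.5, 0, 45, 0), seed = 18)
  res <- fit_logistic(sym)
  pooled <- res[res$participant == "pooled", ]
  expect_lt(abs(pooled$pss_ms), 10)
  expect_lt(pooled$slope_per_ms, 0)
  # attended probe (w > 0.5): probe still wins at reference-lead SOAs
  adv <- simulate_toj(design, toj_truth(0.7, 0, 45, 0), seed = 19)
  res_adv <- fit_logistic(adv)
  expect_gt(res_adv$pss_ms[res_adv$participant == "pooled"], 0)
  # and the hierarchical weight agrees in direction
  fit <- shared_fit()  # generated at w_m = 0.6
  expect_gt(mode_estimate(param_draws(fit, "w_m")), 0.5)
  expect_gt(fit_logistic(shared_data())$pss_ms[7], 0)
})

test_that("logistic fit is invariant to trial-count scaling and flags separation", {
  d <- tibble::tibble(condition = "c", participant = 1L,
                      soa_ms = c(-60, -20, 0, 20, 60),
                      n_trials = 40L,
                      n_probe_first = c(38L, 30L, 20L, 10L, 2L))
  doubled <- dplyr::mutate(d, n_trials = n_trials * 2L,
                           n_probe_first = n_probe_first * 2L)
  f1 <- fit_logistic(d)
  f2 <- fit_logistic(doubled)
  expect_equal(f1$pss_ms, f2$pss_ms, tolerance = 1e-8)
  expect_equal(f1$slope_per_ms, f2$slope_per_ms, tolerance = 1e-8)
  # complete separation is flagged, not dropped
  sep <- dplyr::mutate(d, n_probe_first = ifelse(soa_ms < 0, n_trials, 0L))
  expect_true(all(fit_logistic(sep)$flagged))
  expect_error(fit_logistic(d[1:2, ]), "3 distinct SOAs")
})
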