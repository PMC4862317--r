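test_that("model preconditions are enforced", {
  dat <- simulate_toj(small_design(2), toj_truth(), seed = 1)
  expect_error(fit_toj(dat, chains = 1), ">= 2")
  zero <- dat
  zero$n_trials[1] <- 0L
  expect_error(fit_toj(zero), "n_trials < 1")
  two_cond <- rbind(dat, dplyr::mutate(dat, condition = "other"))
  expect_error(fit_toj(two_cond), "multiple conditions")
  expect_error(fit_toj(dat[0, ]), "empty")
  expect_error(fit_toj(dat, priors = list()), "toj_priors")
})

test_that("a minimal one-participant one-SOA model builds and samples", {
  dat <- tibble::tibble(condition = "min", participant = 1L, soa_ms = 0,
                        n_trials = 48L, n_probe_first = 30L)
  fit <- quick_fit(dat, warmup = 200, draws = 200)
  params <- unique(fit$draws$parameter)
  expect_setequal(params, c("w_m", "w_tau", "C_m", "C_tau", "nu_p", "nu_r",
                            "w[1]", "C[1]"))
  # single participant: group rates equal the participant rates draw by draw
  gr <- group_rate_draws(fit)
  expect_equal(gr$nu_p, param_draws(fit, "C[1]") * param_draws(fit, "w[1]"))
})

test_that("identical seed and configuration reproduce the draws exactly", {
  dat <- simulate_toj(toj_design_custom(c(-60, 0, 60), c(20, 20, 20), 3),
                      toj_truth(0.55, 0.05, 35, 4), seed = 13)
  f1 <- quick_fit(dat, warmup = 200, draws = 200, seed = 77)
  f2 <- quick_fit(dat, warmup = 200, draws = 200, seed = 77)
  expect_identical(f1$draws, f2$draws)
  f3 <- quick_fit(dat, warmup = 200, draws = 200, seed = 78)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("weights, capacities and rates factorise exactly in every draw", {
  fit <- shared_fit()
  J <- nrow(fit$participants)
  wide <- tidyr::pivot_wider(fit$draws, names_from = "parameter",
                             values_from = "value")
  v_p <- as.matrix(wide[paste0("C[", 1:J, "]")]) *
    as.matrix(wide[paste0("w[", 1:J, "]")])
  v_r <- as.matrix(wide[paste0("C[", 1:J, "]")]) *
    (1 - as.matrix(wide[paste0("w[", 1:J, "]")]))
  # group rates are per-draw means of participant rates
  expect_equal(rowMeans(v_p), wide$nu_p, tolerance = 1e-10)
  expect_equal(rowMeans(v_r), wide$nu_r, tolerance = 1e-10)
  # rates sum back to capacity
  expect_equal(wide$nu_p + wide$nu_r,
               rowMeans(as.matrix(wide[paste0("C[", 1:J, "]")])),
               tolerance = 1e-10)
  # domain constraints hold for every draw
  expect_true(all(wide$w_m > 0 & wide$w_m < 1))
  expect_true(all(as.matrix(wide[paste0("w[", 1:J, "]")]) > 0 &
                    as.matrix(wide[paste0("w[", 1:J, "]")]) < 1))
  expect_true(all(as.matrix(wide[paste0("C[", 1:J, "]")]) > 0))
})

test_that("the posterior tracks the generating parameters", {
  fit <- shared_fit()
  s <- tidy(fit)
  w_row <- s[s$parameter == "w_m", ]
  C_row <- s[s$parameter == "C_m", ]
  expect_lt(abs(w_row$mode - 0.6), 0.05)
  expect_lt(abs(C_row$mode - 40) / 40, 0.15)
  expect_true(w_row$hdi_low < 0.6 & 0.6 < w_row$hdi_high)
})

test_that("steeper observers yield clearly larger capacity posteriors", {
  design <- small_design(5)
  steep <- simulate_toj(design, toj_truth(0.5, 0.02, 40, 3), seed = 31)
  shallow <- simulate_toj(design, toj_truth(0.5, 0.02, 15, 3), seed = 32)
  f_steep <- quick_fit(steep)
  f_shallow <- quick_fit(shallow)
  expect_gt(mode_estimate(param_draws(f_steep, "C_m")),
            mode_estimate(param_draws(f_shallow, "C_m")))
  # posterior mass well separated
  expect_gt(hdi(param_draws(f_steep, "C_m"))[["lower"]],
            hdi(param_draws(f_shallow, "C_m"))[["upper"]])
})

test_that("prior draws generate valid psychometric curves", {
  priors <- toj_priors()
  withr::with_seed(17, {
    for (i in 1:50) {
      w <- runif(1)
      C <- abs(rnorm(1, priors$C_m_mean, priors$C_m_sd)) + 1e-6
      theta <- p_curve(max(C * w, 1e-9) + 1e-9,
                       max(C * (1 - w), 1e-9) + 1e-9,
                       seq(-100, 100, 20))$p_probe_first
      expect_true(all(theta >= 0 & theta <= 1))
    }
  })
})

test_that("fit accessors and broom methods expose the posterior", {
  fit <- shared_fit()
  expect_error(param_draws(fit, "nope"), "no draws")
  g <- glance(fit)
  expect_equal(g$n_participants, 6L)
  expect_equal(g$n_cells, 66L)
  expect_equal(g$chains, 2L)
  expect_true(is.finite(g$max_rhat))
  gr <- group_rate_draws(fit)
  expect_named(gr, c("chain", "iteration", "nu_p", "nu_r"))
  expect_equal(nrow(gr), 2 * 800)
})
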