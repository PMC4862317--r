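# Hierarchical Bayesian estimation of TVA parameters from one TOJ condition.
#
# Participant weights and capacities are draws from group-level truncated
# normal hierarchies; each (participant, SOA) cell contributes a binomial
# likelihood whose success probability is the closed-form race solution.
# Sampling is delegated to JAGS (rjags); the psychometric likelihood itself
# is written out in the model string below.

#' Prior specification for the hierarchical TOJ model
#'
#' Weakly informative defaults: a flat prior on the group mean weight, a
#' half-normal on its between-participant SD, a wide truncated normal on the
#' group mean capacity centred on the magnitude typical of TVA studies
#' (tens of Hz), and a half-normal on the capacity SD.
#'
#' @param w_tau_scale Half-normal scale of the weight SD.
#' @param C_m_mean,C_m_sd Location and scale of the truncated-normal prior on
#'   the group mean capacity (Hz), truncated to `(0, Inf)`.
#' @param C_tau_scale Half-normal scale of the capacity SD (Hz).
#' @return A `toj_priors` object.
#' @export
toj_priors <- function(w_tau_scale = 0.2, C_m_mean = 40, C_m_sd = 30,
                       C_tau_scale = 15) {
  vals <- c(w_tau_scale, C_m_mean, C_m_sd, C_tau_scale)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all prior scales/locations must be finite and > 0", call. = FALSE)
  }
  structure(list(w_tau_scale = w_tau_scale, C_m_mean = C_m_mean,
                 C_m_sd = C_m_sd, C_tau_scale = C_tau_scale),
            class = "toj_priors")
}

# JAGS expresses normals by precision; truncation bounds keep every draw in
# the domain the race model requires (weights in (0,1), capacities > 0).
toj_jags_model <- function(priors) {
  sprintf("
model {
  w_m ~ dunif(0, 1)
  w_tau ~ dnorm(0, %.10g) T(0.0001, )
  C_m ~ dnorm(%.10g, %.10g) T(0, )
  C_tau ~ dnorm(0, %.10g) T(0.0001, )
  for (j in 1:J) {
    w[j] ~ dnorm(w_m, 1 / (w_tau * w_tau)) T(0.000001, 0.999999)
    C[j] ~ dnorm(C_m, 1 / (C_tau * C_tau)) T(0.000001, )
    v_p[j] <- C[j] * w[j]
    v_r[j] <- C[j] * (1 - w[j])
  }
  for (k in 1:N) {
    theta_raw[k] <- ifelse(dt[k] < 0,
      1 - exp(v_p[pid[k]] * dt[k]) + exp(v_p[pid[k]] * dt[k]) * w[pid[k]],
      exp(-v_r[pid[k]] * dt[k]) * w[pid[k]])
    theta[k] <- min(max(theta_raw[k], 1.0E-9), 1 - 1.0E-9)
    y[k] ~ dbin(theta[k], n[k])
  }
  nu_p <- mean(v_p)
  nu_r <- mean(v_r)
}",
          1 / priors$w_tau_scale^2,
          priors$C_m_mean, 1 / priors$C_m_sd^2,
          1 / priors$C_tau_scale^2)
}

group_params <- c("w_m", "w_tau", "C_m", "C_tau", "nu_p", "nu_r")

#' Fit the hierarchical TVA model to one TOJ condition
#'
#' Builds the generative model — `w_j ~ Normal(w_m, w_tau)` truncated to
#' (0, 1), `C_j ~ Normal(C_m, C_tau)` truncated to (0, Inf), rates
#' `v_pj = C_j w_j`, `v_rj = C_j (1 - w_j)`, and binomial counts with the
#' closed-form race probability at each SOA — and samples it with JAGS.
#' Sessions pooled into one (participant, SOA) cell are handled naturally by
#' the binomial likelihood. Group-level processing rates `nu_p`, `nu_r` are
#' tracked per draw as the mean of the participant rates.
#'
#' Convergence is assessed with split-R-hat and effective sample size on the
#' group-level parameters; the fit is flagged non-converged if any
#' split-R-hat exceeds 1.01 or any ESS falls below 400.
#'
#' @param data A validated single-condition dataset (see [simulate_toj()],
#'   [read_toj()]). Multiple conditions must be fit separately.
#' @param priors A [toj_priors()] specification.
#' @param chains Number of MCMC chains (`>= 2`).
#' @param warmup Burn-in iterations discarded per chain.
#' @param draws Retained iterations per chain.
#' @param adapt JAGS adaptation iterations.
#' @param seed Integer seed; chain RNGs are derived from it, so an identical
#'   seed and configuration reproduces the draws exactly.
#' @param quiet Suppress JAGS progress output.
#' @return A `toj_fit` object with elements `draws` (long tibble: `chain`,
#'   `iteration`, `parameter`, `value`), `diagnostics` (split-R-hat and ESS
#'   per group parameter), `converged`, `participants` (id lookup), `data`,
#'   `priors`, `sampler` and `seed`.
#' @examples
#' \donttest{
#' dat <- simulate_toj(toj_design("exp1", n_participants = 4),
#'                     toj_truth(0.6, 0.05, 40, 5), seed = 2)
#' fit <- fit_toj(dat, chains = 2, warmup = 300, draws = 300, seed = 2)
#' tidy(fit)
#' }
#' @export
fit_toj <- function(data, priors = toj_priors(), chains = 4, warmup = 1000,
                    draws = 1000, adapt = 500, seed = 1, quiet = TRUE) {
  data <- validate_toj_data(data)
  if (!inherits(priors, "toj_priors")) {
    stop("`priors` must be a toj_priors object", call. = FALSE)
  }
  if (chains < 2) stop("`chains` must be >= 2", call. = FALSE)
  if (dplyr::n_distinct(data$condition) > 1) {
    stop("`data` contains multiple conditions; fit each separately",
         call. = FALSE)
  }
  ids <- sort(unique(data$participant))
  pid <- match(data$participant, ids)
  jdata <- list(J = length(ids), N = nrow(data), pid = pid,
                dt = data$soa_ms / 1000, n = data$n_trials,
                y = data$n_probe_first)
  inits <- lapply(seq_len(chains), function(ch) {
    list(w_m = 0.5, w_tau = 0.1, C_m = priors$C_m_mean, C_tau = 5,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) %% 1000003L) * 1000L + ch)
  })
  model <- rjags::jags.model(textConnection(toj_jags_model(priors)),
                             data = jdata, inits = inits,
                             n.chains = chains, n.adapt = adapt,
                             quiet = quiet)
  pb <- if (quiet) "none" else "text"
  stats::update(model, n.iter = warmup, progress.bar = pb)
  samples <- rjags::coda.samples(model,
                                 variable.names = c(group_params, "w", "C"),
                                 n.iter = draws, progress.bar = pb)

  long <- purrr::imap_dfr(samples, function(chain_mat, ch) {
    m <- as.matrix(chain_mat)
    # JAGS drops the bracket index for length-one vectors
    cn <- colnames(m)
    cn[cn == "w"] <- "w[1]"
    cn[cn == "C"] <- "C[1]"
    tibble::tibble(chain = as.integer(ch),
                   iteration = rep(seq_len(nrow(m)), times = ncol(m)),
                   parameter = rep(cn, each = nrow(m)),
                   value = as.vector(m))
  })

  diag <- purrr::map_dfr(group_params, function(p) {
    mat <- sapply(samples, function(s) as.matrix(s)[, p])
    tibble::tibble(parameter = p,
                   rhat = split_rhat(mat),
                   ess = sum(coda::effectiveSize(
                     coda::as.mcmc.list(lapply(samples, function(s)
                       coda::as.mcmc(as.matrix(s)[, p, drop = FALSE]))))))
  })
  converged <- all(diag$rhat <= 1.01) && all(diag$ess >= 400)
  if (!converged) {
    warning("fit flagged non-converged: max split-R-hat = ",
            signif(max(diag$rhat), 4), ", min ESS = ",
            signif(min(diag$ess), 4), call. = FALSE)
  }
  structure(list(draws = long,
                 diagnostics = diag,
                 converged = converged,
                 participants = tibble::tibble(index = seq_along(ids),
                                               participant = ids),
                 data = data,
                 priors = priors,
                 sampler = list(chains = chains, warmup = warmup,
                                draws = draws, adapt = adapt),
                 seed = seed),
            class = "toj_fit")
}

# Split-R-hat of Gelman et al.: each chain is halved, then the classic
# potential scale reduction factor is computed over the 2m half-chains.
split_rhat <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  half <- floor(n / 2)
  splits <- cbind(mat[seq_len(half), , drop = FALSE],
                  mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Extract posterior draws of one parameter
#'
#' @param fit A `toj_fit`.
#' @param parameter Parameter name as it appears in `fit$draws` (e.g.
#'   `"w_m"`, `"C_m"`, `"nu_p"`, `"w[3]"`).
#' @return Numeric vector of draws, ordered by chain then iteration.
#' @export
param_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "toj_fit"))
  d <- fit$draws[fit$draws$parameter == parameter, ]
  if (nrow(d) == 0) {
    stop("no draws for parameter ", parameter, call. = FALSE)
  }
  d$value[order(d$chain, d$iteration)]
}

#' Group-level processing-rate draws
#'
#' Per posterior draw, the group rates are the mean over participants of the
#' participant-level rates `v_pj = C_j w_j` and `v_rj = C_j (1 - w_j)`; they
#' carry no information beyond the weights and capacities but are the scale
#' on which processing speed is reported.
#'
#' @param fit A `toj_fit`.
#' @return A tibble with columns `chain`, `iteration`, `nu_p`, `nu_r`.
#' @export
group_rate_draws <- function(fit) {
  stopifnot(inherits(fit, "toj_fit"))
  fit$draws |>
    dplyr::filter(.data$parameter %in% c("nu_p", "nu_r")) |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "value") |>
    dplyr::arrange(.data$chain, .data$iteration)
}

#' @export
print.toj_fit <- function(x, ...) {
  cat("<toj_fit> condition:", unique(x$data$condition), "\n")
  cat("  participants:", nrow(x$participants),
      " cells:", nrow(x$data), "\n")
  cat("  chains:", x$sampler$chains, " retained draws/chain:",
      x$sampler$draws, " seed:", x$seed, "\n")
  cat("  converged:", x$converged,
      " (max split-R-hat", signif(max(x$diagnostics$rhat), 4), ")\n")
  print(tidy(x))
  invisible(x)
}
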