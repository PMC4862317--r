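# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the group-level posterior of a TOJ fit
#'
#' @param x A `toj_fit`.
#' @param parameters Which parameters to summarise; defaults to the six
#'   group-level ones. Participant-level names like `"w[3]"` also work.
#' @param mass HDI mass.
#' @param ... Unused.
#' @return A tibble: `parameter`, `mode`, `hdi_low`, `hdi_high`, `rhat`,
#'   `ess` (diagnostics `NA` for non-group parameters).
#' @method tidy toj_fit
#' @export
tidy.toj_fit <- function(x, parameters = group_params, mass = 0.95, ...) {
  purrr::map_dfr(parameters, function(p) {
    s <- posterior_summary(param_draws(x, p), mass)
    d <- x$diagnostics[x$diagnostics$parameter == p, ]
    tibble::tibble(parameter = p, mode = s$mode,
                   hdi_low = s$hdi_low, hdi_high = s$hdi_high,
                   rhat = if (nrow(d)) d$rhat else NA_real_,
                   ess = if (nrow(d)) d$ess else NA_real_)
  })
}

#' One-row fit overview
#'
#' @param x A `toj_fit`.
#' @param ... Unused.
#' @return A tibble with the condition, data and sampler dimensions,
#'   worst-case diagnostics and the convergence flag.
#' @method glance toj_fit
#' @export
glance.toj_fit <- function(x, ...) {
  tibble::tibble(condition = unique(x$data$condition),
                 n_participants = nrow(x$participants),
                 n_cells = nrow(x$data),
                 n_trials = sum(x$data$n_trials),
                 chains = x$sampler$chains,
                 draws_per_chain = x$sampler$draws,
                 max_rhat = max(x$diagnostics$rhat),
                 min_ess = min(x$diagnostics$ess),
                 converged = x$converged)
}

#' @method tidy toj_contrast
#' @export
tidy.toj_contrast <- function(x, ...) {
  dplyr::mutate(x$summary, type = x$type, contains_zero = x$contains_zero,
                .before = 1)
}
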