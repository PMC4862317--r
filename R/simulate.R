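# Synthetic-experiment generator: draws participant-level TVA parameters from
# the same truncated-normal hierarchies the inference model assumes, then
# generates per-cell judgment counts either binomially from the closed-form
# psychometric function or by trial-level races.

#' Group-level generating truth for synthetic experiments
#'
#' @param w_m Group mean attentional weight of the probe, in (0, 1).
#' @param w_sd Between-participant SD of the weight (`>= 0`).
#' @param C_m Group mean processing capacity in Hz (`> 0`).
#' @param C_sd Between-participant SD of the capacity in Hz (`>= 0`).
#' @return A `toj_truth` object.
#' @examples
#' toj_truth(w_m = 0.658, w_sd = 0.05, C_m = 40.7, C_sd = 5)
#' @export
toj_truth <- function(w_m = 0.5, w_sd = 0.05, C_m = 40, C_sd = 5) {
  if (!is.finite(w_m) || w_m <= 0 || w_m >= 1) {
    stop("`w_m` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.finite(C_m) || C_m <= 0) stop("`C_m` must be > 0", call. = FALSE)
  if (w_sd < 0 || C_sd < 0) stop("spreads must be >= 0", call. = FALSE)
  structure(list(w_m = w_m, w_sd = w_sd, C_m = C_m, C_sd = C_sd),
            class = "toj_truth")
}

# Inverse-CDF draws from a Normal(mean, sd) truncated to (lower, upper).
# sd = 0 degenerates to the mean (clamped into the interval).
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, p_lo, p_hi)
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic TOJ condition
#'
#' Per participant, draws an attentional weight from Normal(`w_m`, `w_sd`)
#' truncated to (0, 1) and a capacity from Normal(`C_m`, `C_sd`) truncated to
#' (0, Inf); rates follow as `v_p = C w`, `v_r = C (1 - w)`. Per SOA cell the
#' "probe first" count is drawn either binomially with the closed-form
#' success probability (`mode = "binomial"`) or by counting wins in
#' trial-level exponential races (`mode = "race"`); the two modes are
#' statistically indistinguishable.
#'
#' @param design A [toj_design()].
#' @param truth A [toj_truth()].
#' @param mode `"binomial"` (closed-form theta) or `"race"` (trial-level
#'   simulation).
#' @param seed Integer seed; a seed plus design, truth and mode fully
#'   determines the dataset.
#' @param condition Condition label stored in the data; defaults to the
#'   design label.
#' @return A tibble with columns `condition`, `participant`, `soa_ms`,
#'   `n_trials`, `n_probe_first`, one row per (participant, SOA) cell.
#'   Attributes `truth`, `participants` (tibble of per-participant generating
#'   parameters), `design`, `mode` and `seed` record the provenance.
#' @examples
#' simulate_toj(toj_design("exp1", n_participants = 3),
#'              toj_truth(0.6, 0.05, 40, 5), seed = 7)
#' @export
simulate_toj <- function(design, truth, mode = c("binomial", "race"),
                         seed = 1, condition = design$label) {
  stopifnot(inherits(design, "toj_design"), inherits(truth, "toj_truth"))
  mode <- match.arg(mode)
  J <- design$n_participants
  withr::with_seed(seed, {
    w_j <- clamp_prob(rtrunc_norm(J, truth$w_m, truth$w_sd, 0, 1),
                      eps = 1e-6)
    C_j <- pmax(rtrunc_norm(J, truth$C_m, truth$C_sd, 0, Inf), 1e-6)
    cells <- tidyr::expand_grid(participant = seq_len(J),
                                idx = seq_along(design$soa_ms))
    cells$soa_ms <- design$soa_ms[cells$idx]
    cells$n_trials <- design$trials_per_soa[cells$idx]
    theta <- p_probe_first(C_j[cells$participant] * w_j[cells$participant],
                           C_j[cells$participant] * (1 - w_j[cells$participant]),
                           cells$soa_ms / 1000)
    if (mode == "binomial") {
      y <- stats::rbinom(nrow(cells), cells$n_trials, theta)
    } else {
      start_r <- -cells$soa_ms / 1000
      y <- vapply(seq_len(nrow(cells)), function(k) {
        v_p <- C_j[cells$participant[k]] * w_j[cells$participant[k]]
        v_r <- C_j[cells$participant[k]] - v_p
        n <- cells$n_trials[k]
        finish_p <- stats::rexp(n, v_p)
        finish_r <- start_r[k] + stats::rexp(n, v_r)
        sum(finish_p < finish_r)
      }, integer(1))
    }
  })
  out <- tibble::tibble(condition = condition,
                        participant = cells$participant,
                        soa_ms = cells$soa_ms,
                        n_trials = cells$n_trials,
                        n_probe_first = as.integer(y))
  attr(out, "truth") <- truth
  attr(out, "participants") <- tibble::tibble(
    participant = seq_len(J), w = w_j, C = C_j,
    v_p = C_j * w_j, v_r = C_j * (1 - w_j))
  attr(out, "design") <- design
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  out
}

toj_data_cols <- c("condition", "participant", "soa_ms", "n_trials",
                   "n_probe_first")

#' Validate a trial-aggregated TOJ dataset
#'
#' Checks the tabular schema used throughout the package: columns
#' `condition`, `participant`, `soa_ms`, `n_trials`, `n_probe_first`; one row
#' per (condition, participant, SOA); `0 <= n_probe_first <= n_trials`,
#' `n_trials >= 1`; and an identical SOA grid for every participant within a
#' condition. Violations are reported with the offending row index.
#'
#' @param data A data frame in the dataset schema.
#' @return The validated data, invisibly, as a tibble.
#' @export
validate_toj_data <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    stop("dataset is empty or not a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(toj_data_cols, names(data))
  if (length(missing_cols) > 0) {
    stop("dataset lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  bad <- which(!is.finite(data$soa_ms) | !is.finite(data$n_trials) |
                 !is.finite(data$n_probe_first))
  if (length(bad) > 0) {
    stop("non-finite values in row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(data$n_trials < 1)
  if (length(bad) > 0) {
    stop("n_trials < 1 in row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(data$n_probe_first < 0 | data$n_probe_first > data$n_trials)
  if (length(bad) > 0) {
    stop("n_probe_first outside [0, n_trials] in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(data$condition, data$participant, data$soa_ms)
  bad <- which(duplicated(key))
  if (length(bad) > 0) {
    stop("duplicate (condition, participant, SOA) cell in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  grids <- data |>
    dplyr::group_by(.data$condition, .data$participant) |>
    dplyr::summarise(grid = paste(sort(.data$soa_ms), collapse = ","),
                     .groups = "drop_last") |>
    dplyr::summarise(n_grids = dplyr::n_distinct(.data$grid),
                     .groups = "drop")
  if (any(grids$n_grids > 1)) {
    stop("participants within condition(s) ",
         paste(grids$condition[grids$n_grids > 1], collapse = ", "),
         " have differing SOA grids", call. = FALSE)
  }
  invisible(data)
}

#' Read / write TOJ datasets as CSV
#'
#' The on-disk schema is a UTF-8, comma-separated file with header
#' `condition,participant,soa_ms,n_trials,n_probe_first`, one row per
#' (participant, SOA) cell. Reading validates the schema and reports
#' offending rows; `read_toj(write_toj(x, path))` is the identity on valid
#' data.
#'
#' @param data A dataset in the schema of [simulate_toj()].
#' @param path File path.
#' @return `write_toj()` returns `path` invisibly; `read_toj()` returns a
#'   validated tibble.
#' @export
write_toj <- function(data, path) {
  validate_toj_data(data)
  readr::write_csv(data[toj_data_cols], path)
  invisible(path)
}

#' @rdname write_toj
#' @export
read_toj <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            condition = readr::col_character(),
                            participant = readr::col_integer(),
                            soa_ms = readr::col_double(),
                            n_trials = readr::col_integer(),
                            n_probe_first = readr::col_integer()))
  validate_toj_data(data)
  data
}
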