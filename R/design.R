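# Experimental designs: SOA grids, per-SOA trial counts, participant counts.

exp_grid_soa <- seq(-100, 100, by = 20)
exp_grid_trials <- function() {
  soa <- exp_grid_soa
  dplyr::case_when(abs(soa) >= 80 ~ 24L,
                   abs(soa) >= 40 ~ 32L,
                   TRUE ~ 48L)
}

builtin_designs <- function() {
  list(exp1 = 20L, exp2 = 20L, exp3 = 19L, exp4 = 30L)
}

#' Built-in and custom TOJ designs
#'
#' The four built-in designs (`"exp1"`..`"exp4"`) share one SOA grid: -100 to
#' +100 ms in 20 ms steps, with 24 trials at |SOA| of 80 and 100 ms, 32 at 40
#' and 60 ms, and 48 at 0 and 20 ms — 368 trials per participant, sampled
#' more densely where the psychometric function is steepest. They differ only
#' in participant count: 20, 20, 19 and 30.
#'
#' @param name One of `"exp1"`, `"exp2"`, `"exp3"`, `"exp4"`.
#' @param n_participants Optional override of the participant count.
#' @return A `toj_design` object: list with `label`, `soa_ms`,
#'   `trials_per_soa`, `n_participants`.
#' @examples
#' toj_design("exp1")
#' @seealso [toj_design_custom()]
#' @export
toj_design <- function(name, n_participants = NULL) {
  known <- builtin_designs()
  if (!is.character(name) || length(name) != 1 || !name %in% names(known)) {
    stop("unknown design name; use one of ",
         paste(names(known), collapse = ", "),
         " or toj_design_custom()", call. = FALSE)
  }
  toj_design_custom(soa_ms = exp_grid_soa,
                    trials_per_soa = exp_grid_trials(),
                    n_participants = n_participants %||% known[[name]],
                    label = name)
}

#' Custom TOJ design
#'
#' @param soa_ms Vector of signed SOAs in ms (negative: probe leads).
#' @param trials_per_soa Trial counts aligned with `soa_ms`, all `>= 1`.
#' @param n_participants Number of participants (`>= 1`).
#' @param label Condition/design label.
#' @return A `toj_design` object.
#' @export
toj_design_custom <- function(soa_ms, trials_per_soa, n_participants,
                              label = "custom") {
  if (length(soa_ms) == 0 || length(soa_ms) != length(trials_per_soa)) {
    stop("`soa_ms` and `trials_per_soa` must be nonempty and of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(soa_ms)) || anyDuplicated(soa_ms)) {
    stop("`soa_ms` must be finite and without duplicates", call. = FALSE)
  }
  if (any(trials_per_soa < 1)) {
    stop("all `trials_per_soa` must be >= 1", call. = FALSE)
  }
  if (length(n_participants) != 1 || n_participants < 1) {
    stop("`n_participants` must be a single count >= 1", call. = FALSE)
  }
  ord <- order(soa_ms)
  structure(list(label = label,
                 soa_ms = as.numeric(soa_ms[ord]),
                 trials_per_soa = as.integer(trials_per_soa[ord]),
                 n_participants = as.integer(n_participants)),
            class = "toj_design")
}

#' @export
print.toj_design <- function(x, ...) {
  cat("<toj_design> ", x$label, "\n", sep = "")
  cat("  participants: ", x$n_participants, "\n", sep = "")
  cat("  SOAs (ms): ", paste(x$soa_ms, collapse = ", "), "\n", sep = "")
  cat("  trials/SOA: ", paste(x$trials_per_soa, collapse = ", "),
      "  (", sum(x$trials_per_soa), " per participant)\n", sep = "")
  invisible(x)
}

#' @method as_tibble toj_design
#' @export
as_tibble.toj_design <- function(x, ...) {
  tibble::tibble(soa_ms = x$soa_ms, n_trials = x$trials_per_soa)
}
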