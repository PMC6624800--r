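#' Operational plateau detection on a survival curve tail
#'
#' The ESMO-MCBS long-term-plateau criterion is qualitative ("long-term
#' plateau of the OS/PFS curve"); this detector operationalises it as a flat
#' trailing window with enough patients still at risk. The window is the
#' trailing `window_frac` fraction of follow-up; the curve is called a plateau
#' when the total Kaplan-Meier drop inside that window is below `drop_tol`
#' and the at-risk count at the window start is at least `min_at_risk`. The
#' at-risk guard mirrors the milestone-imprecision concern that motivates the
#' ASCO 20% floor: a flat tail supported by a handful of patients is noise,
#' not a plateau.
#'
#' @param curve A [step_curve()].
#' @param window_frac Trailing fraction of follow-up inspected, in (0, 1).
#'   Default 0.2.
#' @param drop_tol Maximum absolute survival drop tolerated inside the
#'   window. Default 0.05.
#' @param min_at_risk Minimum at-risk count at the window start. Default 10.
#' @return A one-row tibble (class `plateau_verdict`) with columns
#'   `is_plateau`, `window_start`, `drop_in_window`, `at_risk_at_window`,
#'   `source` (`"detector"`).
#' @seealso [manual_plateau()] to inject a reviewer-based call.
#' @export
detect_plateau <- function(curve, window_frac = 0.2, drop_tol = 0.05,
                           min_at_risk = 10) {
  assert_step_curve(curve)
  if (window_frac <= 0 || window_frac >= 1) {
    abort("`window_frac` must lie strictly between 0 and 1")
  }
  if (drop_tol < 0) abort("`drop_tol` must be non-negative")
  if (min_at_risk < 1) abort("`min_at_risk` must be at least 1")
  if (curve$max_followup <= 0) {
    abort("degenerate curve: follow-up must be positive to assess a plateau")
  }
  window_start <- (1 - window_frac) * curve$max_followup
  drop <- survival_at(curve, window_start) - survival_at(curve, curve$max_followup)
  # at-risk just before the first grid time at/after the window start; when the
  # grid has no row that late (digitised tail), fall back on the last count
  later <- which(curve$times >= window_start)
  at_risk_win <- if (length(later) > 0L) {
    curve$at_risk[later[1]]
  } else {
    curve$at_risk[length(curve$at_risk)]
  }
  new_plateau_verdict(
    is_plateau = drop < drop_tol && at_risk_win >= min_at_risk,
    window_start = window_start,
    drop_in_window = drop,
    at_risk_at_window = at_risk_win,
    source = "detector"
  )
}

#' Record a reviewer-based plateau call
#'
#' Published long-term-plateau assessments (e.g. framework field-testing or
#' two-reviewer qualitative calls) can be injected in place of the detector.
#'
#' @param is_plateau Logical verdict.
#' @return A `plateau_verdict` tibble with `source = "manual_override"`.
#' @export
manual_plateau <- function(is_plateau) {
  stopifnot(is.logical(is_plateau), length(is_plateau) == 1L, !is.na(is_plateau))
  new_plateau_verdict(
    is_plateau = is_plateau,
    window_start = NA_real_,
    drop_in_window = NA_real_,
    at_risk_at_window = NA_real_,
    source = "manual_override"
  )
}

new_plateau_verdict <- function(is_plateau, window_start, drop_in_window,
                                at_risk_at_window, source) {
  out <- tibble(
    is_plateau = is_plateau,
    window_start = window_start,
    drop_in_window = drop_in_window,
    at_risk_at_window = at_risk_at_window,
    source = source
  )
  class(out) <- c("plateau_verdict", class(out))
  out
}

is_plateau_verdict <- function(x) inherits(x, "plateau_verdict")
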