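#' Evaluate the four ASCO-VF v2 tail-of-the-curve criteria on one endpoint
#'
#' The tail-of-the-curve (TOC) bonus inspects the survival curves at
#' `t2 = 2 x median` of the standard (control) regimen, and is met when all
#' four criteria hold: (1) the endpoint is reported, (2) both curves extend
#' to `t2`, (3) survival on the test regimen at `t2` is at least 50% higher
#' than on control (relative: `S_test >= 1.5 * S_ctrl`), and (4) at least 20%
#' of control patients are still alive (or progression-free) at `t2`. The 20%
#' floor exists to keep the milestone readout away from the sparse end of the
#' control curve.
#'
#' When the control median is not reached, `t2` cannot be formed and the
#' criteria are recorded as unmet (`control_median = NA`) — a verdict, not an
#' error. Likewise a curve that stops short of `t2` fails
#' `data_extends_to_t2` rather than raising.
#'
#' @param test,control [step_curve()]s for the test and control arms.
#' @param ratio_threshold Relative-improvement threshold, default 1.5.
#' @param floor_threshold Control survival floor at `t2`, default 0.20.
#' @param endpoint Label carried into the result (`"OS"` or `"PFS"`).
#' @return A one-row tibble: `endpoint`, `control_median`, `t2`,
#'   `data_extends_to_t2`, `s_test_t2`, `s_ctrl_t2`, `improvement_ratio`,
#'   `ratio_ok`, `ctrl_floor_ok`, `met`.
#' @export
#' @examples
#' ctrl <- step_curve(c(10, 20), c(0.5, 0.25), c(80, 30))
#' test <- step_curve(c(14, 20), c(0.6, 0.40), c(90, 40))
#' evaluate_toc(test, ctrl)
evaluate_toc <- function(test, control, ratio_threshold = 1.5,
                         floor_threshold = 0.20, endpoint = "OS") {
  assert_step_curve(test, "test")
  assert_step_curve(control, "control")
  cm <- median_survival(control)
  if (is.na(cm)) {
    return(tibble(
      endpoint = endpoint, control_median = NA_real_, t2 = NA_real_,
      data_extends_to_t2 = FALSE, s_test_t2 = NA_real_, s_ctrl_t2 = NA_real_,
      improvement_ratio = NA_real_, ratio_ok = FALSE, ctrl_floor_ok = FALSE,
      met = FALSE
    ))
  }
  t2 <- 2 * cm
  s_test <- if (t2 <= test$max_followup) survival_at(test, t2) else NA_real_
  s_ctrl <- if (t2 <= control$max_followup) survival_at(control, t2) else NA_real_
  extends <- !is.na(s_test) && !is.na(s_ctrl)
  ratio <- if (extends && s_ctrl > 0) s_test / s_ctrl else NA_real_
  # inclusive thresholds with a float guard: 0.3/0.2 must count as >= 1.5
  ratio_ok <- isTRUE(ratio >= ratio_threshold - 1e-9)
  floor_ok <- extends && s_ctrl >= floor_threshold - 1e-9
  tibble(
    endpoint = endpoint, control_median = cm, t2 = t2,
    data_extends_to_t2 = extends, s_test_t2 = s_test, s_ctrl_t2 = s_ctrl,
    improvement_ratio = ratio, ratio_ok = ratio_ok, ctrl_floor_ok = floor_ok,
    met = extends && ratio_ok && floor_ok
  )
}

empty_toc_criteria <- function(endpoint) {
  tibble(
    endpoint = endpoint, control_median = NA_real_, t2 = NA_real_,
    data_extends_to_t2 = NA, s_test_t2 = NA_real_, s_ctrl_t2 = NA_real_,
    improvement_ratio = NA_real_, ratio_ok = NA, ctrl_floor_ok = NA,
    met = NA
  )
}

#' Award the ASCO-VF v2 tail-of-the-curve bonus for one trial
#'
#' Endpoint routing follows the framework algorithm: overall survival is
#' evaluated first whenever it is reported and not obscured by crossover in
#' the comparator arm; a trial whose OS is unreported does not qualify for an
#' OS-evaluated bonus, and a crossover-obscured trial is evaluated on PFS
#' instead. At most one bonus is awarded per trial: 20 points when the OS
#' criteria are met, else 16 points when the PFS criteria are met. By default
#' PFS is still evaluated when OS was assessable but failed its criteria;
#' `os_strict = TRUE` disables that fallback for sensitivity analysis.
#'
#' @param trial A one-row cohort tibble (see [cohort()]).
#' @param ratio_threshold,floor_threshold Passed to [evaluate_toc()].
#' @param os_strict If `TRUE`, a trial with assessable OS is never evaluated
#'   on PFS, even when the OS criteria fail.
#' @return One-row tibble: `awarded`, `points` (0/16/20), `endpoint_used`
#'   (`"OS"`, `"PFS"`, `"none"`), plus the per-endpoint criteria flattened
#'   with `os_` / `pfs_` prefixes (`NA` where an endpoint was not evaluated).
#' @seealso [score_asco()] for whole-cohort scoring.
#' @export
award_toc <- function(trial, ratio_threshold = 1.5, floor_threshold = 0.20,
                      os_strict = FALSE) {
  stopifnot(is.data.frame(trial), nrow(trial) == 1L)
  os_assessable <- trial$os_reported && !trial$os_obscured_by_crossover
  os_crit <- empty_toc_criteria("OS")
  pfs_crit <- empty_toc_criteria("PFS")
  if (os_assessable) {
    cv <- trial_curves(trial, "OS")
    os_crit <- evaluate_toc(cv$test, cv$control, ratio_threshold,
                            floor_threshold, endpoint = "OS")
  }
  pfs_allowed <- trial$pfs_reported &&
    (!os_assessable || (!isTRUE(os_crit$met) && !os_strict))
  if (pfs_allowed) {
    cv <- trial_curves(trial, "PFS")
    pfs_crit <- evaluate_toc(cv$test, cv$control, ratio_threshold,
                             floor_threshold, endpoint = "PFS")
  }
  if (isTRUE(os_crit$met)) {
    awarded <- TRUE; points <- 20; used <- "OS"
  } else if (isTRUE(pfs_crit$met)) {
    awarded <- TRUE; points <- 16; used <- "PFS"
  } else {
    awarded <- FALSE; points <- 0; used <- "none"
  }
  dplyr::bind_cols(
    tibble(trial_id = trial$trial_id, awarded = awarded, points = points,
           endpoint_used = used),
    prefix_criteria(os_crit, "os"),
    prefix_criteria(pfs_crit, "pfs")
  )
}

prefix_criteria <- function(crit, prefix) {
  crit <- dplyr::select(crit, -"endpoint")
  names(crit) <- paste(prefix, names(crit), sep = "_")
  crit
}

#' Score a whole cohort with the ASCO-VF v2 tail-of-the-curve bonus
#'
#' @param trials A cohort tibble.
#' @inheritParams award_toc
#' @return A tibble with one row per trial: trial metadata
#'   (`therapy_class`, `disease_site`), the award (`awarded`, `points`,
#'   `endpoint_used`) and the flattened per-endpoint criteria.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_recipe(n_trials = 4, seed = 1))
#' score_asco(coh)
score_asco <- function(trials, ratio_threshold = 1.5, floor_threshold = 0.20,
                       os_strict = FALSE) {
  trials <- cohort(trials)
  res <- purrr::map_dfr(
    seq_len(nrow(trials)),
    function(i) award_toc(trials[i, ], ratio_threshold, floor_threshold,
                          os_strict)
  )
  dplyr::bind_cols(
    dplyr::select(trials, "trial_id", "therapy_class", "disease_site"),
    dplyr::select(res, -"trial_id")
  )
}

#' Sweep the control-survival floor of the tail-of-the-curve bonus
#'
#' Re-runs the full ASCO award pass at each floor value in `floor_grid`,
#' leaving every other criterion untouched, and tabulates award counts by
#' therapy class. Lowering the 20% floor has been proposed as a refinement of
#' the bonus; the sweep makes the trade-off visible: award counts are
#' monotone non-increasing in the floor.
#'
#' @param trials A cohort tibble.
#' @param floor_grid Floor values in `[0, 1]`.
#' @inheritParams award_toc
#' @return A tibble with columns `floor_threshold`, `therapy_class`,
#'   `n_trials`, `n_awarded`.
#' @export
threshold_sweep <- function(trials, floor_grid = seq(0, 0.3, by = 0.05),
                            ratio_threshold = 1.5, os_strict = FALSE) {
  if (length(floor_grid) == 0L) abort("`floor_grid` must be non-empty")
  if (any(floor_grid < 0 | floor_grid > 1)) {
    abort("`floor_grid` values must lie in [0, 1]")
  }
  trials <- cohort(trials)
  purrr::map_dfr(floor_grid, function(fl) {
    score_asco(trials, ratio_threshold = ratio_threshold,
               floor_threshold = fl, os_strict = os_strict) |>
      dplyr::group_by(.data$therapy_class) |>
      dplyr::summarise(n_trials = dplyr::n(),
                       n_awarded = sum(.data$awarded), .groups = "drop") |>
      dplyr::mutate(floor_threshold = fl, .before = 1)
  })
}
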