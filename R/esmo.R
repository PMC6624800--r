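#' Select the endpoint form for the ESMO-MCBS long-term-plateau adjustment
#'
#' The two immunotherapy-triggered long-term-plateau (LTP) adjustments are
#' mutually exclusive: a trial is evaluated on exactly one of OS or PFS,
#' chosen by its primary endpoint. Coprimary "OS+PFS" trials route to the OS
#' form (OS being the stronger endpoint), unless the trial carries an
#' `ltp_form_override`.
#'
#' @param trial A one-row cohort tibble; must be ESMO-eligible
#'   (see [esmo_eligible()]).
#' @return `"OS"` or `"PFS"`.
#' @export
select_ltp_endpoint <- function(trial) {
  stopifnot(is.data.frame(trial), nrow(trial) == 1L)
  if (!esmo_eligible(trial)) {
    abort(sprintf("trial %s is not ESMO-eligible; gate on esmo_eligible() first",
                  trial$trial_id))
  }
  ov <- trial$ltp_form_override %||% NA_character_
  if (!is.na(ov)) {
    if (!ov %in% c("OS", "PFS")) abort("`ltp_form_override` must be 'OS' or 'PFS'")
    return(ov)
  }
  if (trial$primary_endpoint == "PFS") "PFS" else "OS"
}

ltp_milestone <- function(endpoint, control_median) {
  # Table-2 branch: OS milestone 5 y when control median <= 12 mo, else 7 y;
  # PFS milestone 1 y when control median <= 6 mo, else 2 y. An unreached
  # median exceeds observed follow-up and routes to the longer milestone.
  if (endpoint == "OS") {
    if (!is.na(control_median) && control_median <= 12) 60 else 84
  } else {
    if (!is.na(control_median) && control_median <= 6) 12 else 24
  }
}

evaluate_ltp <- function(test, control, plateau, endpoint, delta_threshold) {
  assert_step_curve(test, "test")
  assert_step_curve(control, "control")
  if (!is_plateau_verdict(plateau)) {
    abort("`plateau` must be a plateau_verdict (detect_plateau() or manual_plateau())")
  }
  cm <- median_survival(control)
  t_eval <- ltp_milestone(endpoint, cm)
  s_test <- if (t_eval <= test$max_followup) survival_at(test, t_eval) else NA_real_
  s_ctrl <- if (t_eval <= control$max_followup) survival_at(control, t_eval) else NA_real_
  extends <- !is.na(s_test) && !is.na(s_ctrl)
  delta <- if (extends) s_test - s_ctrl else NA_real_
  crit2 <- if (!extends) {
    FALSE
  } else if (endpoint == "OS") {
    delta > 0                             # strict advantage, no significance demand
  } else {
    delta >= delta_threshold - 1e-9       # absolute gain, inclusive at the threshold
  }
  has_plateau <- plateau$is_plateau
  plateau_source <- plateau$source
  tibble(
    endpoint = endpoint, control_median = cm, t_eval = t_eval,
    plateau = has_plateau, plateau_source = plateau_source,
    data_extends_to_t_eval = extends, s_test = s_test, s_ctrl = s_ctrl,
    delta = delta, criterion2_ok = crit2,
    met = has_plateau && extends && crit2
  )
}

#' Evaluate the ESMO-MCBS v1.1 long-term-plateau criteria on one endpoint
#'
#' Both adjustments are two-criterion rules. OS form: (1) a long-term plateau
#' of the OS curve and (2) an OS advantage of the test regimen at 5 years
#' (control median <= 12 months) or 7 years (control median > 12 months).
#' PFS form: (1) a long-term plateau of the PFS curve and (2) an absolute
#' improvement of at least 10 percentage points in PFS at 1 year (control
#' median <= 6 months) or 2 years (control median > 6 months). Curves that do
#' not extend to the milestone fail the data criterion — a recorded verdict,
#' not an error; trials with immature follow-up simply cannot earn the
#' adjustment.
#'
#' @param test,control [step_curve()]s for the two arms of the selected
#'   endpoint.
#' @param plateau A plateau verdict from [detect_plateau()] or
#'   [manual_plateau()], assessed on the test-arm curve.
#' @param delta_threshold PFS absolute improvement threshold, default 0.10.
#' @return One-row tibble: `endpoint`, `control_median`, `t_eval`, `plateau`,
#'   `plateau_source`, `data_extends_to_t_eval`, `s_test`, `s_ctrl`, `delta`,
#'   `criterion2_ok`, `met`.
#' @name evaluate_ltp
NULL

#' @rdname evaluate_ltp
#' @export
evaluate_ltp_os <- function(test, control, plateau) {
  evaluate_ltp(test, control, plateau, "OS", delta_threshold = NA_real_)
}

#' @rdname evaluate_ltp
#' @export
evaluate_ltp_pfs <- function(test, control, plateau, delta_threshold = 0.10) {
  evaluate_ltp(test, control, plateau, "PFS", delta_threshold)
}

#' Award the ESMO-MCBS v1.1 long-term-plateau adjustment for one trial
#'
#' Ineligible trials (non-significant primary endpoint, or hematological
#' agent) are returned unawarded with the reason recorded. Eligible trials
#' are evaluated on exactly the endpoint chosen by
#' [select_ltp_endpoint()]; a met PFS form upgrades the clinical benefit
#' grade by one level (`adjustment = "pfs_upgrade"`), a met OS form routes
#' the trial to curative-intent scoring (`adjustment = "os_curative_scoring"`).
#' The downstream grade itself is out of scope: the award decision is binary.
#'
#' The plateau verdict comes from the trial's `plateau_override_*` column
#' when present (reviewer/field-testing call), otherwise from
#' [detect_plateau()] on the test-arm curve with the supplied settings.
#'
#' @param trial A one-row cohort tibble.
#' @param delta_threshold PFS absolute-improvement threshold, default 0.10.
#' @param window_frac,drop_tol,min_at_risk Plateau detector settings, see
#'   [detect_plateau()].
#' @return One-row tibble: `trial_id`, `eligible`, `ineligible_reason`,
#'   `awarded`, `adjustment` (`"none"`, `"pfs_upgrade"`,
#'   `"os_curative_scoring"`), `endpoint_used`, plus the flattened
#'   criteria (`ltp_` prefix).
#' @seealso [score_esmo()] for whole-cohort scoring.
#' @export
award_ltp <- function(trial, delta_threshold = 0.10, window_frac = 0.2,
                      drop_tol = 0.05, min_at_risk = 10) {
  stopifnot(is.data.frame(trial), nrow(trial) == 1L)
  base <- tibble(trial_id = trial$trial_id, eligible = esmo_eligible(trial),
                 ineligible_reason = esmo_ineligible_reason(trial))
  empty <- tibble(
    endpoint = NA_character_, control_median = NA_real_, t_eval = NA_real_,
    plateau = NA, plateau_source = NA_character_,
    data_extends_to_t_eval = NA, s_test = NA_real_, s_ctrl = NA_real_,
    delta = NA_real_, criterion2_ok = NA, met = NA
  )
  if (!base$eligible) {
    return(dplyr::bind_cols(
      base, tibble(awarded = FALSE, adjustment = "none",
                   endpoint_used = "none"),
      prefix_criteria_ltp(empty)
    ))
  }
  ep <- select_ltp_endpoint(trial)
  cv <- trial_curves(trial, ep)
  reported <- if (ep == "OS") trial$os_reported else trial$pfs_reported
  if (!reported || is.null(cv$test) || is.null(cv$control)) {
    # framework-selected endpoint has no curves: cannot be evaluated
    empty$endpoint <- ep
    empty$met <- FALSE
    return(dplyr::bind_cols(
      base, tibble(awarded = FALSE, adjustment = "none", endpoint_used = ep),
      prefix_criteria_ltp(empty)
    ))
  }
  override <- if (ep == "OS") trial$plateau_override_os else trial$plateau_override_pfs
  plateau <- if (!is.na(override)) {
    manual_plateau(override)
  } else {
    detect_plateau(cv$test, window_frac = window_frac, drop_tol = drop_tol,
                   min_at_risk = min_at_risk)
  }
  crit <- if (ep == "OS") {
    evaluate_ltp_os(cv$test, cv$control, plateau)
  } else {
    evaluate_ltp_pfs(cv$test, cv$control, plateau, delta_threshold)
  }
  adjustment <- if (!crit$met) {
    "none"
  } else if (ep == "PFS") "pfs_upgrade" else "os_curative_scoring"
  dplyr::bind_cols(
    base,
    tibble(awarded = crit$met, adjustment = adjustment, endpoint_used = ep),
    prefix_criteria_ltp(crit)
  )
}

prefix_criteria_ltp <- function(crit) {
  names(crit) <- paste("ltp", names(crit), sep = "_")
  crit
}

#' Score a whole cohort with the ESMO-MCBS v1.1 long-term-plateau adjustment
#'
#' @param trials A cohort tibble.
#' @inheritParams award_ltp
#' @return A tibble with one row per trial: trial metadata, eligibility and
#'   reason, the award decision and the flattened criteria.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_recipe(n_trials = 4, seed = 1))
#' score_esmo(coh)
score_esmo <- function(trials, delta_threshold = 0.10, window_frac = 0.2,
                       drop_tol = 0.05, min_at_risk = 10) {
  trials <- cohort(trials)
  res <- purrr::map_dfr(
    seq_len(nrow(trials)),
    function(i) award_ltp(trials[i, ], delta_threshold, window_frac,
                          drop_tol, min_at_risk)
  )
  dplyr::bind_cols(
    dplyr::select(trials, "trial_id", "therapy_class", "disease_site"),
    dplyr::select(res, -"trial_id")
  )
}
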