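# curve with a given control median, a plateau-shaped tail at `tail` from
# t = start, and follow-up long enough for the 5y/7y milestones
ltp_curve <- function(median_at, tail, followup = 96, at_risk_late = 40) {
  step_curve(
    times = c(median_at, median_at * 1.5, followup * 0.6),
    surv = c(0.5, max(tail + 0.05, tail), tail),
    at_risk = c(120, 80, at_risk_late),
    max_followup = followup
  )
}

ltp_trial <- function(primary = "OS", os_test = NULL, os_ctrl = NULL,
                      pfs_test = NULL, pfs_ctrl = NULL, significant = TRUE,
                      hematological = FALSE, override_os = NA,
                      override_pfs = NA, form_override = NA_character_) {
  cohort(tibble::tibble(
    trial_id = "E1", therapy_class = "ICI", therapy_subclass = "ICI",
    disease_site = "skin", hematological = hematological,
    primary_endpoint = primary, primary_significant = significant,
    os_reported = !is.null(os_test), os_obscured_by_crossover = FALSE,
    pfs_reported = !is.null(pfs_test),
    plateau_override_os = override_os, plateau_override_pfs = override_pfs,
    ltp_form_override = form_override,
    curve_os_test = list(os_test), curve_os_control = list(os_ctrl),
    curve_pfs_test = list(pfs_test), curve_pfs_control = list(pfs_ctrl)
  ))
}

test_that("the LTP endpoint form follows the primary endpoint, OS for coprimary", {
  os <- ltp_curve(10, 0.3)
  tr <- ltp_trial("OS", os, os)
  expect_equal(select_ltp_endpoint(tr), "OS")
  trp <- ltp_trial("PFS", pfs_test = os, pfs_ctrl = os)
  expect_equal(select_ltp_endpoint(trp), "PFS")
  trc <- ltp_trial("OS+PFS", os, os, os, os)
  expect_equal(select_ltp_endpoint(trc), "OS")
  trov <- ltp_trial("OS+PFS", os, os, os, os, form_override = "PFS")
  expect_equal(select_ltp_endpoint(trov), "PFS")
  ineligible <- ltp_trial("OS", os, os, significant = FALSE)
  expect_error(select_ltp_endpoint(ineligible), "eligible")
})

test_that("the OS milestone branches at a 12-month control median, inclusively", {
  test <- ltp_curve(20, 0.4)
  for (cm in c(11.9, 12, 12.1)) {
    ctrl <- ltp_curve(cm, 0.2)
    crit <- evaluate_ltp_os(test, ctrl, manual_plateau(TRUE))
    expect_equal(crit$t_eval, if (cm <= 12) 60 else 84,
                 info = sprintf("control median %.1f", cm))
  }
  # unreached control median routes to the 7-year milestone
  flat <- km_estimate(rep(90, 30), rep(FALSE, 30))
  crit <- evaluate_ltp_os(test, flat, manual_plateau(TRUE))
  expect_equal(crit$t_eval, 84)
})

test_that("the PFS milestone branches at a 6-month control median, inclusively", {
  test <- ltp_curve(8, 0.4)
  for (cm in c(5.9, 6, 6.1)) {
    ctrl <- ltp_curve(cm, 0.1)
    crit <- evaluate_ltp_pfs(test, ctrl, manual_plateau(TRUE))
    expect_equal(crit$t_eval, if (cm <= 6) 12 else 24,
                 info = sprintf("control median %.1f", cm))
  }
})

test_that("the PFS form needs a plateau plus a 10-point absolute gain", {
  # control median 4 -> 1-year milestone; S_test(12)=0.35, S_ctrl(12)=0.20
  test <- step_curve(c(4, 10), c(0.6, 0.35), c(100, 50), max_followup = 30)
  ctrl <- step_curve(c(4, 10), c(0.5, 0.20), c(100, 40), max_followup = 30)
  crit <- evaluate_ltp_pfs(test, ctrl, manual_plateau(TRUE))
  expect_equal(crit$t_eval, 12)
  expect_equal(crit$delta, 0.15)
  expect_true(crit$met)
  # an 8-month control median moves the read-out to 2 years
  ctrl8 <- step_curve(c(8, 10), c(0.5, 0.20), c(100, 40), max_followup = 30)
  crit <- evaluate_ltp_pfs(test, ctrl8, manual_plateau(TRUE))
  expect_equal(crit$t_eval, 24)
  # without the plateau a large delta is not enough: criteria are conjunctive
  crit <- evaluate_ltp_pfs(test, ctrl, manual_plateau(FALSE))
  expect_false(crit$met)
  # exactly 0.10 qualifies (inclusive)
  ctrl10 <- step_curve(c(4, 10), c(0.5, 0.25), c(100, 40), max_followup = 30)
  crit <- evaluate_ltp_pfs(test, ctrl10, manual_plateau(TRUE))
  expect_equal(crit$delta, 0.10)
  expect_true(crit$met)
})

test_that("the OS form needs a plateau plus any strict OS advantage", {
  test <- ltp_curve(14, 0.25)
  ctrl <- ltp_curve(10, 0.10)
  crit <- evaluate_ltp_os(test, ctrl, manual_plateau(TRUE))
  expect_equal(crit$t_eval, 60)
  expect_true(crit$met)
  # follow-up 70 < the 84-month milestone of a >12-month control median
  ctrl14 <- ltp_curve(14, 0.10, followup = 96)
  test70 <- ltp_curve(14, 0.25, followup = 70)
  crit <- evaluate_ltp_os(test70, ctrl14, manual_plateau(TRUE))
  expect_equal(crit$t_eval, 84)
  expect_false(crit$data_extends_to_t_eval)
  expect_false(crit$met)
  # a tie is not an advantage
  tie <- ltp_curve(10, 0.25)
  crit <- evaluate_ltp_os(tie, ltp_curve(10, 0.25), manual_plateau(TRUE))
  expect_equal(crit$delta, 0)
  expect_false(crit$met)
})

test_that("award_ltp gates on eligibility and labels the adjustment kinds", {
  os_t <- ltp_curve(10, 0.25)
  os_c <- ltp_curve(10, 0.10)
  hem <- ltp_trial("OS", os_t, os_c, hematological = TRUE)
  res <- award_ltp(hem)
  expect_false(res$awarded)
  expect_match(res$ineligible_reason, "hematological")
  notsig <- ltp_trial("OS", os_t, os_c, significant = FALSE)
  expect_match(award_ltp(notsig)$ineligible_reason, "not significant")

  # OS award: curative-intent scoring; plateau from the manual override
  tros <- ltp_trial("OS", os_t, os_c, override_os = TRUE)
  res <- award_ltp(tros)
  expect_true(res$awarded)
  expect_equal(res$adjustment, "os_curative_scoring")
  expect_equal(res$ltp_plateau_source, "manual_override")

  # PFS award: one-grade upgrade
  pfs_t <- step_curve(c(4, 10), c(0.6, 0.35), c(100, 50), max_followup = 30)
  pfs_c <- step_curve(c(4, 10), c(0.5, 0.20), c(100, 40), max_followup = 30)
  trpfs <- ltp_trial("PFS", pfs_test = pfs_t, pfs_ctrl = pfs_c,
                     override_pfs = TRUE)
  res <- award_ltp(trpfs)
  expect_true(res$awarded)
  expect_equal(res$adjustment, "pfs_upgrade")

  # without the override, the detector runs on the test-arm curve
  res <- award_ltp(ltp_trial("PFS", pfs_test = pfs_t, pfs_ctrl = pfs_c))
  expect_equal(res$ltp_plateau_source, "detector")
})

test_that("an eligible trial earns at most one adjustment kind", {
  set.seed(501)
  for (i in 1:60) {
    res <- award_ltp(cohort(random_trial("M1")))
    expect_true(res$adjustment %in% c("none", "pfs_upgrade",
                                      "os_curative_scoring"))
    expect_equal(res$awarded, res$adjustment != "none")
  }
})

test_that("award_ltp matches a brute-force transcription of the criteria", {
  set.seed(502)
  for (i in 1:200) {
    tr <- cohort(random_trial(sprintf("B%03d", i)))
    got <- award_ltp(tr)
    want <- oracle_ltp_award(tr)
    expect_equal(got$awarded, want$awarded, info = sprintf("trial %d", i))
    expect_equal(got$adjustment, want$adjustment, info = sprintf("trial %d", i))
  }
})

test_that("lowering the PFS delta threshold never removes an award", {
  set.seed(503)
  trials <- purrr::map(1:40, ~ cohort(random_trial(sprintf("S%02d", .x))))
  counts <- vapply(c(0.3, 0.2, 0.1, 0.05, 0), function(thr) {
    sum(vapply(trials, function(tr) award_ltp(tr, delta_threshold = thr)$awarded,
               logical(1)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
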