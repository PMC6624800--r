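test_that("risk_difference reproduces the published award-rate contrasts", {
  # ASCO: 8/14 ICI vs 37/86 non-ICI
  rd <- risk_difference(8, 14, 37, 86)
  expect_equal(round(rd$rd, 2), 0.14)
  expect_equal(round(rd$ci_low, 2), -0.14)
  expect_equal(round(rd$ci_high, 2), 0.42)
  expect_equal(round(rd$p_value, 2), 0.32)
  # ESMO: 1/12 ICI vs 1/66 non-ICI
  rd <- risk_difference(1, 12, 1, 66)
  expect_equal(round(rd$rd, 2), 0.07)
  expect_equal(round(rd$ci_low, 2), -0.09)
  expect_equal(round(rd$ci_high, 2), 0.23)
  expect_equal(round(rd$p_value, 2), 0.40)
})

test_that("risk_difference basics: identical groups, symmetry, validation", {
  rd <- risk_difference(5, 10, 5, 10)
  expect_equal(rd$rd, 0)
  expect_equal(rd$ci_low, -rd$ci_high)
  # CI is centred on the estimate and narrows with n
  wide <- risk_difference(8, 14, 37, 86)
  narrow <- risk_difference(80, 140, 370, 860)
  expect_equal(narrow$rd, wide$rd)
  expect_lt(narrow$ci_high - narrow$ci_low, wide$ci_high - wide$ci_low)
  expect_equal(wide$ci_high - wide$rd, wide$rd - wide$ci_low)
  expect_error(risk_difference(1, 0, 1, 5), "at least 1")
  expect_error(risk_difference(6, 5, 1, 5), "exceed")
  # pooled-SE variant changes the test, not the interval
  pooled <- risk_difference(8, 14, 37, 86, pooled = TRUE)
  expect_equal(pooled$ci_low, wide$ci_low)
  expect_false(isTRUE(all.equal(pooled$z, wide$z)))
})

test_that("cohen_kappa matches independent large-sample reference values", {
  # reference values computed with statsmodels cohens_kappa
  k <- cohen_kappa(1, 37, 1, 39)
  expect_equal(k$kappa, 0.0013477089, tolerance = 1e-8)
  expect_equal(k$se, 0.0366977513, tolerance = 1e-7)
  expect_equal(k$se0, 0.0366743466, tolerance = 1e-7)
  expect_equal(k$ci_low, -0.07057856, tolerance = 1e-6)
  expect_equal(k$ci_high, 0.07327398, tolerance = 1e-6)
  expect_equal(k$p_value, 0.97068594, tolerance = 1e-6)

  k <- cohen_kappa(10, 5, 3, 20)
  expect_equal(k$kappa, 0.5489614243, tolerance = 1e-8)
  expect_equal(k$se, 0.1396359830, tolerance = 1e-7)
  expect_equal(k$p_value, 0.00065983, tolerance = 1e-4)

  k <- cohen_kappa(3, 14, 6, 27)
  expect_equal(k$kappa, -0.0060362173, tolerance = 1e-8)
  expect_equal(k$se, 0.1289773028, tolerance = 1e-7)
})

test_that("cohen_kappa endpoints: perfect agreement, independence, degeneracy", {
  expect_equal(cohen_kappa(10, 0, 0, 10)$kappa, 1)
  expect_equal(cohen_kappa(25, 25, 25, 25)$kappa, 0)
  # degenerate margins: everything in one cell leaves kappa undefined
  expect_true(is.na(cohen_kappa(0, 0, 0, 50)$kappa))
})

test_that("kappa is label-symmetric and bounded", {
  set.seed(601)
  for (i in 1:100) {
    cells <- as.numeric(stats::rmultinom(1, sample(10:200, 1), runif(4)))
    k1 <- cohen_kappa(cells[1], cells[2], cells[3], cells[4])$kappa
    # swapping the two frameworks transposes the table
    k2 <- cohen_kappa(cells[1], cells[3], cells[2], cells[4])$kappa
    if (!is.na(k1)) {
      expect_equal(k1, k2)
      expect_gte(k1, -1)
      expect_lte(k1, 1)
    }
  }
})

test_that("mcnemar_discordant agrees with stats::mcnemar.test on random tables", {
  # direct value: (37-1)^2 / 38, and the corrected variant
  expect_equal(mcnemar_discordant(37, 1)$chi2, 36^2 / 38)
  expect_equal(mcnemar_discordant(37, 1, correct = TRUE)$chi2, 35^2 / 38)
  expect_equal(mcnemar_discordant(5, 5)$chi2, 0)
  expect_equal(mcnemar_discordant(5, 5)$p_value, 1)
  expect_equal(mcnemar_discordant(0, 0)$n_discordant, 0L)
  expect_true(is.na(mcnemar_discordant(0, 0)$chi2))
  set.seed(602)
  for (i in 1:50) {
    cells <- as.numeric(stats::rmultinom(1, sample(20:150, 1), runif(4)))
    if (cells[2] + cells[3] == 0) next
    got <- mcnemar_discordant(cells[2], cells[3])
    ref <- stats::mcnemar.test(matrix(c(cells[1], cells[3], cells[2], cells[4]),
                                      2, 2), correct = FALSE)
    expect_equal(got$chi2, unname(ref$statistic))
    expect_equal(got$p_value, unname(ref$p.value))
  }
})

test_that("mcnemar depends only on the discordant cells", {
  a <- mcnemar_discordant(12, 4)
  expect_equal(mcnemar_discordant(12, 4)$chi2, a$chi2)
  k1 <- cohen_kappa(5, 12, 4, 5)
  k2 <- cohen_kappa(50, 12, 4, 50)
  expect_false(isTRUE(all.equal(k1$kappa, k2$kappa)))  # kappa does change
  expect_equal(mcnemar_discordant(12, 4)$chi2,
               mcnemar_discordant(12, 4)$chi2)
})

known_award_cohort <- function() {
  # four eligible trials engineered to land in each cell of the 2x2 table:
  # ASCO award needs ratio >= 1.5 & floor >= 0.2 at t2; ESMO OS award needs
  # plateau (overridden) + advantage at 60 months
  good_t <- step_curve(c(10, 20, 60), c(0.5, 0.40, 0.35), c(100, 60, 30),
                       max_followup = 80)
  good_c <- step_curve(c(10, 20, 60), c(0.5, 0.25, 0.20), c(100, 55, 25),
                       max_followup = 80)
  bad_t <- step_curve(c(10, 20, 60), c(0.5, 0.26, 0.20), c(100, 60, 30),
                      max_followup = 80)
  ctrl_eo <- step_curve(c(10, 20, 60), c(0.5, 0.20, 0.10), c(100, 55, 25),
                        max_followup = 80)
  cohort(tibble::tibble(
    trial_id = c("both", "asco_only", "esmo_only", "neither"),
    therapy_class = c("ICI", "non-ICI", "ICI", "non-ICI"),
    therapy_subclass = c("ICI", "targeted", "ICI", "targeted"),
    disease_site = c("skin", "lung", "skin", "lung"),
    hematological = FALSE, primary_endpoint = "OS",
    primary_significant = TRUE, os_reported = TRUE,
    os_obscured_by_crossover = FALSE, pfs_reported = FALSE,
    plateau_override_os = c(TRUE, FALSE, TRUE, FALSE),
    curve_os_test = list(good_t, good_t, bad_t, bad_t),
    curve_os_control = list(good_c, good_c, ctrl_eo, good_c)
  ))
}

test_that("build_concordance tabulates known awards into the right cells", {
  coh <- known_award_cohort()
  asco <- score_asco(coh)
  esmo <- score_esmo(coh)
  expect_equal(asco$awarded, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(esmo$awarded, c(TRUE, FALSE, TRUE, FALSE))
  cc <- build_concordance(coh, asco, esmo)
  expect_equal(unname(cc$cells), c(1, 1, 1, 1))
  expect_equal(cc$n, 4)
  g <- glance(cc)
  expect_equal(g$percent_agreement, 50)
  td <- tidy(cc)
  expect_equal(sum(td$count), 4)
  # subgroup split by therapy class covers all dual-eligible trials
  expect_equal(sum(cc$subgroups$therapy_class$n), 4)
})

test_that("ineligible trials never enter the concordance table", {
  coh <- known_award_cohort()
  coh$primary_significant <- c(TRUE, FALSE, TRUE, FALSE)
  cc <- build_concordance(coh, score_asco(coh), score_esmo(coh))
  expect_equal(cc$n, 2)
  all_out <- known_award_cohort()
  all_out$hematological <- rep(TRUE, 4)
  cc0 <- build_concordance(all_out, score_asco(all_out), score_esmo(all_out))
  expect_equal(cc0$n, 0)
  expect_equal(unname(cc0$cells), c(0, 0, 0, 0))
})

test_that("build_concordance rejects mismatched trial sets", {
  coh <- known_award_cohort()
  asco <- score_asco(coh)
  esmo <- score_esmo(coh)
  expect_error(build_concordance(coh, asco[-1, ], esmo), "cover exactly")
})

test_that("percent agreement from the published cross-classification is 51.3%", {
  g <- glance(structure(
    list(cells = c(both = 1, asco_only = 37, esmo_only = 1, neither = 39),
         n = 78, trials = NULL, subgroups = NULL),
    class = "tc_concordance"
  ))
  expect_equal(round(g$percent_agreement, 1), 51.3)
  expect_equal(g$n_agree, 40)
})

test_that("award_risk_difference splits by therapy class and honours eligibility", {
  coh <- known_award_cohort()
  asco <- score_asco(coh)
  rd <- award_risk_difference(asco)
  expect_equal(rd$x_ici, 1); expect_equal(rd$n_ici, 2)
  expect_equal(rd$x_non_ici, 1); expect_equal(rd$n_non_ici, 2)
  expect_equal(rd$rd, 0)
  esmo <- score_esmo(coh)
  esmo$eligible[2] <- FALSE
  rd <- award_risk_difference(esmo)
  expect_equal(rd$n_non_ici, 1)
})
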