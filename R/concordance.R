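#' Risk difference between two award proportions
#'
#' Difference in award rates between two trial groups (typically ICI vs
#' non-ICI), with the unpooled Wald standard error for the confidence
#' interval. The two-sided test uses the same unpooled SE by default; set
#' `pooled = TRUE` for the pooled-proportion null SE.
#'
#' @param x1,n1 Awards and trials in group 1.
#' @param x2,n2 Awards and trials in group 2.
#' @param conf_level Confidence level, default 0.95.
#' @param pooled Use the pooled SE for the test statistic, default `FALSE`.
#' @return One-row tibble: `p1`, `p2`, `rd`, `ci_low`, `ci_high`, `z`,
#'   `p_value`.
#' @export
#' @examples
#' risk_difference(8, 14, 37, 86)   # rd 0.14, CI (-0.14, 0.42)
risk_difference <- function(x1, n1, x2, n2, conf_level = 0.95,
                            pooled = FALSE) {
  for (v in list(x1, n1, x2, n2)) {
    if (length(v) != 1L || is.na(v) || v < 0) {
      abort("counts must be single non-negative numbers")
    }
  }
  if (n1 < 1 || n2 < 1) abort("both group sizes must be at least 1")
  if (x1 > n1 || x2 > n2) abort("awards cannot exceed group size")
  p1 <- x1 / n1
  p2 <- x2 / n2
  rd <- p1 - p2
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  se_test <- if (pooled) {
    pbar <- (x1 + x2) / (n1 + n2)
    sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  } else {
    se
  }
  z <- if (se_test > 0) rd / se_test else NA_real_
  tibble(
    p1 = p1, p2 = p2, rd = rd,
    ci_low = rd - zq * se, ci_high = rd + zq * se,
    z = z, p_value = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z))
  )
}

#' Cohen kappa for a 2x2 award/withhold cross-classification
#'
#' Chance-corrected agreement between the two frameworks' binary decisions:
#' `kappa = (po - pe) / (1 - pe)` where `po` is observed agreement and `pe`
#' the agreement expected from the marginal award rates. The confidence
#' interval uses the large-sample (Fleiss-Cohen-Everitt) variance; the
#' p-value for H0: kappa = 0 uses the null-variance SE. Degenerate margins
#' (`pe = 1`) leave kappa undefined (`NA`).
#'
#' @param both,asco_only,esmo_only,neither Cell counts of the 2x2 table:
#'   awarded by both, by the first framework only, by the second only,
#'   by neither.
#' @param conf_level Confidence level, default 0.95.
#' @return One-row tibble: `kappa`, `se`, `ci_low`, `ci_high`, `se0`, `z`,
#'   `p_value`, `po`, `pe`, `n`.
#' @export
#' @examples
#' cohen_kappa(1, 37, 1, 39)   # near-chance agreement
cohen_kappa <- function(both, asco_only, esmo_only, neither,
                        conf_level = 0.95) {
  cells <- c(both, asco_only, esmo_only, neither)
  if (any(is.na(cells)) || any(cells < 0)) {
    abort("cell counts must be non-negative")
  }
  n <- sum(cells)
  if (n < 1) abort("the table must contain at least one trial")
  p <- matrix(cells / n, 2, 2, byrow = TRUE)  # rows: framework 1, cols: framework 2
  prow <- rowSums(p)
  pcol <- colSums(p)
  po <- p[1, 1] + p[2, 2]
  pe <- sum(prow * pcol)
  if (1 - pe < 1e-12) {
    return(tibble(kappa = NA_real_, se = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, se0 = NA_real_, z = NA_real_,
                  p_value = NA_real_, po = po, pe = pe, n = n))
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt large-sample variance
  a <- sum(diag(p) * ((1 - pe) - (prow + pcol) * (1 - po))^2)
  b <- (1 - po)^2 * (p[1, 2] * (pcol[1] + prow[2])^2 +
                     p[2, 1] * (pcol[2] + prow[1])^2)
  cc <- (po * pe - 2 * pe + po)^2
  var_k <- (a + b - cc) / (n * (1 - pe)^4)
  # null variance for H0: kappa = 0
  var0 <- (pe + pe^2 - sum(prow * pcol * (prow + pcol))) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  se0 <- sqrt(max(var0, 0))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  z <- if (se0 > 0) kappa / se0 else NA_real_
  tibble(
    kappa = kappa, se = se, ci_low = kappa - zq * se, ci_high = kappa + zq * se,
    se0 = se0, z = z, p_value = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
    po = po, pe = pe, n = n
  )
}

#' McNemar test on the discordant awards
#'
#' Tests marginal homogeneity of the two frameworks' award rates using only
#' the discordant cells: `chi2 = (b - c)^2 / (b + c)` on 1 df, where `b` and
#' `c` count trials awarded by exactly one framework. Uncorrected by default
#' (a continuity correction is available behind the flag). With no discordant
#' trials the test is undefined (`NA`).
#'
#' @param asco_only,esmo_only Discordant cell counts.
#' @param correct Apply the continuity correction, default `FALSE`.
#' @return One-row tibble: `chi2`, `df`, `p_value`, `n_discordant`.
#' @export
#' @examples
#' mcnemar_discordant(37, 1)   # chi2 = 36^2 / 38
mcnemar_discordant <- function(asco_only, esmo_only, correct = FALSE) {
  b <- asco_only
  cc <- esmo_only
  if (any(is.na(c(b, cc))) || b < 0 || cc < 0) {
    abort("discordant counts must be non-negative")
  }
  nd <- b + cc
  if (nd < 1) {
    return(tibble(chi2 = NA_real_, df = 1L, p_value = NA_real_,
                  n_discordant = 0L))
  }
  num <- if (correct) (abs(b - cc) - 1)^2 else (b - cc)^2
  chi2 <- num / nd
  tibble(chi2 = chi2, df = 1L, p_value = pchisq(chi2, 1, lower.tail = FALSE),
         n_discordant = as.integer(nd))
}

#' Cross-classify the two frameworks' awards over a cohort
#'
#' Joins the ASCO and ESMO scoring tables on `trial_id`, keeps the
#' dual-eligible trials (those the ESMO rules could assess at all), and
#' builds the 2x2 award/withhold table plus subgroup tables by therapy
#' class, by the ESMO-selected endpoint, and by disease site. Mismatched
#' trial sets are an error.
#'
#' @param trials The cohort tibble both scoring passes were run on.
#' @param asco_results Output of [score_asco()].
#' @param esmo_results Output of [score_esmo()].
#' @return An object of class `tc_concordance`: list with `cells` (named
#'   counts `both`, `asco_only`, `esmo_only`, `neither`), `n`, `trials`
#'   (per-trial award pairs), and `subgroups` (named list of count tables).
#'   Use [glance()] for kappa/McNemar/percent agreement, [tidy()] for the
#'   cell counts.
#' @export
build_concordance <- function(trials, asco_results, esmo_results) {
  trials <- cohort(trials)
  ids <- sort(trials$trial_id)
  if (!identical(sort(asco_results$trial_id), ids) ||
      !identical(sort(esmo_results$trial_id), ids)) {
    abort("ASCO/ESMO results must cover exactly the trials of the cohort")
  }
  merged <- trials |>
    dplyr::select("trial_id", "therapy_class", "disease_site") |>
    dplyr::left_join(
      dplyr::select(asco_results, "trial_id", asco_awarded = "awarded"),
      by = "trial_id") |>
    dplyr::left_join(
      dplyr::select(esmo_results, "trial_id", esmo_awarded = "awarded",
                    esmo_eligible = "eligible", esmo_endpoint = "endpoint_used"),
      by = "trial_id")
  dual <- dplyr::filter(merged, .data$esmo_eligible)
  count_cells <- function(d) {
    c(both = sum(d$asco_awarded & d$esmo_awarded),
      asco_only = sum(d$asco_awarded & !d$esmo_awarded),
      esmo_only = sum(!d$asco_awarded & d$esmo_awarded),
      neither = sum(!d$asco_awarded & !d$esmo_awarded))
  }
  subgroup_tables <- function(d, col) {
    d |>
      dplyr::group_by(.data[[col]]) |>
      dplyr::group_map(~ tibble(group = .y[[1]], !!!as.list(count_cells(.x)),
                                n = nrow(.x))) |>
      dplyr::bind_rows()
  }
  structure(
    list(
      cells = count_cells(dual),
      n = nrow(dual),
      trials = dual,
      subgroups = list(
        therapy_class = subgroup_tables(dual, "therapy_class"),
        esmo_endpoint = subgroup_tables(dual, "esmo_endpoint"),
        disease_site = subgroup_tables(dual, "disease_site")
      )
    ),
    class = "tc_concordance"
  )
}

#' @export
print.tc_concordance <- function(x, ...) {
  cat(sprintf("<tc_concordance> %d dual-eligible trials\n", x$n))
  print(tidy(x))
  if (x$n > 0) print(glance(x))
  invisible(x)
}

#' @describeIn build_concordance Cell counts in long form.
#' @param x A `tc_concordance` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tc_concordance <- function(x, ...) {
  tibble(
    cell = names(x$cells),
    asco = c(TRUE, TRUE, FALSE, FALSE),
    esmo = c(TRUE, FALSE, TRUE, FALSE),
    count = as.integer(x$cells)
  )
}

#' @describeIn build_concordance One-row summary: percent agreement, Cohen
#'   kappa with CI and p, McNemar chi-squared and p.
#' @exportS3Method generics::glance
glance.tc_concordance <- function(x, ...) {
  cl <- as.list(x$cells)
  kap <- cohen_kappa(cl$both, cl$asco_only, cl$esmo_only, cl$neither)
  mcn <- mcnemar_discordant(cl$asco_only, cl$esmo_only)
  tibble(
    n = x$n,
    n_agree = cl$both + cl$neither,
    percent_agreement = 100 * (cl$both + cl$neither) / x$n,
    kappa = kap$kappa, kappa_ci_low = kap$ci_low, kappa_ci_high = kap$ci_high,
    kappa_p = kap$p_value,
    mcnemar_chi2 = mcn$chi2, mcnemar_p = mcn$p_value
  )
}

#' Award-rate risk difference between therapy classes
#'
#' Convenience wrapper: computes the ICI vs non-ICI award-rate risk
#' difference from a scoring table ([score_asco()] or [score_esmo()]
#' output). For ESMO results only eligible trials enter the denominators.
#'
#' @param results A scoring table with `therapy_class` and `awarded` columns
#'   (and optionally `eligible`).
#' @param conf_level Confidence level, default 0.95.
#' @return One-row tibble as [risk_difference()], plus the four counts.
#' @export
award_risk_difference <- function(results, conf_level = 0.95) {
  if ("eligible" %in% names(results)) {
    results <- dplyr::filter(results, .data$eligible)
  }
  ici <- dplyr::filter(results, .data$therapy_class == "ICI")
  non <- dplyr::filter(results, .data$therapy_class == "non-ICI")
  if (nrow(ici) == 0L || nrow(non) == 0L) {
    abort("both therapy classes must be present to compare award rates")
  }
  rd <- risk_difference(sum(ici$awarded), nrow(ici), sum(non$awarded),
                        nrow(non), conf_level = conf_level)
  dplyr::bind_cols(
    tibble(x_ici = sum(ici$awarded), n_ici = nrow(ici),
           x_non_ici = sum(non$awarded), n_non_ici = nrow(non)),
    rd
  )
}
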