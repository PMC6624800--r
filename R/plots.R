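#' Plot a Kaplan-Meier step curve
#'
#' @param object A [step_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.step_curve <- function(object, ...) {
  df <- as_tibble(object)
  df <- dplyr::bind_rows(
    tibble(time_months = 0, survival = 1, at_risk = object$n_enrolled),
    df,
    tibble(time_months = object$max_followup,
           survival = df$survival[nrow(df)],
           at_risk = df$at_risk[nrow(df)])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_months, y = .data$survival)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Overlay the two arms of a trial endpoint
#'
#' @param trial A one-row cohort tibble.
#' @param endpoint `"OS"` or `"PFS"`.
#' @return A ggplot with one step per arm.
#' @export
plot_trial_curves <- function(trial, endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  cv <- trial_curves(trial, endpoint)
  if (is.null(cv$test) || is.null(cv$control)) {
    abort(sprintf("trial %s has no %s curves", trial$trial_id, endpoint))
  }
  df <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(cv$test), arm = "test"),
    dplyr::mutate(as_tibble(cv$control), arm = "control")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_months, y = .data$survival,
                                   colour = .data$arm)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("%s: %s", trial$trial_id, endpoint),
                  x = "Months", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ASCO floor-threshold sweep
#'
#' @param sweep Output of [threshold_sweep()].
#' @return A ggplot of award counts against the floor, by therapy class.
#' @export
plot_threshold_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$floor_threshold,
                                      y = .data$n_awarded,
                                      colour = .data$therapy_class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Control-survival floor at t2",
                  y = "Trials awarded the TOC bonus", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a framework-agreement table
#'
#' @param object A `tc_concordance` from [build_concordance()].
#' @param ... Unused.
#' @return A ggplot tile view of the 2x2 table.
#' @exportS3Method ggplot2::autoplot
autoplot.tc_concordance <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(
      asco = factor(ifelse(.data$asco, "awarded", "withheld"),
                    levels = c("withheld", "awarded")),
      esmo = factor(ifelse(.data$esmo, "awarded", "withheld"),
                    levels = c("awarded", "withheld"))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$asco, y = .data$esmo)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count), colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "ASCO-VF v2 TOC bonus", y = "ESMO-MCBS v1.1 LTP adjustment",
                  fill = "Trials") +
    ggplot2::theme_minimal()
}
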