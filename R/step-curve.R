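#' Construct a Kaplan-Meier step curve
#'
#' A `step_curve` is a right-continuous survival step function: at each grid
#' time the curve holds the recorded survival probability until the next grid
#' time. The grid may contain times at which the curve does not drop (e.g.
#' censoring times, or rows read from a digitised number-at-risk table); what
#' matters is that survival is non-increasing along the grid. Queries beyond
#' `max_followup` are answered with `NA` rather than extrapolated: the curve
#' simply does not extend that far, a distinction the award rules rely on.
#'
#' Invariant violations are errors, never silently repaired: a digitised curve
#' whose survival column increases, whose times are not strictly increasing,
#' or whose at-risk counts grow over time is rejected as-is.
#'
#' @param times Strictly increasing event/censoring time grid, in months,
#'   all non-negative.
#' @param surv Survival probability just after each grid time, non-increasing,
#'   in `[0, 1]`.
#' @param at_risk Number of subjects at risk just before each grid time;
#'   positive, non-increasing.
#' @param max_followup Largest observed (event or censoring) time in months.
#'   Defaults to the last grid time.
#' @param n_enrolled Number of subjects the curve was estimated from.
#'   Defaults to `at_risk[1]`.
#'
#' @return An object of class `step_curve`.
#' @seealso [km_estimate()], [survival_at()], [median_survival()], [rmst()],
#'   [detect_plateau()]
#' @export
#' @examples
#' sc <- step_curve(times = c(4, 9), surv = c(0.6, 0.4), at_risk = c(10, 6))
#' survival_at(sc, 5)
#' median_survival(sc)
step_curve <- function(times, surv, at_risk, max_followup = NULL,
                       n_enrolled = NULL) {
  times <- as.numeric(times)
  surv <- as.numeric(surv)
  at_risk <- as.numeric(at_risk)
  n <- length(times)
  if (n == 0L) {
    abort("a step curve needs at least one grid time")
  }
  if (length(surv) != n || length(at_risk) != n) {
    abort("`times`, `surv` and `at_risk` must have equal length")
  }
  if (anyNA(times) || anyNA(surv) || anyNA(at_risk)) {
    abort("step curve fields must not contain missing values")
  }
  if (any(times < 0)) {
    abort("times must be non-negative")
  }
  if (n > 1L && any(diff(times) <= 0)) {
    abort("times must be strictly increasing")
  }
  if (any(surv < 0) || any(surv > 1)) {
    abort("survival probabilities must lie in [0, 1]")
  }
  if (n > 1L && any(diff(surv) > 1e-12)) {
    abort("survival must be non-increasing along the grid")
  }
  if (any(at_risk <= 0)) {
    abort("at-risk counts must be positive at every listed time")
  }
  if (n > 1L && any(diff(at_risk) > 0)) {
    abort("at-risk counts must be non-increasing")
  }
  max_followup <- as.numeric(max_followup %||% times[n])
  if (length(max_followup) != 1L || is.na(max_followup) ||
      max_followup < times[n]) {
    abort("`max_followup` must be a single time >= the last grid time")
  }
  n_enrolled <- as.numeric(n_enrolled %||% at_risk[1])
  if (length(n_enrolled) != 1L || is.na(n_enrolled) || n_enrolled < at_risk[1]) {
    abort("`n_enrolled` must be a single count >= the first at-risk count")
  }
  structure(
    list(times = times, surv = surv, at_risk = at_risk,
         max_followup = max_followup, n_enrolled = n_enrolled),
    class = "step_curve"
  )
}

#' @export
print.step_curve <- function(x, ...) {
  cat(sprintf(
    "<step_curve> %d grid times, follow-up %.3g mo, n = %g enrolled\n",
    length(x$times), x$max_followup, x$n_enrolled
  ))
  print(as_tibble(x), ...)
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.step_curve <- function(x, ...) {
  tibble(time_months = x$times, survival = x$surv, at_risk = x$at_risk)
}

#' @export
format.step_curve <- function(x, ...) {
  sprintf("<step_curve: %d times, followup %.3g>", length(x$times),
          x$max_followup)
}

is_step_curve <- function(x) inherits(x, "step_curve")

assert_step_curve <- function(x, what = "curve") {
  if (!is_step_curve(x)) {
    abort(sprintf("`%s` must be a step_curve object", what))
  }
  invisible(x)
}

#' Kaplan-Meier product-limit estimate from raw follow-up times
#'
#' Fits the product-limit estimator (via [survival::survfit()]) and packages
#' it as a [step_curve()]. The grid keeps every distinct observed time,
#' censorings included, so at-risk counts remain queryable along the whole
#' curve; survival does not drop at censoring-only times. An input with no
#' events yields a curve flat at 1.
#'
#' @param event_times Follow-up times in months, non-negative.
#' @param event_flags Logical (or 0/1) vector; `TRUE` marks an event,
#'   `FALSE` a censoring.
#' @return A [step_curve()].
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))$surv
km_estimate <- function(event_times, event_flags) {
  event_times <- as.numeric(event_times)
  event_flags <- as.logical(event_flags)
  if (length(event_times) == 0L) {
    abort("at least one subject is required")
  }
  if (length(event_flags) != length(event_times)) {
    abort("`event_times` and `event_flags` must have equal length")
  }
  if (anyNA(event_times) || anyNA(event_flags)) {
    abort("missing values are not allowed in follow-up data")
  }
  if (any(event_times < 0)) {
    abort("negative follow-up times are not allowed")
  }
  fit <- survival::survfit(
    survival::Surv(event_times, event_flags) ~ 1,
    conf.type = "none"
  )
  step_curve(
    times = fit$time,
    surv = fit$surv,
    at_risk = fit$n.risk,
    max_followup = max(event_times),
    n_enrolled = length(event_times)
  )
}

#' Milestone survival: read the curve at a fixed time
#'
#' Right-continuous step convention: the value recorded at the last grid time
#' at or before `t` holds; before the first grid time survival is 1. Queries
#' beyond the curve's follow-up return `NA_real_` — the trial did not report
#' data that far out, which the award rules treat as a failed
#' "data extend to the milestone" criterion, never as zero survival.
#'
#' @param curve A [step_curve()].
#' @param t Time(s) in months, non-negative; vectorised.
#' @return Numeric vector of survival probabilities, `NA` beyond follow-up.
#' @export
survival_at <- function(curve, t) {
  assert_step_curve(curve)
  t <- as.numeric(t)
  if (anyNA(t) || any(t < 0)) {
    abort("query times must be non-negative and non-missing")
  }
  idx <- findInterval(t, curve$times)
  out <- ifelse(idx == 0L, 1.0, curve$surv[pmax(idx, 1L)])
  out[t > curve$max_followup] <- NA_real_
  out
}

#' Median survival time of a step curve
#'
#' The smallest grid time at which survival is less than or equal to 0.5
#' (inclusive at exactly 0.5). Returns `NA_real_` when the curve never
#' reaches 0.5 within follow-up ("median not reached").
#'
#' @param curve A [step_curve()].
#' @return Months, or `NA_real_` if the median is not reached.
#' @export
median_survival <- function(curve) {
  assert_step_curve(curve)
  hit <- which(curve$surv <= 0.5 + 1e-12)
  if (length(hit) == 0L) NA_real_ else curve$times[hit[1]]
}

#' Restricted mean survival time (RMST)
#'
#' Area under the survival step function on `[0, tau]`. The truncation time
#' must lie within observed follow-up; asking for the area beyond the data is
#' an error, not an extrapolation.
#'
#' @param curve A [step_curve()].
#' @param tau Truncation time in months, `0 < tau <= max_followup`.
#' @return RMST in months.
#' @export
#' @examples
#' sc <- step_curve(4, 0.5, 10, max_followup = 12)
#' rmst(sc, 10)  # 4 * 1 + 6 * 0.5 = 7
rmst <- function(curve, tau) {
  assert_step_curve(curve)
  tau <- as.numeric(tau)
  if (length(tau) != 1L || is.na(tau) || tau <= 0) {
    abort("`tau` must be a single positive time")
  }
  if (tau > curve$max_followup) {
    abort("`tau` exceeds the curve's follow-up; RMST is only defined within observed data")
  }
  # segment boundaries: 0, grid times below tau, tau; S = 1 before first step
  cuts <- c(0, curve$times[curve$times < tau], tau)
  heights <- c(1, curve$surv[curve$times < tau])
  sum(diff(cuts) * heights)
}
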