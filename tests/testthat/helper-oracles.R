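# Independent re-implementations used as oracles. These deliberately avoid
# the package's own query functions: curves are evaluated through
# stats::stepfun, Kaplan-Meier by direct risk-set counting, and the award
# rules by straight-line transcriptions of the framework criteria.

oracle_surv <- function(curve, t) {
  if (t > curve$max_followup) return(NA_real_)
  f <- stats::stepfun(curve$times, c(1, curve$surv), right = FALSE)
  f(t)
}

oracle_median <- function(curve) {
  # inclusive at 0.5 with the same float-noise guard as the implementation:
  # product-limit arithmetic can land an exact 1/2 a few ulp either side
  hit <- curve$times[curve$surv <= 0.5 + 1e-12]
  if (length(hit) == 0) NA_real_ else min(hit)
}

# product-limit by direct counting over distinct event times
oracle_km <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  dt <- sort(unique(times[events]))
  s <- 1
  out <- numeric(0)
  for (d in dt) {
    n_at_risk <- sum(times >= d)
    n_events <- sum(times == d & events)
    s <- s * (1 - n_events / n_at_risk)
    out <- c(out, s)
  }
  list(times = dt, surv = out)
}

oracle_rmst <- function(curve, tau) {
  # integrate the step function on a fine grid midpoint-free: exact via knots
  knots <- sort(unique(c(0, curve$times[curve$times < tau], tau)))
  total <- 0
  for (i in seq_len(length(knots) - 1)) {
    lo <- knots[i]
    val <- if (lo < curve$times[1]) 1 else oracle_surv(curve, lo)
    total <- total + val * (knots[i + 1] - lo)
  }
  total
}

oracle_plateau <- function(curve, window_frac = 0.2, drop_tol = 0.05,
                           min_at_risk = 10) {
  ws <- (1 - window_frac) * curve$max_followup
  drop <- oracle_surv(curve, ws) - oracle_surv(curve, curve$max_followup)
  later <- curve$times[curve$times >= ws]
  ar <- if (length(later) > 0) {
    curve$at_risk[match(min(later), curve$times)]
  } else {
    curve$at_risk[length(curve$at_risk)]
  }
  drop < drop_tol && ar >= min_at_risk
}

# straight transcription of the four ASCO TOC criteria + endpoint routing
oracle_toc_endpoint <- function(test, control, ratio = 1.5, floor = 0.20) {
  med <- oracle_median(control)
  if (is.na(med)) return(FALSE)
  t2 <- 2 * med
  s_t <- oracle_surv(test, t2)
  s_c <- oracle_surv(control, t2)
  if (is.na(s_t) || is.na(s_c)) return(FALSE)          # criterion 2
  if (!(s_c >= floor - 1e-9)) return(FALSE)            # criterion 4
  if (s_c == 0) return(FALSE)
  s_t / s_c >= ratio - 1e-9                            # criterion 3
}

oracle_toc_award <- function(trial, ratio = 1.5, floor = 0.20,
                             os_strict = FALSE) {
  os_ok <- FALSE
  os_assessable <- trial$os_reported && !trial$os_obscured_by_crossover
  if (os_assessable) {
    os_ok <- oracle_toc_endpoint(trial$curve_os_test[[1]],
                                 trial$curve_os_control[[1]], ratio, floor)
  }
  if (os_ok) return(list(awarded = TRUE, points = 20, endpoint = "OS"))
  pfs_allowed <- trial$pfs_reported &&
    (!os_assessable || !os_strict)
  if (pfs_allowed &&
      oracle_toc_endpoint(trial$curve_pfs_test[[1]],
                          trial$curve_pfs_control[[1]], ratio, floor)) {
    return(list(awarded = TRUE, points = 16, endpoint = "PFS"))
  }
  list(awarded = FALSE, points = 0, endpoint = "none")
}

# straight transcription of the ESMO LTP rules
oracle_ltp_award <- function(trial, delta_threshold = 0.10) {
  if (!(trial$primary_significant && !trial$hematological)) {
    return(list(awarded = FALSE, adjustment = "none"))
  }
  ep <- if (!is.na(trial$ltp_form_override)) {
    trial$ltp_form_override
  } else if (trial$primary_endpoint == "PFS") "PFS" else "OS"
  reported <- if (ep == "OS") trial$os_reported else trial$pfs_reported
  if (!reported) return(list(awarded = FALSE, adjustment = "none"))
  test <- if (ep == "OS") trial$curve_os_test[[1]] else trial$curve_pfs_test[[1]]
  ctrl <- if (ep == "OS") trial$curve_os_control[[1]] else trial$curve_pfs_control[[1]]
  override <- if (ep == "OS") trial$plateau_override_os else trial$plateau_override_pfs
  plat <- if (!is.na(override)) override else oracle_plateau(test)
  if (!plat) return(list(awarded = FALSE, adjustment = "none"))
  med <- oracle_median(ctrl)
  t_eval <- if (ep == "OS") {
    if (!is.na(med) && med <= 12) 60 else 84
  } else {
    if (!is.na(med) && med <= 6) 12 else 24
  }
  s_t <- oracle_surv(test, t_eval)
  s_c <- oracle_surv(ctrl, t_eval)
  if (is.na(s_t) || is.na(s_c)) return(list(awarded = FALSE, adjustment = "none"))
  ok <- if (ep == "OS") s_t - s_c > 0 else s_t - s_c >= delta_threshold - 1e-9
  if (!ok) return(list(awarded = FALSE, adjustment = "none"))
  list(awarded = TRUE,
       adjustment = if (ep == "OS") "os_curative_scoring" else "pfs_upgrade")
}

# random small trials spanning reported/unreported endpoints, crossover,
# eligibility flags, cure and no-cure arms, short and long follow-up
random_trial <- function(id) {
  draw_curve <- function() {
    n <- sample(15:40, 1)
    pi_ <- sample(c(0, runif(1, 0, 0.5)), 1)
    lam <- runif(1, 0.03, 0.4)
    followup <- runif(1, 10, 90)
    latent <- stats::rexp(n, lam)
    latent[runif(n) < pi_] <- Inf
    cens <- runif(n, followup * 0.5, followup)
    km_estimate(pmin(latent, cens), latent <= cens)
  }
  os_reported <- runif(1) < 0.9
  pfs_reported <- runif(1) < 0.85 || !os_reported
  tibble::tibble(
    trial_id = id,
    therapy_class = sample(c("ICI", "non-ICI"), 1),
    therapy_subclass = "targeted",
    disease_site = sample(c("lung", "skin", "breast"), 1),
    hematological = runif(1) < 0.2,
    primary_endpoint = sample(c("OS", "PFS", "OS+PFS"), 1),
    primary_significant = runif(1) < 0.8,
    os_reported = os_reported,
    os_obscured_by_crossover = os_reported & runif(1) < 0.25,
    pfs_reported = pfs_reported,
    plateau_override_os = sample(c(NA, TRUE, FALSE), 1, prob = c(0.7, 0.15, 0.15)),
    plateau_override_pfs = sample(c(NA, TRUE, FALSE), 1, prob = c(0.7, 0.15, 0.15)),
    curve_os_test = list(if (os_reported) draw_curve()),
    curve_os_control = list(if (os_reported) draw_curve()),
    curve_pfs_test = list(if (pfs_reported) draw_curve()),
    curve_pfs_control = list(if (pfs_reported) draw_curve())
  )
}

# small deterministic curve maker for hand fixtures
mk_curve <- function(times, surv, at_risk = NULL, followup = NULL, n = NULL) {
  if (is.null(at_risk)) at_risk <- rev(seq_along(times)) + 10
  step_curve(times, surv, at_risk, max_followup = followup, n_enrolled = n)
}
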