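#' Mixture-cure-model configuration for one simulated trial
#'
#' The generative model for each arm is a mixture cure model: a subject is
#' cured (long-term survivor) with probability `pi`, in which case the event
#' never occurs; otherwise the event time follows a Weibull latency with rate
#' `lambda` per month and shape `k` (`k = 1` gives exponential event times),
#' so the underlying survival function is
#' `S(t) = pi + (1 - pi) * exp(-(lambda * t)^k)` — the plateau height equals
#' the cure fraction. Subjects accrue uniformly over `accrual_months` and are
#' administratively censored when the study closes `followup_months` after
#' accrual ends, so a subject enrolled at accrual offset `a` has censoring
#' time `followup_months + (accrual_months - a)`. There is no dropout
#' process.
#'
#' @param n_per_arm Subjects per arm.
#' @param cure_fraction_test,cure_fraction_control Cure fractions in
#'   `[0, 1)`. (`1` is accepted for the degenerate all-cured edge case.)
#' @param event_rate_test,event_rate_control Latency rate per month, > 0.
#' @param shape Weibull shape `k` shared by both arms, default 1
#'   (exponential).
#' @param accrual_months,followup_months Accrual window and minimum
#'   follow-up, both > 0.
#' @return A validated `cure_config` list.
#' @export
cure_config <- function(n_per_arm = 500,
                        cure_fraction_test = 0.4,
                        cure_fraction_control = 0.25,
                        event_rate_test = 0.08,
                        event_rate_control = 0.15,
                        shape = 2,
                        accrual_months = 12,
                        followup_months = 36) {
  stopifnot(length(n_per_arm) == 1L, n_per_arm >= 1)
  for (pi_ in c(cure_fraction_test, cure_fraction_control)) {
    if (is.na(pi_) || pi_ < 0 || pi_ > 1) {
      abort("cure fractions must lie in [0, 1]")
    }
  }
  for (lam in c(event_rate_test, event_rate_control)) {
    if (is.na(lam) || lam <= 0) abort("event rates must be positive")
  }
  if (shape <= 0) abort("`shape` must be positive")
  if (accrual_months <= 0 || followup_months <= 0) {
    abort("accrual and follow-up durations must be positive")
  }
  structure(
    list(n_per_arm = n_per_arm,
         cure_fraction_test = cure_fraction_test,
         cure_fraction_control = cure_fraction_control,
         event_rate_test = event_rate_test,
         event_rate_control = event_rate_control,
         shape = shape,
         accrual_months = accrual_months,
         followup_months = followup_months),
    class = "cure_config"
  )
}

#' True survival function of a cure-model arm
#'
#' `S(t) = pi + (1 - pi) * exp(-(lambda * t)^k)`: the closed form the
#' Kaplan-Meier estimate of a simulated arm converges to, used as the oracle
#' in parameter-recovery checks.
#'
#' @param t Time(s) in months.
#' @param cure_fraction,event_rate,shape Model parameters.
#' @return Survival probabilities.
#' @export
cure_model_survival <- function(t, cure_fraction, event_rate, shape = 1) {
  cure_fraction + (1 - cure_fraction) * exp(-(event_rate * t)^shape)
}

#' Simulate one arm of a cure-model trial
#'
#' @param config A [cure_config()].
#' @param arm `"test"` or `"control"` (selects that arm's cure fraction and
#'   rate).
#' @param seed Integer seed; identical config + seed reproduce the draw
#'   exactly.
#' @return Tibble with `time_months` (observed follow-up) and `event`
#'   (logical).
#' @export
simulate_arm <- function(config, arm = c("test", "control"), seed = NULL) {
  if (!inherits(config, "cure_config")) abort("`config` must be a cure_config")
  arm <- match.arg(arm)
  pi_ <- if (arm == "test") config$cure_fraction_test else config$cure_fraction_control
  lam <- if (arm == "test") config$event_rate_test else config$event_rate_control
  n <- config$n_per_arm
  draw <- function() {
    cured <- runif(n) < pi_
    latent <- rweibull(n, shape = config$shape, scale = 1 / lam)
    latent[cured] <- Inf
    offset <- runif(n, 0, config$accrual_months)
    censor <- config$followup_months + (config$accrual_months - offset)
    tibble(time_months = pmin(latent, censor), event = latent <= censor)
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

# local seed scope without depending on withr at run time
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Named simulation presets
#'
#' Three study conditions spanning the behaviours the award rules are meant
#' to separate:
#'
#' * `ici_like` — the test arm has both a higher cure fraction (0.40 vs
#'   0.25) and slower latency among non-cured patients (rate 0.08 vs
#'   0.15/month, Weibull shape 2), the pattern immune checkpoint inhibitor
#'   trials show: a raised plateau plus delayed events. Metadata: ICI class,
#'   OS primary endpoint, significant.
#' * `non_ici_like` — proportional-hazards-style benefit with no cure in
#'   either arm (rates 0.09 vs 0.12/month, shape 2); the sharpened Weibull
#'   tail pushes control survival at twice its median below the 20% ASCO
#'   floor, the classic failure mode of conventional agents. Metadata:
#'   non-ICI targeted, PFS primary, significant.
#' * `null` — identical arms (cure fraction 0.15, rate 0.12/month, shape 2);
#'   any award is a false positive of the decision rule.
#'
#' @param preset Preset name.
#' @param n_per_arm Subjects per arm, default 500.
#' @return A list with `config` (a [cure_config()]) and `metadata` (trial
#'   flags).
#' @export
trial_preset <- function(preset = c("ici_like", "non_ici_like", "null"),
                         n_per_arm = 500) {
  preset <- match.arg(preset)
  switch(
    preset,
    ici_like = list(
      config = cure_config(
        n_per_arm = n_per_arm,
        cure_fraction_test = 0.40, cure_fraction_control = 0.25,
        event_rate_test = 0.08, event_rate_control = 0.15,
        shape = 2, accrual_months = 12, followup_months = 36
      ),
      metadata = list(therapy_class = "ICI", therapy_subclass = "ICI",
                      disease_site = "skin", hematological = FALSE,
                      primary_endpoint = "OS", primary_significant = TRUE)
    ),
    non_ici_like = list(
      config = cure_config(
        n_per_arm = n_per_arm,
        cure_fraction_test = 0, cure_fraction_control = 0,
        event_rate_test = 0.09, event_rate_control = 0.12,
        shape = 2, accrual_months = 12, followup_months = 36
      ),
      metadata = list(therapy_class = "non-ICI", therapy_subclass = "targeted",
                      disease_site = "lung", hematological = FALSE,
                      primary_endpoint = "PFS", primary_significant = TRUE)
    ),
    null = list(
      config = cure_config(
        n_per_arm = n_per_arm,
        cure_fraction_test = 0.15, cure_fraction_control = 0.15,
        event_rate_test = 0.12, event_rate_control = 0.12,
        shape = 2, accrual_months = 12, followup_months = 36
      ),
      metadata = list(therapy_class = "non-ICI", therapy_subclass = "targeted",
                      disease_site = "breast", hematological = FALSE,
                      primary_endpoint = "OS", primary_significant = TRUE)
    )
  )
}

#' Simulate a complete two-arm trial record
#'
#' Draws both OS arms from `config`, both PFS arms from `pfs_config`
#' (defaulting to a scaled OS configuration: event rates doubled, cure
#' fractions halved — progression precedes death and fewer patients are
#' progression-free long-term), estimates all four Kaplan-Meier curves, and
#' assembles a one-row cohort tibble with the preset's framework flags.
#'
#' @param config [cure_config()] for OS.
#' @param trial_id Trial identifier.
#' @param metadata Named list of trial flags (as in [trial_preset()]);
#'   missing entries fall back on the `null` preset's metadata.
#' @param pfs_config Optional [cure_config()] for PFS.
#' @param seed Integer seed for the whole trial.
#' @return A one-row cohort tibble.
#' @export
simulate_trial <- function(config, trial_id = "trial_1", metadata = list(),
                           pfs_config = NULL, seed = NULL) {
  if (!inherits(config, "cure_config")) abort("`config` must be a cure_config")
  if (is.null(pfs_config)) {
    pfs_config <- cure_config(
      n_per_arm = config$n_per_arm,
      cure_fraction_test = config$cure_fraction_test / 2,
      cure_fraction_control = config$cure_fraction_control / 2,
      event_rate_test = config$event_rate_test * 2,
      event_rate_control = config$event_rate_control * 2,
      shape = config$shape,
      accrual_months = config$accrual_months,
      followup_months = config$followup_months
    )
  }
  defaults <- trial_preset("null")$metadata
  meta <- utils::modifyList(defaults, metadata)
  build <- function() {
    arms <- list(
      os_test = simulate_arm(config, "test"),
      os_control = simulate_arm(config, "control"),
      pfs_test = simulate_arm(pfs_config, "test"),
      pfs_control = simulate_arm(pfs_config, "control")
    )
    purrr::map(arms, ~ km_estimate(.x$time_months, .x$event))
  }
  curves <- if (is.null(seed)) build() else withr_seed(seed, build())
  cohort(tibble(
    trial_id = trial_id,
    therapy_class = meta$therapy_class,
    therapy_subclass = meta$therapy_subclass,
    disease_site = meta$disease_site,
    hematological = meta$hematological,
    primary_endpoint = meta$primary_endpoint,
    primary_significant = meta$primary_significant,
    os_reported = TRUE,
    os_obscured_by_crossover = FALSE,
    pfs_reported = TRUE,
    curve_os_test = list(curves$os_test),
    curve_os_control = list(curves$os_control),
    curve_pfs_test = list(curves$pfs_test),
    curve_pfs_control = list(curves$pfs_control)
  ))
}

#' Recipe for a simulated cohort
#'
#' A cohort is a mixture of the three presets. Default weights emulate the
#' 14% ICI / 86% non-ICI therapy-class composition of the FDA-approval trial
#' set the award rules were compared on.
#'
#' @param n_trials Number of trials.
#' @param weights Named mixture weights over
#'   `c(ici_like, non_ici_like, null)`, summing to 1.
#' @param n_per_arm Subjects per arm for every trial.
#' @param seed Master seed; each trial gets a counter-derived substream so
#'   changing `n_trials` never shifts earlier trials' draws.
#' @return A `cohort_recipe` list.
#' @export
cohort_recipe <- function(n_trials = 100,
                          weights = c(ici_like = 0.14, non_ici_like = 0.86,
                                      null = 0),
                          n_per_arm = 500,
                          seed = 1L) {
  if (n_trials < 1) abort("`n_trials` must be at least 1")
  need <- c("ici_like", "non_ici_like", "null")
  if (!all(need %in% names(weights))) {
    weights <- setNames(as.numeric(weights), need[seq_along(weights)])
  }
  weights <- weights[need]
  if (any(is.na(weights)) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    abort("`weights` must be non-negative and sum to 1")
  }
  structure(
    list(n_trials = n_trials, weights = weights, n_per_arm = n_per_arm,
         seed = as.integer(seed)),
    class = "cohort_recipe"
  )
}

#' Read a cohort recipe from YAML
#'
#' Schema: top-level keys `n_trials`, `n_per_arm`, `seed`, and `weights`
#' (mapping of `ici_like` / `non_ici_like` / `null` to numbers).
#'
#' @param path YAML file path.
#' @return A [cohort_recipe()].
#' @export
read_recipe <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_recipe(
    n_trials = y$n_trials %||% 100,
    weights = unlist(y$weights %||% c(ici_like = 0.14, non_ici_like = 0.86,
                                      null = 0)),
    n_per_arm = y$n_per_arm %||% 500,
    seed = y$seed %||% 1L
  )
}

trial_substream_seed <- function(master_seed, i) {
  # counter-based substream: trial i's seed depends only on (master, i)
  (as.double(master_seed) * 48271 + i * 16807) %% 2147483647
}

#' Simulate a cohort of trials from a recipe
#'
#' Each trial's preset assignment and survival draws come from its own
#' counter-derived substream of the master seed, so two runs with the same
#' recipe are identical and changing the cohort size leaves earlier trials
#' untouched.
#'
#' @param recipe A [cohort_recipe()].
#' @return A cohort tibble with `n_trials` rows; `provenance` records each
#'   trial's preset.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_recipe(n_trials = 5, seed = 42))
#' coh$provenance
simulate_cohort <- function(recipe) {
  if (!inherits(recipe, "cohort_recipe")) {
    abort("`recipe` must be a cohort_recipe")
  }
  presets <- names(recipe$weights)
  rows <- purrr::map(seq_len(recipe$n_trials), function(i) {
    seed_i <- trial_substream_seed(recipe$seed, i)
    preset_i <- withr_seed(seed_i, {
      sample(presets, 1, prob = recipe$weights)
    })
    ps <- trial_preset(preset_i, n_per_arm = recipe$n_per_arm)
    trial <- simulate_trial(
      ps$config,
      trial_id = sprintf("sim_%04d", i),
      metadata = ps$metadata,
      seed = (seed_i + 1) %% 2147483647
    )
    trial$provenance <- preset_i
    trial
  })
  cohort(dplyr::bind_rows(rows))
}
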