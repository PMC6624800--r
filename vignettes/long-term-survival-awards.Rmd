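---
title: "Scoring long-term survival benefit: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring long-term survival benefit: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(tailcurve)
library(dplyr)
```

## The problem

A plateau at the tail of a Kaplan–Meier curve indicates a subset of patients
with durable, possibly curative benefit. Hazard ratios and medians summarise
the middle of the survival distribution and can miss that tail entirely, so
two oncology value frameworks added explicit long-term-survival awards: the
ASCO-VF v2 *tail-of-the-curve* (TOC) bonus and the ESMO-MCBS v1.1
immunotherapy-triggered *long-term-plateau* (LTP) adjustments. Both are
binary decision rules over the two arms' survival curves, but they encode
very different operational definitions of "long-term benefit", and on real
trial cohorts they agree barely above chance. This package makes both rules
executable, with per-criterion diagnostics, the agreement statistics used to
compare them, and a simulator whose ground truth is known, so the behaviour
of each rule can be studied quantitatively.

## Curves and their queries

Everything is built on the `step_curve`: a right-continuous survival step
function with an at-risk count at every grid time, a maximum follow-up, and
the enrolled count. Curves come either from raw per-subject follow-up via
`km_estimate()` (the product-limit estimator, fitted with the survival
package; the grid keeps censoring times so risk sets stay queryable along
the whole curve) or from digitised step tables read by `read_curve_tsv()`.
Digitised input is validated, never repaired: survival that rises, unsorted
times or growing risk sets are data errors the user must resolve, because a
"fixed" curve would silently change award decisions.

Three query conventions matter and are applied consistently:

* **Right-continuity.** `survival_at(curve, t)` returns the value *after*
  the step at `t`; before the first grid time survival is 1.
* **No extrapolation.** Queries beyond `max_followup` return `NA`. The
  award rules turn that `NA` into a failed "data extend to the milestone"
  criterion — a trial with immature follow-up cannot earn an award, which
  is precisely how short FDA-registration trials behave under these rules.
* **Median, inclusive at 0.5.** `median_survival()` is the first grid time
  with `S ≤ 0.5`. Because product-limit arithmetic can land an exact ½ a
  few ulp to either side, the comparison carries a `1e-12` guard; the same
  guard is applied at every inclusive award threshold (`≥ 1.5`, `≥ 0.20`,
  `≥ 0.10`), so a ratio that is mathematically exactly 1.5 qualifies
  regardless of floating-point representation.

`rmst(curve, tau)` integrates the step function exactly on `[0, tau]` and
refuses `tau` beyond follow-up: restricted mean survival time is a
within-data summary by definition.

## The plateau detector

ESMO's plateau criterion is qualitative; published applications used
reviewer judgement. The package's operational counterpart,
`detect_plateau()`, declares a plateau when the total Kaplan–Meier drop over
the trailing `window_frac` of follow-up is below `drop_tol` *and* at least
`min_at_risk` patients remain at risk at the window start. Defaults —
window 20% of follow-up, drop tolerance 0.05 absolute, 10 at risk — are a
deliberately conservative reading of "flat tail": a 5-point drop over the
last fifth of a trial is visually flat, and the at-risk guard refuses to
call a plateau on a tail supported by a handful of patients (the same
imprecision concern that motivates ASCO's 20% control floor). All three are
tunable, and the verdict is monotone in `drop_tol` by construction.
Published reviewer or field-testing calls can be injected per trial via the
`plateau_override_*` columns (`manual_plateau()`), bypassing the detector
entirely; the verdict records its `source` either way. When the detector
runs inside `award_ltp()` it runs on the **test-arm** curve: the adjustment
rewards a plateau in the experimental regimen.

## Award rules: readings the algorithms leave open

Both published algorithms leave gaps a software implementation must close.
The choices here, each surfaced as an explicit field in the criteria output:

* **"≥50% improvement in proportion alive" is relative**
  (`S_test ≥ 1.5 S_ctrl`), not an absolute 50-point gain — an absolute
  reading would be nearly unsatisfiable alongside a 20% control floor and
  contradicts the companion ESMO criterion being explicitly absolute.
* **Unreached control median ⇒ TOC criteria unmet**, recorded rather than
  raised: `t2 = 2 × median` cannot be formed. For the ESMO milestone branch
  the analogous case routes to the *longer* milestone (84 / 24 months),
  since an unreached median exceeds observed follow-up.
* **PFS fallback after a failed OS evaluation** is enabled by default (the
  published rule that "when both OS and PFS criteria are met, only the OS
  bonus is awarded" presupposes both can be checked); `os_strict = TRUE`
  disables it for sensitivity analysis.
* **Coprimary OS+PFS trials route to the OS form** in the ESMO endpoint
  selection — OS is the stronger endpoint — overridable per trial via
  `ltp_form_override`.
* **"OS advantage" is a strict inequality** at the milestone, with no
  significance requirement, and the milestone boundaries (≤ 12, ≤ 6 months)
  are inclusive.
* The downstream ESMO grade computation (forms, letter grades) is out of
  scope; `os_curative_scoring` is a terminal award kind, because the
  comparison of interest is binary award/withhold.

## Agreement statistics

`build_concordance()` restricts the 2×2 table to *dual-eligible* trials —
those the ESMO rules may assess at all (significant primary endpoint,
non-hematological agent); the ASCO side has no gate. On the table,
`glance()` reports percent agreement, Cohen κ with the large-sample
(Fleiss–Cohen–Everitt) variance for the CI and the null-variance SE for the
test, and the McNemar χ² on the discordant cells, uncorrected by default
(a continuity correction sits behind a flag). Risk differences between
therapy classes use the unpooled Wald standard error for both the interval
and the default test, which reproduces published intervals at printed
precision. No multiplicity adjustment is applied anywhere. Note that the κ
confidence-interval method in published comparisons is often unstated;
point estimates, not CI bounds, are the comparable surface.

## The simulator: what it emulates, and what it does not

`simulate_arm()` draws from a mixture cure model: with probability π the
subject is a long-term survivor (event time `+∞`); otherwise the event time
is Weibull with rate λ per month and shape k (`k = 1` exponential), so

$$S(t) = \pi + (1-\pi)\,e^{-(\lambda t)^k},$$

and the plateau height *is* π — which is why KM tail heights recover cure
fractions in the validation suite (within 0.03 at n = 5000 per arm across
20 seeds). Accrual is uniform over `accrual_months`; censoring is purely
administrative at study closure. Units are months throughout;
year-denominated milestones convert at 12 months/year.

Three presets define the study conditions:

* `ici_like` — π 0.40 vs 0.25, λ 0.08 vs 0.15/month, shape 2, 500 per arm,
  12-month accrual, 36-month follow-up. The test arm gets *both* a higher
  cure fraction and slower latency among non-cured patients, the pattern
  checkpoint-inhibitor trials actually show. The latency gain matters for
  the decision-rule arithmetic: with a shared latency the survival ratio at
  `t2 = 2 ×` control median is pinned at
  `(π_t + (1-π_t)q) / (π_c + (1-π_c)q)`, where the median relation fixes
  `q = S_0(t2) = 3^{-2^k}` for a control cure fraction of 0.25 — giving a
  ratio of ≈ 1.4–1.6 for these cure fractions regardless of λ — too
  close to the 1.5 cutoff for reliable finite-sample awards. With the
  latency gain the asymptotic ratio is ≈ 2.2 and the control floor sits at
  ≈ 0.26, so the bonus is awarded in essentially every replicate at
  n = 500.
* `non_ici_like` — no cure in either arm, proportional-hazards-style
  benefit (λ 0.09 vs 0.12, shape 2). The sharpened Weibull tail drives
  control survival at `t2` to `e^{-2^k \ln 2}` ≈ 0.06, far below the 20%
  floor: the classic way conventional agents miss the bonus. (With
  exponential latency the control tail at `t2` is exactly
  `e^{-2\ln 2} = 0.25` and would pass the floor marginally — the shape
  parameter is what makes this preset a clean negative.)
* `null` — identical arms (π 0.15, λ 0.12, shape 2); any award is a false
  positive of the rule.

`simulate_trial()` adds a PFS endpoint (independent of OS; default config:
rates doubled, cure fractions halved — progression precedes death) and the
preset's framework flags. `simulate_cohort()` mixes presets with default
weights 14% / 86% / 0%, matching the ICI share of the FDA-approval trial
cohorts these rules are usually applied to, and derives one substream per
trial from the master seed with a counter scheme, so enlarging a cohort
never changes earlier trials' draws.

```{r}
coh <- simulate_cohort(cohort_recipe(n_trials = 10, n_per_arm = 200, seed = 7))
score_asco(coh) |> count(therapy_class, awarded)
```

What the simulator does **not** emulate: dependent OS/PFS endpoints (they
are drawn independently), dropout or loss to follow-up (censoring is purely
administrative), delayed treatment-effect onset or crossing curves,
digitisation noise in curve tables, and reviewer variability in plateau
calls. Passing tests on simulated cohorts therefore demonstrate that the
decision rules implement their stated criteria and separate designed effect
patterns — not that either framework is well calibrated on real, messier
trial data.

ESMO awards are structurally rare under these presets: the OS milestone (5
or 7 years) exceeds the simulated 3–4 years of follow-up, so
`data_extends_to_t_eval` fails — mirroring the immature-data limitation of
real registration trials. Scenarios meant to exercise the ESMO path should
set `followup_months` of 60+ or supply plateau/milestone-reachable curves
directly.

## Problem sizes and numerical checks

The validation suite runs at sizes chosen to keep Monte-Carlo error an
order of magnitude inside each tolerance: curve-level closed-form checks at
4000–5000 subjects per arm; cure-fraction recovery at n = 5000 over 20
seeds against a 0.03 band (binomial SE ≈ 0.007); the award-rule
discrimination check at 100 replicates of 500-per-arm trials (ICI-like
award rate ≥ 95%, null ≤ 5%); and scorer-versus-brute-force agreement on
500 randomly generated small trials spanning reported/unreported endpoints,
crossover, overrides and eligibility flags. Determinism is enforced by
per-call seeds; the acceptance script derives every stream from its
`--seed` argument.

## Known limitations

* The plateau detector is one reasonable operationalisation of a
  qualitative criterion; its defaults are this package's choice, and
  reviewer-based calls on real trials will not always coincide with it.
* Digitised curves are trusted as given (after invariant checks); no
  smoothing, monotonicity repair, or digitisation-error model.
* No interval censoring, competing risks, or confidence bands on curves;
  the frameworks' rules consume point estimates only.
* Published headline award frequencies from real FDA-approval cohorts
  require the original digitised curves, which are not redistributable
  here; the simulator-based properties are the package's substitute
  evidence.
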