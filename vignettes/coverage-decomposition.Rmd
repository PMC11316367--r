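---
title: "Decomposing primary-care coverage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing primary-care coverage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcoverage)
```

## The accounting model

In a list-based primary-care system, every enrolled patient is either on
some GP's list or unassigned. Per unit $j$ and year, with $n$ enrolled
patients, $GP$ full-time-equivalent (FTE) GPs and average list size
$L = (n - m)/GP$, the number of unassigned patients is the identity

$$m = n - GP \cdot L.$$

This is bookkeeping, not an estimator: there is no sampling error, and the
package treats violations of the identity's preconditions
($0 \le m \le n$; $m = n$ whenever $GP = 0$) as data errors to be rejected,
never repaired silently.

At the micro level the same identity reads $m = n - \sum_i L_i$ over
physicians $i$. An alternative reading weights each list by its
physician's FTE, $m = n - \sum_i FTE_i L_i$; with part-time physicians
this undercounts assigned patients (a patient on a half-timer's list is
still assigned), so the package uses the raw sum by default and exposes the
FTE-weighted variant only for comparison
(`unassigned_from_lists(method = "fte_weighted")`). With the raw sum,
$L_j = \sum_i L_i / \sum_i FTE_i$ makes the unit-level identity exact.

## The three-way decomposition

The change in $m$ between periods 0 and 1 splits exactly into

$$m(1)-m(0) = \underbrace{[n(1)-n(0)]}_{\text{demand}}
 - \underbrace{[(GP(1)-GP(0))\,L(0)]}_{\text{supply}}
 - \underbrace{[(L(1)-L(0))\,GP(1)]}_{\text{productivity}}.$$

Like any index-number decomposition of a product, the interaction term
$\Delta GP \cdot \Delta L$ must be allocated somewhere for the sum to be
exact. The default (`allocation = "list"`) values the workforce change at
the *baseline* list size and the list-size change at the *final* workforce,
allocating the cross term to the list dimension. Two alternatives are
provided for sensitivity analysis: `"gp"` (the mirror-image
Laspeyres/Paasche choice) and `"symmetric"` (the average of the two, a
Marshall–Edgeworth-style split). All three sum exactly to $\Delta m$ and
agree on the total; only the split between supply and productivity moves.

Sign convention: effects are stated as signed contributions to the change
in *unassigned* patients — positive means more patients without a GP. The
data model never flips signs for display.

Three properties are worth keeping in mind (all are property-tested):

- **Telescoping.** Chained yearly totals and chained demand effects sum
  exactly to their long-run counterparts. Chained supply and productivity
  effects are *path dependent* and generally differ from the single
  long-run step; this is expected, not an error.
- **Non-additivity across units.** $\Delta m$ is additive over units, but
  effects computed on aggregated records generally differ from summed
  unit-level effects, because the national $L$ is an FTE-weighted mean.
  Both views are legitimate; the package computes whichever the caller
  asks for and never mixes them.
- **Degenerate endpoints.** If $GP = 0$ at either endpoint, $L$ is
  undefined and the decomposition aborts with a classed error rather than
  imputing a list size, which would silently corrupt the attribution.

Relative shares (`relative_shares()`, `decompose_all()`) normalise by the
sum of absolute effects so the three unsigned shares always add to 100%
even when signs are mixed, with the signs carried as metadata; the last
share is set by complement so the sum is exactly 100. Per-unit tables are
ordered by the change in the *percentage* of patients without a GP
($m_1/n_1 - m_0/n_0$), each scope using its own enrolment denominator.

## Workforce arithmetic

**FTE.** `fte_from_hours()` divides effective weekly hours by the 40-hour
standard week. It is uncapped by default (a 60-hour contract counts 1.5
FTE) because the standard defines only the denominator; a cap is available.
The December 2023 national pair — 6 934 GPs employed, 5 395 FTE — gives a
computed FTE/headcount ratio of 77.8%; the package always reports ratios
computed from the data it is given rather than published constants.

**Weighted patient units.** `weighted_units()` risk-adjusts list sizes by
age: 1.5 for ages 0–6, 1.0 for 7–64, 2.0 for 65–74, 2.5 for 75+, with the
regulatory reference list of 1 917 weighted units exposed as the constant
`WEIGHTED_UNIT_LIST_CAP` (context only; the cap is not modelled as a
constraint). Bands are closed integer-age bands; assigning patients to
bands by age at a reference date is the caller's responsibility.

**Required additional workforce.** If weighted units per enrolled patient
rise from $w_0$ to $w_1$, holding weighted workload per FTE constant needs
$GP \cdot (w_1/w_0 - 1)$ extra FTE. For the 1.24 → 1.32 shift observed
over 2009–2023 at the 2023 workforce this is
`r round(required_additional_gps(5395, 1.24, 1.32), 1)` FTE — note that
1.32/1.24 − 1 is a 6.45% increase, and the package uses the computed
ratio throughout.

## The synthetic panel generator

Real coverage panels come from administrative dashboards that cannot be
redistributed, so the generator (`generate_panel()`) produces panels with
the statistical structure the analysis assumes, calibrated to the public
national anchors. The default scenario emulates mainland Portugal
2009–2023: 55 units in 5 regions, 11.3 million enrolled patients in 2009
with a baseline unassigned share of 15.8%, enrolment declining to 2016 —
including a one-off purge of ~7% of records between 2012 and 2013, when
inactive registrations were removed — then growing; FTE workforce
declining to 2014, recovering to 2018, dipping in 2019, and falling in
2021–2022; and average list size drifting down 0.3%/year from a mean of
1 680 patients per FTE.

Design choices that matter for interpretation:

- **The identity is never sampled away.** Unassigned counts are always
  derived as $m = n - \mathrm{round}(GP \cdot L)$ and clamped at full
  coverage ($m \ge 0$); the list size is implied by the stored integer
  counts, so every generated record satisfies the identity exactly.
- **National trends are exact; noise lives in unit shares.** Unit-year
  values are drawn around the trend with 2% relative noise and then
  rescaled within each year so the national enrolment and FTE series
  follow the configured piecewise multipliers exactly. This makes the
  sign pattern of national yearly effects a deterministic function of the
  configured segments, which is what the generator's contract tests
  verify; the unit level keeps realistic heterogeneity (log-normal unit
  sizes — administrative units are right-skewed — and logit-spread
  baseline coverage).
- **Covariates via a controlled copula.** Unit-level latent traits give
  elderly share and diabetes prevalence moderate negative target
  correlations (−0.45) with the list ratio and population density a weak
  one (−0.20); the latents are constructed with *sample* correlations
  hitting the targets exactly, so the achieved panel correlations land
  within a few hundredths of target at 55 units rather than merely in
  expectation. Elderly share is derived from the generated age-band
  counts, keeping covariates and age mix coherent.
- **Age mix.** Band shares interpolate linearly between mixes solved to
  give exactly 1.24 weighted units per patient in the first year and 1.32
  in the last, so the national path is monotone by construction; counts
  are apportioned to integers by largest remainder so bands always sum to
  enrolment.
- **Exact single-driver mode.** `scenario_single_driver()` freezes all but
  one driver, switches noise off and uses integer baseline FTE with a
  common integer list size, so that integer rounding cannot leak change
  into inactive dimensions: parameter-recovery tests can assert effects of
  *exactly* zero, not merely small.

What the generator does **not** emulate: the FHU/PHCU organisational split
and its payment incentives, true within-region heterogeneity (the defaults
are invented, plausible values), spatial structure, and any unit-level
feature of the real series beyond the qualitative trend shapes and
national anchors. Passing tests on synthetic panels therefore demonstrate
the correctness of the arithmetic and the pipeline, not fidelity to any
particular country's microdata.

## Numerical choices

- Counts are integers; FTE is real (hours-derived) and written to CSV at
  full double precision, so read/write round-trips are bit-exact.
- The exact-sum invariant is asserted at 1e-9 relative tolerance; observed
  residuals are ~1e-11 even at multi-million counts.
- Presentation rounding is half-away-from-zero (`round_half_up()`),
  applied only at presentation; internal values stay at full precision
  (e.g. the 2023 coverage pair is 83.81% / 16.19% internally, printed
  83% / 16.5% style figures are presentation artefacts).
- Pearson is the default correlation (conventional for "moderate/weak"
  descriptive tables); Spearman is available.
- Largest-remainder apportionment breaks ties by first occurrence.

## Problem sizes

The test suite and the acceptance script run, per invocation: 10 000
randomized record pairs × 3 allocation conventions for the identity check;
50 randomized 15-year series for telescoping; three 10-unit single-driver
scenarios for recovery; and one 55-unit × 15-year default scenario for the
generator contract — a few seconds in total, chosen because the checks are
exact (or controlled by construction) and larger sizes add no information.

## Limitations

The decomposition is descriptive accounting on aggregate administrative
counts: it attributes, it does not explain. Productivity-effect changes
cannot distinguish smaller lists per physician from compositional shifts
(e.g. exits of physicians with large lists) without physician-level data.
Published headline figures derived from unrounded administrative sources
are reproducible only up to the precision of the published aggregates; the
package reproduces the identity and the robust bounds exactly, and treats
finer published figures as unverifiable from public inputs.
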