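---
title: "Age-stage two-sex life tables: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stage two-sex life tables: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agestage)
```

## The estimator

`agestage` fits cohort life tables that are classified by age *and*
developmental stage, with both sexes and all pre-adult deaths kept in the
denominator. The data unit is one insect's complete daily record: stage
code per day from oviposition (age 0, always an egg) to the last day
alive, plus eggs laid per day for adult females. Death is implicit on the
day after a record ends; there is no censoring — every individual is
followed to death.

From the counts `n_xj` of individuals alive at age `x` in stage `j`, the
package computes `s_xj = n_xj/N`, the collapsed schedules `l_x`, `m_x`
and `l_x m_x`, the net reproductive rate `R0 = Σ l_x m_x`, the
Euler–Lotka root `r`, `λ = e^r`, `T = ln(R0)/r`, and the age-stage life
expectancy `e_xj` and reproductive value `v_xj`.

### Conventions that pin the arithmetic down

The classical sources for this family of life tables state the schedules
but leave several indexing conventions open. The package fixes them so
that a set of exact identities holds for *every* cohort, and the test
suite enforces them:

- **Age is 0-based** and the day of oviposition is age 0, so `l_0 = 1`
  exactly.
- **The Euler–Lotka exponent is `x+1`**: `Σ_x e^{-r(x+1)} l_x m_x = 1`.
  With this choice a schedule concentrated at a single age `x` with mass
  `L` gives the closed form `r = ln(L)/(x+1)`, and `v_{0,egg} = λ`
  exactly.
- **`e_xj` counts the current day**, so `e_xj ≥ 1` on every occupied cell
  and `e_{0,egg}` equals the cohort's mean lifespan exactly (a
  brute-force testable identity).
- `m_x` is defined as 0 (not `NaN`) at ages where `l_x = 0`, keeping the
  schedule arrays dense.

`e_xj` and `v_xj` are realised through the cohort's empirical day-to-day
transition fractions (stay in stage, advance one stage — with the
pupa→female/male branch — or die). Unit mass placed on a cell and pushed
forward through those fractions reproduces the occupancy fractions
`n_xj/N` exactly when started from the egg anchor, which is what makes
the `e_{0,egg}` and `v_{0,egg}` identities exact rather than approximate.
The forward propagation is implemented as the equivalent backward
recursion `e[x,j] = 1 + Σ_k P(x,j→k) e[x+1,k]`; a test compares it
against exhaustive enumeration of all transition paths on tiny cohorts.

### Numerical choices

`r` is found by bisection on a bracket expanded from `[-1, 1]` until it
provably contains the root (hard failure outside `[-10, 10]`), to an
absolute tolerance of 1e-12; the sign of `r` always matches the sign of
`ln R0`. Bisection is slower than Newton but cannot diverge and needs no
derivative bookkeeping; a schedule takes ~45 iterations. Ages with zero
maternity are dropped from the renewal sum so that extreme bracket
endpoints cannot produce `0 × ∞`. Cohorts that lay no eggs (`R0 = 0`)
get `r`, `λ`, `T` as flagged `NA` rather than an error or an imputed
value.

## Bootstrap inference

The sampling unit is the individual: each resample draws `N` records with
replacement and recomputes `r`, `λ`, `R0`, `T` from the resampled
maternity schedule — the same schedule→parameter code path the point
estimate uses, skipping only the `e_xj`/`v_xj` matrices that no scalar
parameter depends on. Resamples with `R0 = 0` leave `r`, `λ` and `T`
undefined; they are flagged, counted and excluded from the mean/SE (with
a warning) rather than imputed, so users see estimator instability
directly. All resample indices are drawn up-front from one seeded
generator: results are bit-identical given `(cohort, B, seed)` and the
caller's RNG state is untouched. The default `B = 10000` matches common
practice for these tables; tests and the examples use `B = 1000`.

Two-group contrasts use a Welch-style statistic on the bootstrap means
with a normal reference — `B` is large, so no arbitrary
degrees-of-freedom choice is imposed. Multi-group contrasts use
Tukey–Kramer: `q = |mean_i − mean_j| / sqrt((se_i² + se_j²)/2)` referred
to the studentized range with `k` means and `B − 1` df, with a compact
letter display assigned greedily from the largest mean. Note that with
four groups the 5% critical `q` is ≈ 3.6: group pairs whose means differ
by less than ~2.5 pooled SEs will legitimately share a letter, so letter
displays on small cohorts are coarser than the underlying ordering.
Groups are always resampled independently of one another.

## The synthetic cohort generator

`generate_cohort()` emulates a serial-inbreeding experiment on the
diamondback moth: cohorts of fresh eggs monitored daily through egg,
larval and pupal development, adult emergence, pairing and daily egg
counts, for a sib-mated line and an outbred control line at generations
1, 4, 7 and 10. The generative model is:

- **Stage durations**: discretized gammas on the integers ≥ 1 (unit bins
  of a gamma with mean `dur_mean − 0.5`; `dur_disp = 0` gives a fixed
  duration). Dispersions are not published for the emulated experiment,
  so all presets use SDs of 0.6/1.2/0.8 d (egg/larva/pupa), typical
  laboratory spreads for a ~2.5/7/3.5 d development.
- **Mortality**: hatching is a Bernoulli draw at the end of the egg
  stage; the remaining egg-to-adult mortality is applied as constant
  daily hazards inside the larval and pupal stages, calibrated
  numerically (to 1e-14) so that overall egg→adult survival equals the
  configured `preadult_p`. The larva/pupa split of that mortality is not
  published; 80% of the log-mortality is assigned to the larval stage —
  an assumption, chosen because larvae are the stage most exposed to
  environmental insult — and the split is a config field
  (`larva_frac`).
- **Adults**: sex is Bernoulli(`sex_ratio`) at emergence; longevity is
  1 + geometric with the configured mean (memoryless adult mortality).
- **Fecundity**: a female's lifetime total is Poisson(`F_mean`),
  allocated multinomially over her alive days by a discretized gamma
  kernel whose cohort-age mode is `ovi_peak_day`. The kernel is
  truncated at death and renormalized, so the realized mean eggs per
  female equals `F_mean` regardless of longevity — matching how
  per-female fecundity is tabulated in such experiments (it is the mean
  over observed females, not a rate net of early death).

`analytic_schedule()` computes the *exact* expected `l_x` and `l_x m_x`
under this model by convolving the duration pmfs, hazards, sex split,
longevity and kernel (the generator samples from the identical pmfs), and
the analytic `r` from the expected maternity schedule. The analytic
`R0 = sex_ratio · preadult_p · F_mean` is closed-form because of the
kernel renormalization. This is the recovery oracle: empirical schedules
of large generated cohorts must converge to these curves, and estimated
`r` of an `n = 2000` cohort must land within 3 Monte-Carlo SEs of the
analytic `r` for every preset.

### Preset calibration

The presets anchor on the emulated experiment's published summaries:
stage-duration means, adult longevities and per-female fecundity per
line × generation; hatch peaks (outbred ≈ 0.94 throughout; inbred
declining 0.97 → 0.67 → 0.53 → 0.15); egg-to-adult survival (outbred
≈ 0.88; inbred 0.55 in F1 falling to 0.12 in F10); oviposition peaks at
cohort age ~13 d (outbred) versus 14–18 d, progressively delayed
(inbred); and cohort sizes of 70 (outbred) and 120 (inbred) started eggs.

Two quantities are not published and are package calibration choices,
made once:

- inbred F4/F7 egg-to-adult survival is interpolated monotonically
  (0.40, 0.32) between the published F1 and F10 values;
- the **sex ratio** of each preset is back-solved from the published net
  reproductive rates via `R0 = sex_ratio · preadult_p · F_mean`, giving
  values between 0.37 and 0.50. A fixed 50:50 ratio cannot reproduce the
  published `R0` set from the published survival and fecundity — the
  three summaries are mutually inconsistent under it — so the sex ratio
  is treated as the free, unpublished parameter.

One published row is internally inconsistent as printed (the inbred F10
parameters pair `r = 0.011` with `λ = 0.984`, although `λ = e^r` forces
`λ ≈ 1.011`); the package does not use that row for λ-identity
validation and makes no attempt to "fix" it.

### What the generator does and does not emulate

It reproduces the *shapes* that matter for the estimator: overlapping
stage occupancy curves, generation-wise collapse of hatch/survival/
fecundity, delayed and flattened inbred oviposition peaks, two-sex
bookkeeping with pre-adult deaths. It does **not** model genetics (no
loci or inbreeding coefficients — presets encode phenotypic consequences
only), egg-to-egg overdispersion of fecundity (Poisson totals are
underdispersed relative to real females), senescent adult mortality
(geometric longevity is memoryless), or correlations between development
speed and survival. Tests passing on synthetic cohorts therefore
demonstrate correctness of the estimator and calibration of the
bootstrap, not biological realism of every moment of real data.

## Problem sizes used by the test suite

Desk-scale checks run on a 4-individual hand fixture with known exact
values (R0 = 10, mean lifespan 6.25 d, grid-searched `r`). Property
suites use 100 random preset cohorts of 20–50 eggs; parameter recovery
uses 50 replicates per preset at `n = 2000`; bootstrap calibration
compares one `B = 1000` bootstrap against the SD across 200 independent
cohorts; coverage uses 120 replicates at `B = 300`; the qualitative
outbred-versus-inbred contrast is checked over 10 seeds per generation
pair at `n = 120`, `B = 1000`, requiring significance in ≥ 90% of seeds
for `r`, `λ` and `R0`. These sizes were chosen to make stochastic bands
(3 SE, or the stated coverage ranges) tight enough to catch real defects
while keeping the suite comfortably re-runnable.

## Known limitations

- No censoring: individuals alive at study end are not representable.
- The empirical transition model permits only stay/advance-one-stage
  moves; unusual observed jumps (e.g. a skipped stage in dirty data) are
  validation errors rather than modelled events.
- Bootstrap comparisons assume independent groups; paired designs are
  not supported.
- The exact `e_xj`/`v_xj` conventions in the literature vary; the ones
  here are chosen to satisfy the exact identities above and are
  documented rather than configurable.
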