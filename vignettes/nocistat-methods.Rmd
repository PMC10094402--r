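---
title: "Methods: phase-wise nociception scoring and parallel-line interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-wise nociception scoring and parallel-line interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nocistat)
```

## The experimental system

The orofacial formalin test injects dilute formalin into a rat's upper lip
and records the time spent face rubbing in fifteen 3-minute bins (45 min).
The response is biphasic: phase 1 (0–9 min, bins 1–3) reflects direct
nociceptor activation, phase 2 (9–45 min, bins 4–15) inflammation and
central sensitization. The package analyses studies in which a
dose-dependent mast-cell stabilizer (cromoglycate, CG) is combined with a
dose-independent, low-efficacy adjuvant (magnesium sulfate, MS), with
groups of n = 6 rats, and in which mast-cell degranulation is scored
histologically alongside the behavior.

## Behavioral statistics

Per-rat **antinociceptive activity** is
$\mathrm{AA\%} = 100\,(C - T)/C$, where $T$ is the rat's phase total and
$C$ the *mean* phase total of the concurrent vehicle (0.9% NaCl +
formalin) group — the "control rubbing time" exists only as a group
quantity, so each treated rat is scored against the vehicle group mean of
its phase. AA% is 100 at complete suppression and deliberately *not*
floored at zero: pro-nociceptive responses (combinations that increase
rubbing) stay visible as negative AA%.

**Percent inhibition** of one drug's effect by the adjuvant is
$\%I = 100 - 100\,\mathrm{AA}_{\text{with}}/\mathrm{AA}_{\text{without}}$,
computed on per-dose group means; values above 100 (reversal) are
returned unclamped. The histological inhibition
$I\% = 100\,(D_c - D_t)/D_c$ on degranulated counts per field shares the
same ratio algebra, and the two are covered by the same scale-invariance
property tests.

Bins are validated at ingestion: exactly 15 per rat, each within
[0, 180] s. Out-of-range values are rejected, never clipped — a 3-minute
bin over 180 s is a data-entry error, not a measurement.

## Dose–response estimation

Log dose–response lines are ordinary least squares of effect on
$\log_{10}(\text{dose})$ (base 10 by pharmacological convention), with
the residual sum of squares and df kept for the pooled-variance tests
downstream. The default fitting unit is the per-rat AA% point (6 per
dose): confidence limits and degrees of freedom need per-subject
replication. Group means with replication weights are accepted.

For a **full-efficacy** drug the ED50 is read directly off the line:
$\mathrm{ED50} = 10^{(50 - a)/b}$, the dose producing a 50% reduction in
time spent in pain behavior. For a **submaximal-efficacy** drug (alone-arm
maximum below 60%), 50% of an asymptote the drug never reaches is the
wrong target, so the asymptote is estimated first from the
double-reciprocal plot: $1/E$ on $1/D$ is exactly linear under the
hyperbolic model $E = E_{\max} D/(D + K)$, with intercept $1/E_{\max}$
and slope $K/E_{\max}$. The reported ED50 is then the half-saturation
dose $K = \text{slope}/\text{intercept}$ — the dose at 50% of the
estimated $E_{\max}$. We take $K$ from the reciprocal fit itself rather
than re-reading 50% off a straight line fitted to the rescaled effects,
because the rescaled hyperbola is not linear in log dose and the re-read
value would miss $K$ even on exact data; the rescaled line is still
fitted and stored (its slope feeds comparisons), and every fit carries a
`method_tag` (`direct` vs `emax_rescaled`) so the convention is explicit.

Effects ≤ 0 are necessarily excluded (with a warning) from reciprocal
fits, whose transform is undefined there. They are *kept* in plain
log-dose line fits: negative AA% is legitimate data on the linear scale,
and excluding it would bias ED50s upward and distort interval coverage.

## Interaction analysis: parallelism, relative potency, verdict

The combination question is answered by comparing the alone and
combination log dose–response lines.

1. **Parallelism pretest.** Extra-sum-of-squares F comparing
   `effect ~ x * arm` against `effect ~ x + arm` on the pooled data
   (α = 0.05). Only parallel lines have a well-defined horizontal
   displacement; if parallelism is rejected the verdict is
   `indeterminate-nonparallel` and the ratio is withheld.
2. **Relative potency.** Under the common-slope model the log potency
   ratio is $M = (a_{\text{alone}} - a_{\text{combo}})/b$ and the ratio
   $R = 10^M$. The direction convention is stated in every report:
   $R > 1$ means the combination needs *more* cromoglycate for equal
   effect (rightward shift, antagonism trend).
3. **Fieller limits.** $M$ is a ratio of two correlated normal estimates,
   so its confidence limits come from Fieller's theorem with the pooled
   residual variance and the t quantile at the pooled df. When Fieller's
   $g = t^2 v_{bb}/b^2 \ge 1$ the slope is too imprecise to bound the
   ratio and the interval is reported unbounded — it degrades gracefully
   instead of exploding. The delta method was rejected by design: a
   published interval like 0.50–139.12 around a point estimate of 2.40 is
   the signature of a Fieller interval at small df, not of a symmetric
   normal approximation. In the zero-noise limit $g \to 0$ and the
   interval collapses onto the point estimate.
4. **Verdict.** A significant leftward shift (CL entirely below 1) is
   synergy; a significant rightward shift antagonism; limits overlapping
   1 mean the shift is not statistically significant and the interaction
   is classified additive. The *direction* of the point shift is always
   reported separately as `trend`, so a right-shifted ratio of 2.40 with
   limits spanning 1 reads "trend antagonism, verdict additive, not
   significant" — exactly the shape of conclusion the underlying study
   drew for its phase-1 combination.

Under the parallel model the identity
$\mathrm{ED50}_{\text{combo}} = R \times \mathrm{ED50}_{\text{alone}}$
holds exactly, and `fixed_dose_analysis()` checks it on every run. No
two-axis isobologram is constructed: the adjuvant is dose-independent and
has no ED50 of its own, so the line-shift analysis *is* the isobolographic
comparison this design admits.

## Inference machinery

Group comparisons use a two-way mixed-design ANOVA (treatment between,
bin or phase within, rat nested in treatment as the error stratum),
implemented on `stats::aov` with an `Error(rat)` stratum and restricted to
balanced layouts — an unbalanced design raises an explicit error rather
than a silent approximation. Sphericity corrections are off by default
(mirroring the source analysis); `gg_correction = TRUE` adds
Greenhouse–Geisser-corrected p-values alongside the uncorrected ones.
Post hoc comparisons are Tukey HSD via the studentized range
(`stats::ptukey`) with the pooled within-group variance; the
implementation cross-validates against `stats::TukeyHSD` in the test
suite. Pearson correlations between degranulation and pain use the t
transform with n − 2 df; at the study's n = 6, |r| must exceed ≈ 0.811
for p < 0.05, which the tests verify against the t distribution.

Because the behavioral and histological cohorts are separate animals,
correlation pairing is configurable: by shared rat id (unmatched rats
dropped with a warning) or by within-group position — the study itself
does not state how its cohorts were paired, so both modes are exposed and
the position mode is used in the worked analysis.

## The synthetic-data generator

`scenario_config()` fixes the study conditions; all defaults were chosen
once, against the published summaries, and are documented here.

* **Control time course.** The study publishes no numeric template
  (figures only), so the default is a plausible biphasic course — burst
  bins of 45 and 40 s, a quiescent bin, then a plateau rising to 30 s and
  decaying — with phase totals of 95 s (phase 1) and 250 s (phase 2). All
  calibration statements are on the AA%/ED50 scale and do not depend on
  the template's absolute seconds.
* **Cromoglycate curve.** Emax-type per phase,
  $E(d) = E_{\max} d^h/(d^h + K^h)$ with $h = 1$ and half-maximal doses
  2.35 / 7.0 mg/kg (the published phase-1/phase-2 ED50s). The phase
  Emax values (56.5% and 95.5%) are back-solved so the expected effect at
  30 mg/kg reproduces the published maxima of 52.4% (phase 1) and 77.4%
  (phase 2); phase 1 is submaximal (< 60%), which exercises the
  double-reciprocal route.
* **Magnesium.** Dose-independent: 40% in phase 2 (published ≈ 41.8/40.0%
  at both doses), 0 in phase 1, where the published effect was not
  statistically significant.
* **Interaction modes.** `null` leaves the effective CG dose unchanged;
  `potentiate`/`inhibit` multiply/divide it by (1 + magnitude) when MS is
  present — `inhibit` with magnitude 1 halves the potency, i.e. an exact
  2× rightward shift of the curve in log dose.
* **Noise.** Multiplicative lognormal per bin, mean 1, CV 0.25, truncated
  to [0, 180] s: rubbing times are nonnegative and right-skewed. This CV
  makes per-rat phase-2 AA% scatter about 4–5 points at moderate effects,
  matching the published group SDs (± 4.0/4.2 at ≈ 40% effect). An
  additive-normal mode exists for ANOVA calibration work. A consequence
  worth knowing: multiplicative noise makes sd(AA%) proportional to
  (100 − E), i.e. heteroscedastic across doses, whereas the published SD
  at 77% effect (± 3.7) suggests the real data had a noise floor; no
  CV-parameterized multiplicative model can reproduce both anchors at
  once.
* **Mast cells.** Per-field totals are Poisson around group × time means
  (naive 212/HRF; formalin reduces totals, by 43.9% at 24 h relative to
  vehicle); degranulated counts are binomial within each field's total
  (naive rate 3/212), with formalin multiplying the degranulation rate
  8-fold and magnesium pretreatment cutting the *expected degranulated
  count per field* by 23% / 40% / 0% at 5 min / 25 min / 24 h — the
  inhibition acts on counts, as the published effect is stated, so the
  measured I% matches the configured value in expectation even where
  magnesium also changes the totals. `degranulated ≤ total` holds by
  construction.
* **Determinism.** Every rat draws from a counter-based sub-stream keyed
  by (seed, group label, rat index): regenerating reproduces byte-identical
  CSVs, adding a group never perturbs existing groups' draws, and the
  caller's RNG state is untouched.

What the generator does *not* emulate: session-to-session drift, litter
or cage effects, observer scoring error, the noise floor at high effect
noted above, and any pharmacokinetic time structure within a phase.
Passing tests therefore demonstrate the statistical machinery on data
with the assumed structure, not robustness to every feature of real
behavioral data.

## Operating characteristics (simulation sizes used)

The test suite and `scripts/acceptance.R` measure, at these problem
sizes:

* ED50 recovery at the study size (6 rats × 3 doses), 200 cohorts:
  median |relative error| ≈ 10%, within the 20% design bound.
* Fieller coverage of a true 2× shift, 1000 replicates of 3 doses × 6
  per arm at σ = 8: ≈ 95%.
* Type-I error of the parallelism F (homoscedastic null) and of the
  RM-ANOVA treatment test, 1000 replicates each: ≈ 5%.
* Verdict behavior, 200 null-scenario runs and 120 power runs per n.

Two findings deserve honesty rather than a green checkmark. First, under
the default generator the null-scenario "additive" rate is ≈ 86–88%, not
≥ 90%: the heteroscedasticity of AA% described above gives the OLS
parallelism pretest a true size near 11%, so ≈ 12% of null runs end
`indeterminate-nonparallel`. This is a property of the modelled noise
interacting with a classical homoscedastic test, and we report it as
measured. Second, under the Emax-curved `inhibit` mode, growing n makes
the *nonparallel* verdict dominate rather than antagonism: a log-shifted
hyperbola sampled at three fixed doses genuinely differs in local slope,
and the pretest detects that lack-of-fit ever more reliably. The study
itself met the same wall — three of its four combination comparisons
ended "lines are not parallel, interaction is not possible to
determine". Antagonism power is therefore demonstrated on constructed
parallel-line arms, where it cleanly grows with n.

## Numerical choices and degenerate inputs

Zero-residual fits are legal throughout (exact data collapse intervals to
points; identical arms give F = 0, p = 1); noise-free unequal slopes
report p = 0 with a degeneracy flag rather than NaN. Effects above 100%
are rejected as AA values; doses must be positive for any log fit; a
slope of zero makes the ED50 undefined (error, not Inf). ANOVA effects
with zero sum of squares report F = 0, p = 1. Fieller discriminants are
floored at 0 against rounding. ED50s outside the fitted dose range are
flagged extrapolated. All tolerance constants live next to the code they
guard.
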