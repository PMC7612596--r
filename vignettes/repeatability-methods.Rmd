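---
title: "Quantifying SUV repeatability in healthy tissue: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying SUV repeatability in healthy tissue: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suvrepeat)
```

## The problem

When FDG-PET is used to monitor treatment effects, a change in a tissue's
standardized uptake value (SUV) is only meaningful if it exceeds what two
scans of the *same untreated* tissue would show. suvrepeat quantifies that
measurement noise for healthy thoracic tissues — mediastinal blood pool
(MBP), left-ventricular myocardium (LV), bone marrow (BM), skeletal muscle
and six lung zones — for the three SUV summaries in routine use
(`SUVmax`, `SUVmean`, `SUVpeak`), in two arms:

* **test-retest**: the same observer measures two scans acquired a few
  days apart with no interval treatment;
* **interobserver**: two observers measure the same scan.

## From counts to SUV

A PET volume stores activity concentration $C$ in Bq/mL. The body-weight
SUV divides by the decay-corrected injected dose per gram:

$$\mathrm{SUV} = \frac{C}{D \cdot 2^{-t/T_{1/2}} / (1000\,W)},$$

with $D$ the injected activity in Bq, $t$ the uptake time
(injection to scan start, minutes), $T_{1/2} = 109.77$ min for F-18 and
$W$ the weight in kg (1 g of tissue taken as 1 mL). `activity_to_suv()`
implements exactly this; the chronology and positivity of the metadata
are validated rather than assumed.

Regions are sampled the way the clinical protocol describes: a 15 mm
diameter sphere for MBP, LV, BM and muscle, a drawn voxel mask for the
lung zones (with lower-lung masks required to stay 20 mm clear of the
liver, `validate_lung_roi()`). A voxel belongs to a sphere iff its
*center* is inside (`voxelize_sphere()`); partial-volume weighting is
deliberately not modelled — the rule is deterministic and
translation-equivariant on the grid, and any weighting scheme would be a
convention of ours rather than of the workstation software such
protocols are executed on.

`SUVpeak` is not defined consistently across vendors. We adopt the
common clinical convention: the mean inside a 12 mm diameter sphere
(about 1 cm³), centered in turn at every region voxel, maximized over
placements. The peak sphere may extend beyond the region (peak is a
neighbourhood property) but not beyond the volume; placements that would
protrude outside the grid are skipped, and a region where no placement
fits raises a degenerate-peak error rather than silently clipping. The
diameter is a parameter (`peak_diameter_mm`) for sites that use 15 mm.

Negative voxel values, which iterative reconstruction can produce in
low-uptake lung, are counted and retained: clamping them to zero would
bias `SUVmean` upward exactly where the measurement is most fragile.

## The repeatability model

SUV measurements are treated as log-normal, so the analysis works on
per-subject log differences
$d_{\ln} = \ln(\mathrm{SUV}_2) - \ln(\mathrm{SUV}_1)$. With
$s = \mathrm{SD}(d_{\ln})$ (sample SD, $n-1$ denominator):

* within-subject SD: $w\mathrm{SD}_{\ln} = s/\sqrt{2}$, because a
  difference of two independent errors inflates the SD by $\sqrt 2$;
* within-subject coefficient of variation:
  $w\mathrm{CV}\% = (e^{w\mathrm{SD}_{\ln}} - 1)\times 100$;
* 95% repeatability coefficients:
  $RC_{\ln} = \pm 1.96\,s$, back-transformed to the asymmetric percent
  bounds $RC = (e^{\pm RC_{\ln}} - 1)\times 100$.

The bounds satisfy $(1 + RC^+/100)(1 + RC^-/100) = 1$ exactly, and the
round-trip identity
$RC^+ = \big((1 + wCV/100)^{1.96\sqrt 2} - 1\big)\times 100$ links the
two summaries; both are asserted to machine precision in the tests.

Confidence intervals for the RCs use the chi-square sampling
distribution of a normal SD:
$s\sqrt{(n-1)/\chi^2_{1-\alpha/2,\,n-1}} \le \sigma \le
 s\sqrt{(n-1)/\chi^2_{\alpha/2,\,n-1}}$,
propagated through the (monotone) exponential maps, so the propagation
is exact. Degrees of freedom are $n - 1$ on $\mathrm{SD}(d_{\ln})$.

Bias is tested with a paired t-test on $d_{\ln}$ (the scale of the
model), with the original-scale t reported as a secondary column since
both scales appear in practice; the Wilcoxon signed-rank test on the
original-scale differences guards against non-normality (exact null for
$n < 25$; zero differences dropped, ties mid-ranked under the
continuity-corrected normal approximation). Normality of $d_{\ln}$ is
screened with Shapiro–Wilk. Proportional bias is the Pearson
correlation of difference versus mean on both scales (equivalent to
testing the regression slope — the two phrasings are one test, which is
why only one is implemented); heteroscedasticity is Kendall's tau-b of
|difference| versus mean, tau-b because printed SUV tables are rounded
and contain ties. All p values are two-sided, and the 11 × 3 family of
bias tests is Bonferroni-controlled: $0.05/33 \approx 0.0015$. Trend
tests are reported unadjusted against the same corrected threshold.

Reports round wCV and RC to two decimals and p values to three.

### Degenerate inputs

* all-zero differences: Wilcoxon and Shapiro–Wilk are reported as
  not-applicable (`NA`), the t-test bias p as 1;
* a zero-variance axis makes a correlation not-applicable, never an
  error;
* a tissue with fewer than 2 complete pairs yields a row of `NA`
  statistics plus a warning, keeping the report shape stable;
* nonpositive SUVs are a hard error naming the subject and tissue: the
  log model cannot absorb them silently.

## The synthetic cohort

`generate_cohort()` draws from the model the analysis assumes:
subject-level true log-SUV $\sim N(\ln g_o, \sigma_{b,o})$ per organ ×
metric, per-scan observation $\exp(\text{truth} + N(0, w_o))$ with
$w_o = \ln(1 + wCV_o/100)$, and observer 2 re-measuring observer 1's
value times $e^{N(0, j_m)}$. The default configuration
(`inst/extdata/default_cohort_config.json`) emulates a 22-patient
thoracic cohort: geometric-mean SUVs around 1.6–2.2 for MBP/BM, 2.5–4
for LV, 0.45–1 for muscle and lung; between-subject log-SDs of
0.15–0.25 (0.6 for the notoriously variable LV); per-organ wCVs spanning
roughly 10–70% as published healthy-tissue panels do; observer jitter
chosen so the implied interobserver wCV sits near 7% for `SUVmean` and
15–18% for `SUVmax`; and exclusions of 4 LV subjects (field of view) and
1–4 subjects per affected lung zone (disease involvement), so the
analysed $n$ varies by tissue exactly as in real cohorts. These numbers
are illustrative defaults describing the simulator, not any patient
dataset.

Truths are drawn independently per organ × metric; cross-metric
correlation within an organ (a hot subject is hot in all three metrics)
is *not* modelled, which is irrelevant for the per-family statistics the
package computes but means the simulator should not be used to study
joint behaviour across metrics.

`generate_phantom_pair()` supplies the voxel-level counterpart: uniform
ellipsoidal compartments on a 2 mm grid, a per-compartment
multiplicative log-normal factor drawn independently per scan (so the
log-difference SD across subjects is $\sqrt 2\,\ln(1+wCV/100)$, matching
the measurement-level model), optional additive Gaussian voxel noise,
and metadata (75 kg, 300 MBq, 67 min uptake) chosen so SUV conversion
recovers the target exactly. It does **not** emulate scanner physics:
no point-spread function, no partial-volume blur at compartment edges,
no respiratory motion, no anatomically realistic shapes. Passing tests
on these phantoms therefore validate the *bookkeeping and mathematics*
of the pipeline — geometry, conversion, extraction, statistics — not
robustness to reconstruction artefacts.

All randomness in both generators flows from the single config seed
through a private RNG stream; the caller's `.Random.seed` is restored on
exit.

## Validation strategy and problem sizes

The test suite validates each layer against an independent route:

* every reported statistic (t, Pearson, tau-b, exact signed-rank,
  Shapiro–Wilk) is checked against closed forms, $O(n^2)$ pair counting,
  exhaustive $2^n$ sign-flip and $n!$ permutation enumeration, or values
  frozen from a second implementation, at tolerance $10^{-10}$ (an
  exception is Shapiro–Wilk at $10^{-7}$, the agreement level of the two
  implementations of the same published algorithm);
* published healthy-tissue wCV/RC triples (shipped in
  `inst/extdata/reference_repeatability_tables.csv`) round-trip through
  the equations within ±0.05 percentage points for all 66 rows;
* the wCV estimator is validated by parameter recovery at the study
  design point: 22 subjects, true wCV ∈ {5, 10, 30, 65}%,
  2000 replicates per level, requiring < 5% relative bias and 93–97%
  chi-square CI coverage (observed ≈ 1% bias and ≈ 95% coverage);
* SUV triplet extraction is compared bit-for-bit (max/mean) and to
  $10^{-12}$ (peak) against an exhaustive brute force on regions of a
  few hundred voxels, and the full phantom → extraction → analysis
  pipeline recovers per-organ wCV at 200 simulated subjects within
  Monte-Carlo tolerance (3 standard errors ≈ 15% relative).

Simulation sizes (1000–2000 replicates, 200 phantom subjects, 44×44×28
phantom grids) were chosen so the whole suite completes in well under a
minute while leaving Monte-Carlo error far smaller than the acceptance
bands.

## Worked example

```{r example}
cfg <- cohort_config(seed = 7)
meas <- generate_cohort(cfg)
res <- analyze_cohort(meas, "test_retest")
format_summary(res)[1:6, c("tissue", "metric", "n", "mean_diff",
                           "sd_diff", "wcv_pct", "rc_upper_pct",
                           "rc_lower_pct")]
```

A subject whose MBP `SUVmean` changes by more than the upper RC (here
roughly +25–30%) has changed more than scan-to-scan noise explains.
`bland_altman_data()` returns the corresponding plot-ready points and
limit lines on the log axis.

## Known limitations

* No mixed-effects or variance-components extensions; each tissue ×
  metric family is analysed marginally.
* No DICOM rescale handling: volumes must already be in Bq/mL (NIfTI).
* The sphere discretization is a center-inclusion convention; tools
  using partial-volume weighting will differ slightly for small spheres.
* The interobserver arm models observer disagreement as pure
  multiplicative jitter around a shared reading; systematic
  observer-specific bias (one reader consistently larger) is not
  generated, though the analysis would detect it.
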