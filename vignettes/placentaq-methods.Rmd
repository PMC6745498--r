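---
title: "Quantifying placental contrast dynamics, histology and expression changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying placental contrast dynamics, histology and expression changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentaq)
```

## The measurement problem

The syncytiotrophoblast — the multinucleated maternal–fetal exchange layer
of the placenta — exhibits hallmarks of cellular senescence, and attenuating
the senescence programs (p53–p21 and p16–pRb) alters both placental
structure and its function as measured *in vivo*. placentaq implements the
quantification layer for three assay families used to characterise this
biology:

1. **Macromolecular DCE-MRI.** After bolus injection of an albumin-bound
   contrast agent, the mean signal intensity (SI) of a placental region of
   interest follows a biphasic course: rapid enhancement as the agent
   arrives and is internalised by labyrinth trophoblasts, a decline, and a
   late *recovery* as the agent is recycled into the maternal circulation.
2. **Histological quantification.** Percent of syncytia containing
   DAB-positive nuclei, a nine-level semi-quantitative Ki67 proliferation
   rubric, trophoblast fusion indices, and ImageJ-style area-fraction
   quantification of SA-β-gal staining and in situ gelatin zymography.
3. **Expression screening.** A linear fold-change filter for genes
   modulated between early (days 1.5–2) and late (days 3–5)
   syncytiotrophoblast cultures, plus the group-comparison statistics
   (pooled t-test, one-way ANOVA with Tukey HSD) used throughout.

Because the underlying animal and human data cannot be regenerated at desk
scale, every stage is paired with a synthetic-data generator that plants a
known ground truth; the test suite exercises all downstream code against
those planted truths and against independent brute-force oracles.

## The SI landmark statistics

For a curve $\mathrm{SI}(t_k)$ sampled at scan times $t_k$, three landmarks
are located: the first interior local maximum $m_1$, the interior minimum
$m_0$ between the two maxima, and the second maximum $m_2$ in the remaining
tail. The two statistics are

$$E = \frac{\mathrm{SI}(m_1)}{\mathrm{SI}(t_1)}, \qquad
  R = \frac{\mathrm{SI}(m_2)}{\mathrm{SI}(m_0)},$$

the *initial enhancement* and the *recovery*. Both are dimensionless ratios
and therefore invariant under rescaling of the scanner's arbitrary SI
units. The per-interval *rate of enhancement*
$\mathrm{ROE}_k = (\mathrm{SI}_{k+1}-\mathrm{SI}_k)/\Delta t_k / C_{vc}$
(units $\mathrm{min}^{-1}$) scales the SI slope to a vena cava reference
level $C_{vc}$ so curves from different animals are comparable.

### Detection rules and their rationale

* **Baseline = first acquired timepoint.** Acquisition starts at contrast
  administration; there is no pre-injection frame to average.
* **Smoothing.** A centred moving average (default window 3 samples, odd,
  configurable; edges use a shrinking window) is applied *only* for
  locating extrema; the ratios always read the unsmoothed values at the
  detected indices. Measured curves are visibly noisy and a 3-sample window
  suppresses single-sample spikes without displacing an 8-minute-wide
  uptake peak by more than one scan interval.
* **Non-strict maxima, earliest-index ties.** Robust to plateaus produced
  by quantised SI.
* **Interior minimum = global minimum after the first maximum,** not the
  nearest local minimum: the physiological minimum falls roughly mid-window
  and a global search cannot be trapped by a noise dip.
* **The final timepoint is eligible as the second maximum,** because
  recovery is often still rising when the 60–75 min acquisition ends. If
  the *minimum* falls on the final timepoint there is no recovery limb and
  the curve is reported as a failure (`placentaq_no_recovery_limb`);
  monotone or never-enhancing curves fail with
  `placentaq_no_first_maximum`. In cohort analysis these failures are
  first-class rows of a failures table, never silent drops, mirroring the
  real per-placenta variability of the assay.
* **Vena cava reference.** How the scaling concentration is summarised is
  an open choice; placentaq uses the mean of the first three timepoints
  after the vena cava peak — an early-plateau summary that is insensitive
  to the exact peak sample and to late washout.

## The synthetic curve model

The generator produces the noiseless shape

$$S(t) = S_0\Big(1 + A_1\,\frac{t}{t_1}e^{1-t/t_1}
        + \frac{A_2}{1+e^{-r(t-t_0)}}\Big) + \varepsilon_t,
  \qquad \varepsilon_t \sim N(0, \sigma^2),$$

a gamma-variate uptake pulse peaking at $t_1$ plus a logistic recovery
limb. This family guarantees exactly one early maximum followed by a late
rise — the structure the landmark definitions assume — while remaining
smooth enough that ground truth is meaningful. Ground-truth $E$ and $R$ are
computed on a 1000-fold oversampled grid rather than in closed form, so the
truth machinery survives future changes of the curve family.

Default parameters (one placenta, wild-type-like): $S_0 = 100$ signal
units, $A_1 = 0.6$, $t_1 = 8$ min, $A_2 = 0.5$, $t_0 = 45$ min,
$r = 0.10\,\mathrm{min}^{-1}$, $\sigma = 2$ signal units (about 1.5% of the
enhanced signal), and a between-placenta fractional amplitude jitter of
0.10. The uptake timing and amplitudes follow the qualitative course of the
measured curves; the recovery onset and rate are set so that the recovery
limb is still rising at the end of the 67 min 55 s window, as observed — an
early-saturating recovery would leave low-amplitude genotypes with their
global minimum at the final timepoint and hence no measurable recovery at
all. The noise level and between-placenta variability are free parameters
of the generator, chosen as realistic values for this assay class; they are
not estimates fitted to any study's data.

The genotype panel plants a graded loss of the recovery limb: WT
($A_2 = 0.50$), *Cdkn1a* knockout (0.45), *p53* knockout (0.30), *Cdkn2a*
knockout (0.30), and the *Cdkn2a;p53* double knockout (0.10, with uptake
amplitude also reduced to 0.40). The double knockout always carries the
smallest recovery amplitude — the planted analogue of the strongest
measured phenotype.

The acquisition schedule uses an end-of-scan timestamp convention: scan $k$
(of 25, each 2 min 43 s) is attributed time $k \times 163$ s, which makes a
series running "up to 67 min 55 s" arithmetically exact
($25 \times 163 = 4075$ s).

## Histology rules

* **Percent positive syncytia**: a syncytium is positive when it contains
  at least one positive nucleus; the statistic is the percentage of
  positive syncytia per field. Aggregation over fields reports mean ± SEM
  and warns (rather than fails) below 12 fields, since the 12-field minimum
  is a study-design guideline.
* **Ki67 rubric**: scores 0–4 in 0.5 steps. Printed ranges ("5–10%",
  "10–25%", …) are read left-closed/right-open; the only strictly worded
  bin is "more than 75%", so exactly 75% scores 3.5. A fraction of exactly
  0 is "negative staining" (score 0) and any positive fraction below 5%
  scores 0.5, which makes the scale exhaustive over $[0, 1]$.
* **Fusion index**: no formula is in general use for "% fused cells", so
  both candidates are implemented. The default is nuclei-based (percent of
  all nuclei residing in cells with ≥ 2 nuclei), which naturally exceeds
  50% once large syncytia dominate a culture; the per-cell variant
  (percent of multinucleated cells) is selectable.
* **Intensity quantification**: area fraction above a threshold plus mean
  intensity over the (masked) pixels — a deterministic stand-in for an
  ImageJ measurement whose exact recipe (background correction,
  measurement choice) is rarely reported. The default threshold is Otsu's
  method on the masked histogram because it is parameter-free and
  deterministic; a fixed numeric threshold is accepted. A constant image
  has no Otsu threshold and is reported as area fraction 0 with a warning.

## Statistics

`t_test()` is the classical pooled-variance unpaired Student's test
(Welch's variant behind a flag); one-tailed p-values are half the
two-tailed value when the effect lies in the hypothesised direction. Two
degenerate conventions are fixed: zero pooled variance with equal means
gives $t = 0$, $p = 1$; with unequal means the result is flagged degenerate
($p = 0$). `anova_tukey()` wraps one-way ANOVA with Tukey's HSD; perfectly
flat data returns the $F = 0$, $p = 1$ convention. With two groups the
identity $F = t^2$ holds exactly and is enforced by tests.

The fold-change filter works on linear-scale group means with an inclusive
boundary (`FC >= 1.8` or `FC <= 1/1.8`), the documented default among the
underdetermined alternatives (per-replicate vs group-mean, log vs linear);
inclusivity makes reported gene counts reproducible. No multiple-testing
correction is applied to t-tests — matching the analysis conventions this
package reproduces — and none is silently added. Genes with a zero early
mean have no finite ratio and are reported separately rather than dropped.

## What the synthetic data does and does not show

The generators emulate the *structure* the estimators assume: biphasic
curves with genotype-graded amplitudes, Bernoulli nucleus positivity within
fields, two-level staining images with a planted positive-area fraction,
and log-normal expression noise around planted folds. They do not emulate
fetal motion, partial-volume effects, scanner drift, spatially correlated
staining, section artefacts, or probe-level microarray noise. Passing tests
therefore demonstrate correctness of the quantification rules and
recoverability of planted effects under idealised noise — not robustness to
every failure mode of real acquisitions.

Problem sizes used by the checks (the package's own choice of
desk-scale study conditions): oracle-equivalence sweeps use 270 noiseless
parameter combinations spanning the genotype panel's amplitude range;
direction-recovery uses 100 seeded replicates of WT vs double-knockout
cohorts with n = 8 placentas per group at noise SD 0.5; counting oracles
use 500 randomised fields; expression recovery uses 5000 genes with 204 or
50 planted; the end-to-end determinism check runs the full default pipeline
(5 genotypes × 8 placentas, histology, images, 2000 genes) twice.

## Numerical choices and edge cases

* Dense-grid ground truth: 1000× oversampling; landmark equivalence is
  asserted to within one scan interval and ratios to within 2%
  (discretisation of a 163 s grid against a continuous extremum).
* Seeding: every generator is a pure function of (parameters, seed); the
  caller's RNG state is saved and restored. Composite generators derive
  stable per-component sub-seeds (a multiplicative congruential mix kept
  below $2^{31}$), so adding a placenta never reshuffles another's draws.
* Degenerate inputs are classed conditions (`placentaq_config_error`,
  `placentaq_data_error`, `placentaq_degenerate_error`, landmark errors),
  so pipelines can distinguish bad configuration from bad data from
  genuinely featureless curves.
* I/O: tabular formats are plain CSV/TSV with strict schema validation
  naming the offending row/column; floats are written with 6 significant
  digits; images are 32-bit float single-channel TIFF with intensities in
  $[0, 1]$.

## Known limitations

* The ROE vena cava summary and the fusion-index formula are documented
  conventions for under-specified quantities; alternative conventions will
  shift absolute values (not orderings) and both are parameterised.
* Landmark detection assumes one early maximum; pathological curves with
  multiple early peaks of similar height resolve by the earliest-index
  rule, which may not match a human rater.
* Otsu thresholding assumes a roughly bimodal masked histogram; heavily
  skewed staining distributions may need a fixed threshold.
* The recovery statistic of very-low-amplitude genotypes sits close to 1
  and close to the no-recovery-limb failure boundary by construction;
  cohort summaries should always be read together with the failures table.
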