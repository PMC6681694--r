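---
title: "Quantitative imaging test–retest repeatability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative imaging test–retest repeatability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RepeatQuant)
```

# Scope and model

RepeatQuant analyzes test–retest studies of quantitative tumor imaging:
each subject is imaged twice with no intervening therapy, a metric
(SUV~max~, SUL~peak~, ADC~median~, ...) is extracted from each session,
and the question is how much the metric moves when the biology has not.
The analysis is the Bland–Altman repeatability framework on *relative*
differences:

$$\%\Delta_i = 100\,\frac{m_{i2}-m_{i1}}{(m_{i1}+m_{i2})/2},$$

normalized by the pair mean (the quantity a Bland–Altman plot uses for
its x-axis), not by the first measurement, so that the statistic is
antisymmetric in the session labels. From the cohort of $\%\Delta$
values the package reports the mean (systematic drift), the sample SD
($n-1$ denominator — small cohorts are the norm here), the
within-subject coefficient of variation $\mathrm{wCV} = SD/\mathrm{div}$,
the repeatability coefficient $RC = 1.96\,SD$, the 95% limits of
repeatability $\text{mean} \pm RC$, and the mean $|\%\Delta|$ (zero only
under perfect repeatability, unlike the mean, which can vanish under
large but symmetric changes).

All $\%\Delta$-based statistics are scale-free: multiplying every
measurement by a positive constant changes nothing, which is why a
multiplicative (lognormal) error model is the natural generating model
(below).

## The wCV divisor

Two conventions circulate for turning the SD of paired relative
differences into a per-measurement within-subject CV. If each
measurement carries independent multiplicative error with CV
$\sigma_w$, the difference of two log-measurements has SD
$\sigma_w\sqrt{2}$, so $SD(\%\Delta) \approx 100\,\sigma_w\sqrt 2$ and
dividing by $\sqrt 2$ recovers $100\,\sigma_w$. The SD/2 convention is
also used in the repeatability literature and yields values a factor
$\sqrt 2 / 2$ smaller. `repeatabilitySummary()` defaults to
`wcvDivisor = "sqrt2"` — the convention under which the wCV estimates
the per-measurement CV, verified by the package's Monte-Carlo tests —
and accepts `"2"`; `as.data.frame()` on a summary always reports both
side by side so tables are comparable across conventions. The two
interpretations differ only by a constant; nothing downstream depends
on the choice.

## Hypothesis tests and multiplicity

Session-1-vs-2 location differences use the Wilcoxon signed-rank test;
repeatability comparisons between metrics or modalities compare the
per-subject $|\%\Delta|$ distributions with the Mann–Whitney U test
(unpaired) or the signed-rank test (paired by subject, exposed via the
comparison plan's `test` column — when the same subjects underlie both
groups a paired test is the more powerful choice, and the pipeline
leaves this to configuration). Both tests are two-sided, exact for
small untied samples and tie-corrected normal approximations otherwise
(delegated to `stats::wilcox.test`; the package's enumeration oracles
verify the exact branch on all small inputs). Zero differences are
dropped before ranking — Wilcoxon's original convention, documented
because with $n \approx 14$ it is consequential. Fully tied degenerate
inputs (every difference zero, or identical constant groups) are
reported as $p = 1$: no evidence either way, and a value the FDR step
can consume.

Families of comparisons are corrected with the Benjamini–Hochberg
step-up rule at $q = 0.05$ by default. The realized significance
cutoff — the largest rejected raw p-value — is reported per family
rather than hard-coded, since it is an output of the procedure on the
p-values at hand. Normality of $\%\Delta$ distributions is summarized
by the Shapiro–Wilk test (a numeric surrogate for Q-Q plot
inspection), and `logTransformCheck()` reports whether log-scale
differences are more normal; per standard repeatability practice the
headline statistics are computed on untransformed $\%\Delta$ either
way, as deviations from normality are benign in this setting.

# Image quantitation

## SUV and SUL

$\mathrm{SUV} = c / (D(t)/W)$ with $c$ the activity concentration
(Bq/mL), $W$ body weight in g, and $D(t)$ the injected dose (Bq)
decay-corrected to the reference time $t$ with half-life 109.771 min
(¹⁸F; overridable per call). The decay reference is the *start of the
selected reconstruction frame* — console software conventions vary
here, and within a session the choice only rescales all voxels by a
common factor, so no %Δ statistic is affected.
$\mathrm{SUL} = \mathrm{SUV}\cdot \mathrm{LBM}/W$ with lean body mass
from the James (1976) formula: $1.10W - 128(W/H)^2$ for males,
$1.07W - 148(W/H)^2$ for females ($W$ kg, $H$ cm). For extreme inputs
the quadratic term can make the formula non-positive; that is raised as
out-of-domain rather than clamped.

## Peak, trough, isocontour

The *peak* is the highest mean achievable for a 1-cm³ sphere whose
center voxel lies inside the tumor contour; the ADC *trough* is the
minimum-mean mirror (its published definition is informal, and the
sphere-minimum reading is adopted here as the natural dual). Numerical
choices, all surfaced in the API:

- **Candidate centers are voxel centers** inside the mask — no
  sub-voxel optimization. This matches discrete-grid practice and makes
  the exhaustive brute-force oracle exact, which is how the search is
  validated (commercial implementations may differ sub-voxel).
- **Kernel membership is binary** by voxel-center inclusion within
  $r = (3V/4\pi)^{1/3} = 6.204$ mm. The realized kernel volume
  (count × voxel volume) is reported next to the 1-mL target so the
  discretization error at the session's spacing is visible; at 2-mm
  isotropic spacing it is within ~25%, at 1 mm within ~5%.
- **The sphere may leave the contour but not the image.** Centers whose
  sphere exits the image are excluded; if *no* center fits (tiny images
  or extreme spacing), the kernel is clipped at the border and the
  result flagged `clipped = TRUE` rather than failing or silently
  shrinking.

The percent isocontour keeps all in-mask voxels with value ≥ fraction ×
in-mask max (inclusive, so the argmax always survives; 40% default).
It is purely threshold-based — no connected-component filtering — since
that is the definition's letter; a 6-connectivity component filter
exists behind `connected = TRUE` but defaults off. The isocontour is
undefined (an error) when the in-mask max is non-positive. Medians use
the midpoint-of-central-order-statistics convention for even counts.

Tumor volumes are voxel count × voxel volume; total lesion glycolysis
is in-mask mean × volume. Non-sphere metrics provably ignore
mask-external voxels; sphere means legitimately do not, and both
behaviors are pinned by tests.

## Grids, formats, degenerate inputs

Volumes and masks are NIfTI; arrays are kept in native NIfTI index
order (x, y, z) with spacing (dx, dy, dz) in mm, and no world-space
affine math is performed (single-station axial volumes need none —
registration, resampling and DICOM ingestion are out of scope).
Downstream operations *reject* grid mismatches (shape exactly, spacing
within a relative tolerance of 1e-4) instead of resampling. Non-finite
voxels fail loading with a count; empty masks warn at load and error at
metric extraction.

# Uptake-time matching

Static frames of 1/3/5 min are chosen inside the overlap of the two
sessions' acquisition windows so both sessions reconstruct the *same
real interval* (identical effective uptake time, not merely equal
duration): policy `latest` takes $[\min(\text{end})-f, \min(\text{end})]$,
`earliest` takes $[\max(\text{start}), \max(\text{start})+f]$.
Pairing latest-for-PET/CT with earliest-for-PET/MRI minimizes the
uptake-time gap between the modalities when PET/MRI follows PET/CT, and
is the pipeline default. Intervals are half-open real-valued minutes;
list-mode event replay and reconstruction are out of scope, so
reconstruction labels (OSEM/PSF) ride through the tables as metadata
only. Insufficient overlap errors with the shortfall in minutes.

# Synthetic ground truth

Two generators, deliberately redundant:

- **Metric level** (`simulateMetricCohort`): true values
  $M_i \sim \text{lognormal}$, measurements
  $m_{ij} = M_i e^{\varepsilon_{ij}}$,
  $\varepsilon_{ij} \sim N(0, \sigma_w^2)$ i.i.d. Defaults: $n = 14$
  subjects and two sessions (the emulated study design),
  $\sigma_w = 0.10$ (mid-range of published FDG SUV~max~ wCVs),
  between-subject meanlog $\log 8$, sdlog 0.4 (an SUV~max~-like spread;
  the between-subject law only sets the x-axis of Bland–Altman plots —
  %Δ statistics are invariant to it).
- **Image level** (`generateLesionPhantom`, `generatePairedStudy`): an
  ellipsoid lesion (default semi-axes 12×10×10 mm, honoring a ≥ 2.0 cm
  diameter inclusion floor) on a background, times a per-session
  multiplicative factor $e^{\varepsilon}$, convolved with a Gaussian
  PSF (a stand-in for reconstruction resolution; separable, with
  boundary renormalization so uniform fields stay uniform), plus white
  Gaussian noise. The mask is the pre-blur indicator. ADC phantoms
  reuse the generator with inverted (cold) contrast, since tumors are
  dark on ADC maps. `generatePairedStudy` writes a complete two-session
  PET/CT + PET/MRI + ADC study with per-subject records, jittered
  acquisition windows (PET/CT 15 min from ~60 min post-injection,
  PET/MRI 30 min immediately after), and a ground-truth manifest. PET
  activity concentrations are constructed so SUV conversion at the
  matched frame start recovers the true amplitude exactly.

The two levels must agree, and do exactly: with zero noise and zero
background, blur and SUV/SUL conversion are linear, so every linear (and
order-preserving) metric's %Δ equals the session factors' %Δ — the
package's end-to-end test. The within-subject error model is the
generator's own assumption (the emulated study design implies none);
lognormal is chosen because it is positive, scale-free and makes wCV
recovery exact in expectation. What the phantoms do *not* emulate:
anatomy, attenuation-correction artifacts, bladder filling and
peristalsis, contouring variability, scanner calibration drift. Passing
tests therefore validate the *statistical machinery and metric
definitions*, not clinical variability magnitudes.

# Validation design and problem sizes

The package validates itself at three levels, with sizes chosen to keep
the full suite under a minute of compute:

- **Oracle equivalence** — the sphere search, isocontour, exact rank
  tests and BH rule are each checked against independent brute-force
  enumeration (exhaustive center scans on ≤ 13³ grids; all $2^n$ sign
  assignments for $n \le 10$; all $\binom{n+m}{n}$ labelings; the
  literal step-up definition) on 200+ randomized instances each.
- **Statistical calibration** — 10,000 simulated pairs give mean ± RC
  coverage within 0.7 points of 95%; 2,000 BH replicates over a
  10-null/10-alternative mixture keep the empirical FDR under 5%
  (the theoretical value is $q\,m_0/m = 2.5\%$); 200 replicate
  14-subject cohorts at $\sigma_w = 0.10$ put the median recovered wCV
  within 1.5 points of 10% (divisor $\sqrt 2$), with the replicate
  spread following the 13-df chi law of an SD estimate.
- **End-to-end** — noiseless image fixtures reproduce metric-level
  ground-truth %Δ exactly; a zero-CV study yields identically zero
  repeatability statistics.

`scripts/acceptance.R` re-runs the two calibration checks from scratch
against the installed package and writes the numbers as JSON.

# Known limitations

- Single-station volumes; no registration or contour propagation —
  masks are taken as given, so contouring variability is outside the
  model.
- One lesion per subject; multi-lesion bookkeeping would need manifest
  extensions.
- The sphere search is voxel-centered; sub-voxel peak placement (as in
  some commercial tools) would shift peaks by at most one voxel's worth
  of mean.
- Only the James LBM formula is implemented (Janmahasatian et al. is a
  straightforward extension point).
- Variance-components / mixed-effects repeatability models, Deming
  regression and ICC are intentionally absent: the Bland–Altman %Δ
  battery is the implemented framework.
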