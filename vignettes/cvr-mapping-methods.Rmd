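---
title: "Methods: BOLD cerebrovascular reactivity mapping and two-time-point volumetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BOLD cerebrovascular reactivity mapping and two-time-point volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrmap)
```

## The measurement

Cerebrovascular reactivity (CVR) is the change in cerebral blood flow per
unit change in arterial CO~2~, a bedside-relevant index of the vasodilatory
reserve of the cerebral circulation. This package estimates it regionally
from BOLD fMRI acquired during a stepped end-tidal CO~2~ forcing protocol:
end-tidal partial pressure of CO~2~ (petCO~2~) is held at a sequence of
offsets from baseline (by default two hypocapnic steps at −10 and −5 mmHg,
a return to baseline, then hypercapnic steps at +5, +10, +15 mmHg, two
minutes each) while petO~2~ is clamped at 100 mmHg. Over this ±15 mmHg
range the BOLD signal responds close to linearly in petCO~2~, so a single
linear regressor is used rather than per-step fits; CVR is the fitted slope
expressed in percent signal change per mmHg,

$$\mathrm{CVR}(v) = 100 \cdot \frac{\hat\beta_{\mathrm{petCO_2}}(v)}{\bar S(v)}
\quad [\% \cdot \mathrm{mmHg}^{-1}],$$

with $\bar S(v)$ the voxel's mean signal. Voxels whose signal *falls* under
a global vasodilatory stimulus (negative CVR) are read as vascular steal —
blood redistributed away from the region — and are treated as a finding,
not noise: thresholding is two-sided by default, and each anatomical
structure is dichotomized into its significantly positive and significantly
negative compartments.

The companion structural analysis measures percent brain volume change
(PBVC) between two sessions from the perpendicular displacement of the
brain surface, plus gray/white/CSF volumes from a three-class Gaussian
mixture segmentation, and counts white-matter lesions from a binary mask.

## Gas traces to regressors

Raw mouth-sampled PCO~2~/PO~2~ and pneumotachograph flow (200 Hz in the
emulated recordings) are reduced per breath: expiration is `flow < 0`,
petCO~2~ is the expiratory maximum, petO~2~ the expiratory minimum, tidal
volumes the integrals of each flow half-cycle. Breath onsets are
inspiration zero-crossings found with a hysteresis of 5 % of the peak flow
(configurable); breaths shorter than 1 s merge into their successor.

Each end-tidal value stands for the alveolar gas of its own breath, so the
per-volume regressor holds the value over the volumes the breath covers
(linear interpolation through expiration midpoints is available). The
regressor pair is then lagged, as one unit, by the integer number of
volumes that maximizes the Pearson correlation between petCO~2~ and the
whole-brain mean BOLD course. The search runs over non-negative shifts only
(the response cannot precede the stimulus), at TR granularity, ties broken
toward the smallest lag; this one step absorbs both the gas-transport
(sampling-line) delay and the circulatory delay. SpO~2~, the nuisance
regressor, is computed from the *lag-corrected* petO~2~ series through the
classic one-equation Severinghaus fit of the oxyhemoglobin dissociation
curve,

$$S = \left(\frac{23400}{p^3 + 150\,p} + 1\right)^{-1}, \qquad p = \mathrm{petO_2\ in\ mmHg},$$

which is strictly increasing and bounded in (0, 1). With a perfect 100 mmHg
clamp the SpO~2~ column is constant and is dropped from the design rather
than left to make it rank-deficient.

## Preprocessing and the GLM

Spatial smoothing is a separable 3-D Gaussian (default FWHM 6 mm),
mask-aware: the masked data and the mask are smoothed separately and their
ratio taken, so edge voxels are renormalized instead of being diluted by
background zeros. Temporal high-pass filtering subtracts a
Gaussian-weighted running straight-line fit per voxel and restores the
voxel mean. Its width defaults to sigma = 50 s: the protocol's information
lives at periods of 2 minutes and above, and a width much below that would
fit and remove the steps themselves, so widths under 2 TR are refused
without an explicit override. Crucially the same filter is applied to the
regressors: high-passing the data alone would attenuate the slow stimulus
component out of the data but not the design and bias every beta toward
zero (we measured ~90 % loss on a 120 s step design). Filtering both sides
leaves the slope estimate exact for any signal in the design span. Motion
correction and slice timing are identity hooks — the synthetic data are
motion-free — and registration is not performed (phantoms share a grid);
the hooks exist so acquired data can be slotted in upstream.

The voxelwise model is ordinary least squares on
(intercept, centred petCO~2~, centred SpO~2~), with residual degrees of
freedom `t − rank(X)`. No prewhitening is attempted: on phantom data the
noise is white by construction, and the quantity carried forward is the
beta, not its single-voxel variance. t statistics map to z scores through
matched cumulative probabilities, clipped at |z| = 38 (about the largest
value a double's tail probability can represent). Voxels whose residual
variance is numerical dust relative to their signal level (a perfectly flat
noiseless fit) get z = 0 when the beta is also dust, ±38 otherwise;
non-positive baselines are removed from the mask rather than allowed to
produce infinities.

## Multiple comparisons by resels

Smoothness is estimated from the *residuals* (the data contain the
stimulus, which would inflate apparent smoothness): the lag-one spatial
autocorrelation $\rho_i$ of the standardized residuals along each axis,
pooled over volumes, gives a per-axis kernel width
$\mathrm{FWHM}_i = \sqrt{4\ln 2 / (-2\ln\rho_i)}$ voxels under a Gaussian
autocorrelation model. Estimates are floored at 1 voxel ($\rho \le 0$ maps
to 1), so the resel count — mask voxels divided by the FWHM volume, the
number of effectively independent samples — never exceeds the voxel count.
The significance threshold solves
$R \cdot P(|Z| > z^*) = \alpha$ (default $\alpha = 0.05$, two-sided),
a Bonferroni correction over resels rather than voxels, hence less
conservative than voxelwise Bonferroni whenever the map is smooth.

A known limitation, verified numerically while designing the false-positive
experiment: for strongly smoothed fields this resel-Bonferroni threshold is
*anti*-conservative relative to Euler-characteristic Gaussian-random-field
theory, because the EC density at threshold $z$ carries a polynomial factor
$(z^2-1)$ that exceeds the point tail probability. The package's
false-positive control is therefore validated on unsmoothed null phantoms,
where the resel count approaches the voxel count and the correction is a
plain Bonferroni; users smoothing heavily should treat the threshold as
approximate and, if strict familywise control matters, prefer a higher one.

## Regional analysis

Atlas structures are integer labels plus a (id, structure, hemisphere)
table; the package ships a phantom atlas with gray matter, white matter,
brainstem and seven bilateral subcortical structures rather than
redistributing any third-party atlas files. Region means are arithmetic
means over masked voxels (tested against direct voxel sums). Each structure
is dichotomized at the *pre* session into significant-positive and
significant-negative compartments; voxels with CVR exactly zero join
neither (measure zero under noise; the rule keeps the split deterministic).
The pre-session masks are frozen and applied unchanged at follow-up, so a
compartment's change reflects the same voxels, not shifting membership.
Structures with an empty compartment are recorded as absent and excluded
listwise from the 2×2 analysis — some structures genuinely have no
significant negative voxels, and a fabricated zero would masquerade as
data. Fractional frequency distributions use 0.025 %·mmHg⁻¹ bins over
[−1, 1] by default, normalized to sum to one, with the distribution mean
reported for the customary vertical marker.

## Two-time-point volumetry

Tissue segmentation fits a three-component univariate Gaussian mixture
(mclust, model "V" with an equal-variance fallback) to the masked
intensities and takes posterior class probabilities as partial volume
estimates, classes identified by ascending mean (CSF < GM < WM, the
T1-like ordering). Initialization uses a deterministic intensity-spanning
subset of 2000 voxels — full hierarchical initialization is quadratic in
the voxel count. Masked images with three or fewer distinct values are
noiseless label maps and are assigned exactly by level.

PBVC follows the edge-displacement principle: edge points are the boundary
voxels of the baseline brain mask; outward normals come from the gradient
of a Gaussian-smoothed mask indicator. Along each normal an intensity
profile is sampled in both volumes and the displacement estimated as the
sub-voxel translation minimizing the summed squared difference between the
profiles (shift grid at a quarter voxel, parabolic refinement, and an
exact-match short-circuit so identical inputs give displacement exactly
zero). We deliberately match the whole profile rather than a single
half-maximum level crossing: with a CSF shell about one voxel thick the
"inside plateau" window reaches into gray matter, the crossing sits
off-centre on an interpolation-smoothed ramp, and the single-level estimate
picks up a ~6 % bias (0.9 percentage points of PBVC on the eroded-sphere
oracle). Both volumes are pre-smoothed with a common sigma = 1 voxel
Gaussian first; common smoothing leaves true displacements unchanged but
removes the dependence of the match on the interpolation grid phase.
Each edge point carries a projected-area weight (voxel face area divided by
the largest normal component — a bare edge-voxel count underestimates a
sphere's surface by ~20 %), and

$$\mathrm{PBVC} = 100 \cdot \frac{\sum_i a_i d_i}{V_{\mathrm{brain}}}.$$

On a 60 mm sphere eroded by 1.5 mm (3 mm voxels) this lands within 0.15–0.4
percentage points of the analytic −7.31 %; the estimator is antisymmetric
under swapping the sessions to within 5 % for sub-voxel shifts. Lesions are
26-connected components of a binary mask with a 5 mm³ minimum size — a
deterministic stand-in for a radiologist's read.

## Group statistics

Paired and one-sample t tests wrap `stats::t.test`, with the zero-variance
edge handled explicitly (identical nonzero differences report an infinite
statistic, a machine-floor p, and a flag). The 2×2 repeated-measures ANOVA
(session × hemisphere, or session × compartment sign) uses the classical
within-subject decomposition, each effect tested against its own
effect-by-subject interaction on (1, n−1) degrees of freedom; it is tested
for exact agreement with `aov` error strata on randomized instances. Tukey
HSD compares the four *cell* means using the interaction error mean square
and the studentized range with n−1 degrees of freedom (the choice of error
term and of cells over margins is a design decision; both are recorded
here). p values are two-sided throughout. Lesion counts, small and skewed,
are summarized as median ± IQR with inclusive Tukey-hinge quartiles
(`fivenum`), which reproduces the conventional printed summaries for
five-subject count data.

## The synthetic study and what passing it shows

Every stage is exercised on generated data with known truth. The gas
generator prescribes ventilation (no chemoreflex loop — matching a forcing
design), square-wave expired plateaus with linear transitions (only the
plateau matters downstream), 5 s breaths, and exact plateau bookkeeping.
The BOLD phantom is a three-shell ellipsoid (CSF/GM/WM) responding as
$S = S_0(1 + \mathrm{CVR}/100 \cdot \Delta\mathrm{petCO_2}(t-\delta))$
with gray-matter CVR 0.30, white 0.15 %·mmHg⁻¹ (the ~2:1 ratio seen in
vivo), scattered negative foci at −0.20, a uniform 6 s delay, 1 % Gaussian
noise and optional linear drift — no hemodynamic response function beyond
the pure delay, no motion, no physiological noise. The structural phantom
adds sub-voxel partial-volume ramps (one voxel wide; width 0 gives exact
three-level images), atrophy imposed *geometrically* — the bounding
interface is root-found to the shift that removes the target volume, so a
2.6 % gray-matter loss is a real boundary change a segmentation can see,
not an intensity rescale — and lesions as disjoint white-matter spheres.

Recovery experiments at the study's own scale (40×48×40 voxel phantom,
420 volumes at TR 2 s, six-subject reversal designs, 50-run null
batteries) are what the acceptance script reruns; compartment-mean CVR
errors come back below 0.02 %·mmHg⁻¹ and the 6 s delay exactly. The CVR
recovery runs use no spatial smoothing: a 6 mm kernel mixes compartments
across the GM/WM boundary and the experiment is about the estimator, not
the kernel. Passing on these phantoms demonstrates the estimators are
unbiased under their own assumptions; it does not certify behaviour under
motion, autocorrelated physiological noise, nonlinear or dispersed
hemodynamics, registration error, or real skull/scalp anatomy, all of
which are out of scope here.

## Numerical choices collected

* Lag search: integer volumes, non-negative, ties to the smallest lag.
* High-pass guard: sigma below 2 TR refused without `allow_short = TRUE`.
* z clipping at ±38; degenerate (noiseless) voxels resolved by a
  1e-9-of-baseline dust tolerance.
* FWHM floor at 1 voxel; $\rho \le 0$ or non-finite maps to 1.
* CVR exactly 0 belongs to neither compartment.
* Histogram: width 0.025 %·mmHg⁻¹ on [−1, 1], values clamped into end bins.
* Edge profiles: half-width 2 voxels, step ¼ voxel, shift range ±1 voxel,
  pre-smoothing sigma 1 voxel; matches at the search boundary are dropped
  and counted.
* Lesions: 26-connectivity, 5 mm³ floor.
* Tukey hinges for median ± IQR; mean (SE) rows recomputed from subject
  rows everywhere.
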