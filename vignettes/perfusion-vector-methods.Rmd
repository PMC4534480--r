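---
title: "The perfusion vector: model, phantom and statistical pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The perfusion vector: model, phantom and statistical pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfvec)
```

## The model

Myocardial perfusion SPECT shows the relative distribution of a blood-flow
tracer in the left-ventricular myocardium. `perfvec` reduces the spatial
homogeneity of that distribution to one displacement vector. The
mid-myocardial surface is represented as a grid of rectangles, each carrying
a center position, an area $A_i$ and an intensity weight $W_i$; the weighted
centroid is

$$C = \left(\frac{\sum_i x_i A_i W_i}{\sum_i A_i W_i},\;
            \frac{\sum_i y_i A_i W_i}{\sum_i A_i W_i},\;
            \frac{\sum_i z_i A_i W_i}{\sum_i A_i W_i}\right).$$

Unit weights give the anatomical centroid $C_A$; measured intensities give
the perfusion center of gravity $C_P$; the perfusion vector is
$P = C_P - C_A$. Because the statistic is a ratio, it is invariant to global
intensity scaling (no count normalization is needed) and it is exactly
equivariant under rigid motions of the surface. A localized uptake deficit
removes weight on one side of the ventricle, so $P$ points away from the
defect; to first order in the removed weight fraction $m/S$,
$P \approx \frac{m}{S-m}\,(C_A - \bar r_d)$ where $\bar r_d$ is the area
centroid of the defect patch. This closed-form picture drives several design
choices below.

Assumptions worth keeping in mind: the statistic sees only the *first moment*
of the weight distribution. Two defects on opposite walls can cancel; the
method is a homogeneity summary, not a defect detector, and balanced
multi-vessel disease is its known blind spot.

## The surface model

Patient processing in the source workflow delineates the ventricle with a
commercial segmentation package; `perfvec` instead models the mid-myocardial
surface as a prolate ellipsoid of revolution truncated by a basal plane
(apex pole closed, base open). This keeps every geometric quantity —
surface area, cavity volume, meridian arc length — available in closed form
or by 1-D quadrature, which the test suite uses as independent oracles.

Defaults: short semi-axis 25 mm, long semi-axis 45 mm, truncation at 35 % of
the long radius on the basal side, wall thickness 10 mm, and both radii
rescaled so the endocardial cavity volume is 148 mL (a standard-male
end-diastolic volume; the solved radii come out at roughly 33.7 and 60.6 mm,
a 97 mm apex-to-base meridian). The grid is `n_longitudinal = 32` polar
bands times `n_circumferential = 64` sectors; no canonical resolution exists
for such surfaces, so it is a parameter. Cell areas are the local metric
product (circumferential arc spacing x meridional arc spacing at the cell
center), a midpoint rule whose total-area error falls quadratically with
resolution. The circumferential count must be even so that every rectangle
has exact mirror partners across the x-z and y-z planes — that is what makes
the anatomical centroid sit on the long axis to machine precision and makes
anterior/inferior defect responses exactly antisymmetric.

Axis signs (+x lateral, +y inferior, +z apical, right-handed) are chosen so
that "points away from the defect" lands on the expected clinical reading:
anterior defects push $p_y$ positive, lateral defects push $p_x$ negative.

## The phantom

`render_volume` rasterizes uptake 1 between the endo- and epicardial
ellipsoids (mid surface $\pm$ half the wall thickness per semi-axis) above
the basal plane, scaled by $1-\text{severity}$ inside the defect sector.
Each voxel receives the mean uptake over $2^3$ sub-voxel points
(`supersample = 2`), so wall- and defect-boundary voxels carry fractional
partial-volume values. This antialiasing is what makes the noiseless
pipeline stable under voxel-size halving (vector change well below 0.2 mm);
binary voxel-center membership (`supersample = 1`) is kept for exact
membership oracles.

Degradation is image-domain: an isotropic Gaussian post-filter of 7 mm FWHM
($\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$, discrete kernel truncated at
$4\sigma$ and renormalized, zero-padded boundaries) followed by Poisson
noise scaled to 500 expected counts in the hottest voxel — a typical
clinical count level. Monte Carlo photon transport, projection/reconstruction,
attenuation, scatter and motion are deliberately not modeled: the
quantification consumes reconstructed short-axis images, and blur plus
counting noise are the dominant degradations at that stage. Noise is drawn
after the blur; in a real chain reconstruction correlates the noise, so the
phantom's noise is slightly optimistic in texture. Voxels are 4.8 mm
isotropic; the field of view auto-crops to the ventricle plus a 15 mm margin
so the blur kernel never clips activity.

### Defect geometry

A defect is a circumferential sector of opening angle $\alpha$ (centered
anterior/inferior/lateral/septal or at a custom angle) intersected with a
meridian-arc band of length 60 mm by default; apical defects are arc
distance from the pole. Severity multiplies uptake by $1-s$; the default
$s = 1$ (zero uptake) matches the visually absent uptake of fully developed
simulated defects, and is a free parameter since no contrast value is
canonical.

The band placement is **centered on the short-axis plane through the
anatomical centroid** by default, i.e. a mid-ventricular wall defect, with
apex- and base-anchored placements as options. The first-moment formula
explains why: the $z$ drift of $P$ across defect sizes is proportional to
$|\bar z_{defect} - \bar z_{surface}|$. An apex-anchored 60 mm band on the
97 mm meridian sits about 22 mm apical of the surface centroid, which would
make $p_z$ move almost as much as the in-plane component — contradicting the
defect-size experiments this phantom is built to reproduce, where $p_y$
grows with anterior defect size while $p_x$ and $p_z$ stay nearly constant.
The centered band keeps the defect z-balanced (measured drift: under 10 % of
the $p_y$ range) while leaving the in-plane behavior untouched.

`defect_area_fraction` reports the true extent as an area fraction using
fractional cell overlap (exact in angle, first-order along the arc), so it
is free of the sector-quantization bias of the binary membership used for
weights and tracks the analytic $\alpha/360 \times$ (band area fraction)
within 2 % at default resolution.

## Intensity sampling

`sample_weights` assigns each rectangle the maximum (default) or mean of
trilinear volume samples taken every 1 mm within $\pm$10 mm along the
surface normal. Normals are analytic from the ellipsoid parameterization,
not mesh differencing. Max-sampling is the common practice in perfusion
quantification because it is robust to mild surface misplacement; it also
rides over noise peaks, which inflates all weights roughly uniformly — and
the statistic's scale invariance makes that inflation harmless to first
order. Samples outside the volume contribute zero.

Two residual artifacts are inherent and worth knowing. Near the open base
the blurred wall loses intensity into the void, and near the apex the
converging walls gain it; both shift $C_P$ slightly apically, giving the
defect-free pipeline a systematic $p_z \approx +0.3$ mm at default settings
(the noise floor: median |P| ≈ 0.3 mm over 100 noise realizations, well
below the ≈ 1.8 mm of a noiseless 30-degree defect, with no overlap between
the two distributions). The optional `basal_exclusion_fraction` replaces the
basal-rim weights with the interior median — an approximate neutralization
of delineation artifacts at the rim, kept at 0 by default.

## The synthetic cohort

`generate_cohort` emulates a validation cohort: 40 normal studies plus four
defect-location groups (apical, inferior, anterior, lateral) of 20, each
patient simulated at stress and rest through the full pipeline. Abnormal
draws: $\alpha \sim U(20°, 70°)$ (bracketing the simulated defect sizes),
stress severity $\sim U(0.5, 1)$, and a 50/50 ischemia/infarction split —
ischemia rest severity is the stress severity times $U(0.1, 0.4)$
(largely reversible), infarction keeps stress severity at rest (fixed).
These distributions are the one free choice of the generator; they were set
once, from what a nuclear-cardiology reader would call a plausible case mix,
and are config-overridable. Every draw, including per-study noise seeds,
derives from one master seed; the same spec yields byte-identical CSVs.

What the cohort does and does not show: it demonstrates that the estimator
recovers the generator's own structure (extent-magnitude correlation near
$\rho \approx 0.95$; ischemia separated from normal on
$|P_s| - |P_r|$ while infarction is not, because fixed defects cancel in the
stress-rest difference). Real patients add anatomical variability,
off-center defects, attenuation patterns and delineation error, so
real-data correlations will be weaker; the clean-phantom numbers are upper
bounds, not forecasts.

## The statistical pipeline

`compare_groups` runs Kruskal-Wallis over all groups per metric and, only
when the omnibus is significant at 0.05, Mann-Whitney tests of each abnormal
group against the reference, flagged at the Bonferroni threshold $0.05/k$
(0.0125 for four comparison groups, 0.025 for two). All tests are two-sided
— sidedness is not dictated by the method, and two-sided is the conservative
default. The omnibus gate is applied independently per metric/axis.

The Mann-Whitney wrapper uses the exact null distribution when the pooled
sample is at most 12 and tie-free, else the tie- and continuity-corrected
normal approximation; Spearman p values are exact for $n \le 7$ without
ties, else from the t approximation. The cut-offs keep exact enumeration
desk-scale. Exhaustive enumeration over all tie-free 6+6 configurations
shows the approximate branch within 0.016 of the exact two-sided p (worst at
mid-range U) — adequate far from the thresholds, and the exact branch covers
the small-sample regime where it matters. Degenerate inputs (all
observations identical) return p = 1 rather than NaN. Null simulations with
five groups of 10 keep the post-Bonferroni pairwise type-I rate at or below
the nominal level.

## Numerical choices and edge cases

* Meridian arc length uses a 4097-point trapezoid table with linear
  interpolation; cavity volume is closed-form, with the solver a 1-D root
  find on a common radial scale factor.
* All-zero weights raise a classed error rather than silently returning the
  anatomical centroid — a zero-weight surface means sampling or segmentation
  failed, and masking that would produce a plausible-looking null vector.
* Rotations are accepted when orthonormal within $10^{-8}$; areas, weights
  and intrinsic coordinates are untouched by rigid transforms.
* The surface CSV writer emits 9 significant digits (relative round-trip
  error below $5\times10^{-9}$); CSV-loaded grids support centroid
  computations but not defect geometry or normal sampling, which need the
  parametric form.
* Problem sizes used by the tests and the acceptance script — a 32x64 grid,
  ~35 mm³ voxel volumes, 100-realization noise ensembles, a 120-patient
  cohort, 1000-replicate null simulations — were chosen so the full suite
  runs in about half a minute while leaving every comparison comfortably
  powered.

## Known limitations

* First-moment statistic: balanced or antipodal defects cancel.
* The phantom omits reconstruction physics (correlated noise, attenuation,
  scatter) and anatomical variability; it validates the estimator, not
  clinical performance.
* The ellipsoid surface has no regional wall-thickness or shape variation;
  patient-specific segmentation is out of scope.
* Stress and rest are simulated in the same frame; real stress/rest
  misregistration would add variance to the difference metrics.
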