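---
title: "Long-axis hippocampal profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long-axis hippocampal profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippoaxis)
```

## The problem

Hippocampal sclerosis — the commonest lesion behind drug-resistant temporal
lobe epilepsy — shows radiologically as hippocampal volume loss and elevated
T2 signal. Whole-hippocampus volumetry and T2 relaxometry quantify both, but
a single number per hippocampus is blind to focal disease: a sclerotic
anterior head can hide inside a normal total volume. `hippoaxis` resolves
the measurements along the hippocampal long axis: the cross-sectional area
(CSA, mm²) of the segmentation on every coronal slice, and the quantitative
T2 (qT2, ms) per acquired slice, each indexed by an anterior–posterior (AP)
position in a common template frame and compared pointwise against a
normative band estimated from healthy controls.

All world coordinates are RAS+ millimetres and the AP axis is world +y,
posterior to anterior. The on-disk orientation convention of the source
acquisitions is not knowable in general, so one convention is fixed
throughout and enforced at load time; voxel indices are 0-based internally,
while slice positions in millimetres are 1-based from the most posterior
template slice (a 218-slice 1-mm template carries distances 1–218 mm).

## Pipeline

1. **Long-axis reorientation.** The first principal component of each
   hippocampal mask's voxel coordinates estimates its long axis; the mean of
   the left and right axes is rotated onto +y (rotation about the
   mid-centroid), and the residual roll is fixed by mapping the left→right
   centroid direction onto +x. Axes disagreeing by more than 45° abort with
   an alignment failure.
2. **Groupwise template.** Controls are iteratively registered (full affine,
   normalized cross-correlation, multi-resolution Nelder–Mead) to the
   running mean image; 10 iterations by default. Nonlinear refinement is a
   plug-in interface — a function receiving the two volumes, the cost mask
   and the affine initialization — with no default implementation: the
   standard pipeline is affine-only, and users with an external deformable
   engine can slot it in. Whether affine and nonlinear iterations should
   interleave is not determined by the method's description; they run
   sequentially here (all affine first).
3. **Distance mapping.** The template distance map assigns slice *k* the
   value *k*·(AP spacing) mm. It is propagated through the inverse of each
   subject's template registration; the mean propagated distance over the
   in-mask voxels of each subject slice maps subject slices to template AP
   positions. Non-monotone slice distances raise an alignment warning.
4. **Profiles.** CSA is measured on the subject's coronal slices after
   rigid reorientation (the mask resampled trilinearly; per-slice CSA is the
   sum of fractional mask values times the in-plane voxel area), corrected
   for total intracranial volume, paired with the slice distances and
   linearly interpolated to a 1-mm grid. qT2 stays on the native 4-mm
   acquired slices: the two-point estimator
   `qT2 = (TE2 − TE1) / ln(S(TE1)/S(TE2))` per voxel, masked means per slice
   after partial-volume exclusion, one profile point per slice.
5. **Normative model and comparison.** Kernel-weighted local statistics of
   the pooled control profiles at 1-mm steps give μ(x) and σ(x); the normal
   range is μ ± 1.96 σ. Individuals are flagged one-sidedly (CSA below the
   band = atrophic; qT2 above = elevated); groups are compared by pointwise
   Welch t-tests with Bonferroni correction.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| echo times | 30 / 119 | ms | the dual-echo fast spin echo protocol the estimator is built for |
| qT2 validity ceiling | 1000 | ms | CSF-dominated voxels decay too slowly to be tissue; marked invalid, not clamped |
| partial-volume rule | mask fraction ≥ 0.99 | — | "exclude any partial volume voxels" made deterministic: the segmentation is resampled to the dual-echo grid with linear interpolation and only effectively interior voxels are kept; if fewer than 10 survive, a one-voxel erosion of the binarized mask is the fallback |
| profile grid step | 1 | mm | native T1 resolution; the comparison grid of the method |
| normal-range multiplier z | 1.96 | — | the two-sided 95% Gaussian range, applied one-sidedly per modality |
| kernel bandwidth | 2 | mm | smooths across slice-positioning jitter without flattening the head/tail ramps; the estimator class is named by the method, the bandwidth is this package's documented default |
| body stability rule | 2 | mm²/mm | a slice-to-slice CSA change below 2 mm² per mm defines the body plateau |
| pointwise α | 0.01 | — | Bonferroni-corrected by the number of supported grid points actually tested; regional tests use α/3 over tail/body/head |
| minimum normative support | n_eff ≥ 10 | — | grid points with less effective kernel support are truncated from the model |
| minimum qT2 slice voxels | 5 | — | slices with fewer valid voxels yield no profile point (missing, never zero) |

## The normative estimator

The method's description names a kernel density estimator for μ and σ at
1-mm steps. A pooled local-*constant* (Nadaraya–Watson) weighted sd has a
defect on sloped profile segments: for a cohort of identical profiles the
slope itself leaks into the pooled deviations, giving σ ≈ |slope| × kernel
width where the truth is zero, and an inflated band exactly where the CSA
profile ramps. `hippoaxis` therefore computes, at each grid point, the
kernel-weighted *local-linear* fit: μ is the fitted value and σ the
reliability-weighted standard deviation of the residuals. A cohort of
identical profiles then has σ = 0 wherever the profile is locally linear
(CSA profiles are piecewise linear to good approximation), and as the
bandwidth shrinks to zero on common grids the estimator degenerates to the
per-point sample mean and sd. Where the kernel support has no positional
spread the fit falls back to the local constant, which is what makes that
degeneracy exact. The band remains slightly conservative where σ(x) itself
changes quickly on the bandwidth scale (profile kinks and support edges) —
held-out coverage of the 1.96 σ band on stationary segments is 2.5% per
side as it should be, dropping toward 1–2% at kinks.

Scan–rescan variability uses the same kernel machinery on pooled
scan-difference samples, and patient-group average profiles reuse it with a
lower minimum cohort size.

## TIV correction

Head size is removed by ratio scaling: every CSA value and volume is
multiplied by `tiv_ref / tiv`, with `tiv_ref` the control-cohort mean TIV.
The residual-covariance alternative exists in the literature; the ratio
form is used because it applies identically to slicewise CSA and to
volumes, so profiles integrate exactly to corrected volumes (a conservation
property the tests assert). TIV values are inputs, not estimated here.

## Region partitioning

The body is the maximal contiguous run of normative-grid points with
|dμ/dx| < 2 mm²/mm (central differences; one-sided at the ends); tail and
head are the posterior and anterior remainders. Ties between equal-length
maximal runs break toward the more posterior run. A profile stable
everywhere is a degenerate all-body partition (flagged, zero-length tail
and head allowed only there); no stable point at all is an error. Slices
are assigned to regions by their mean AP distance — a 4-mm qT2 slice may
straddle a boundary, and the mean decides. Regional qT2 averages slice
values weighted by the segmentation volume in each slice.

## The synthetic phantom

The phantom generates what the pipeline needs to be tested end to end with
known truth: bilateral hippocampus-like tubes whose per-slice CSA follows a
piecewise-linear profile (tapering tail 8 mm, stable body 14 mm, head
rising 8 mm to a peak then tapering, 45 mm total), a mild circular-arc
centreline in the sagittal plane so reorientation and registration do real
work, mono-exponential dual-echo signals with additive Gaussian noise, a
cranial ellipsoid with internal structures for the T1-like registration
target, arbitrary rigid poses, and implantable focal lesions (a CSA
reduction and/or T2 elevation confined to an AP band). Defaults are
calibrated to the healthy-control regime at 3 T: tissue T2 115 ms with
3.5 ms between-subject sd, hippocampal volume ≈ 2.9 mL with 8% relative sd
(so the 95% population range spans roughly 2.4–3.4 mL), TIV 1450 ± 120 mL,
and acquisition grids of 1 mm isotropic (T1/masks) and 0.43 × 0.43 mm
in-plane with 4-mm coronal slices (dual echo). Subject size covaries with
TIV in the generator, so ratio correction removes exactly the head-size
component, as it is meant to.

Masks carry fractional edge voxels (3×3 in-plane subvoxel sampling): real
segmentations resampled between grids are fractional at the boundary, and a
purely binary tube would add ±4 mm² of voxelization jitter per slice that
is generator artefact, not anatomy. The ground truth retains both the
binarized voxel-count CSA and the fractional CSA per slice.

What the phantom does **not** emulate — and what passing tests therefore do
not demonstrate about real data: Rician magnitude noise (Gaussian is used;
adequate at the simulated SNR but wrong at very low signal), realistic
whole-brain anatomy and segmentation error, partial-volume mixtures beyond
edge voxels, B1/stimulated-echo effects, and deformable anatomical
variability (between-subject differences are size scalings and rigid
poses, so affine registration can in principle align them perfectly —
real cohorts need the nonlinear plug-in for that).

## Numerical choices

* **Resampling** is pulled back through the composed world transforms in
  one step (trilinear for scalars, nearest for labels; out-of-field voxels
  are 0 for masks and NaN for qT2/distance maps so averages ignore them).
  Masks are binarized at 0.5 after resampling wherever a binary view is
  needed.
* **Registration** optimizes normalized cross-correlation with Nelder–Mead
  over a coarse-to-fine pyramid (factors 4, 2). Pyramid levels are
  block-mean decimated: naive strided decimation aliases the cost surface
  and visibly degrades translation accuracy. With cost-function masking the
  similarity is evaluated only outside the hippocampal exclusion mask, so
  hippocampal pathology cannot bias the alignment.
* **Two-point qT2** marks non-positive, non-decaying and above-ceiling
  voxels invalid with an explicit reason code; nothing is clamped.
* **Group t-tests** are Welch (unequal variance) and two-sided; the
  method's description says only "two-sample t tests", and the robust
  unequal-variance form is the safer default. Individual flags are
  one-sided by the clinical direction of each modality.
* **Determinism**: every stochastic component (phantom noise, population
  draws, optimizer restarts) is seeded; generators save and restore the
  caller's RNG state.

## Validation problem sizes

The shipped validation runs at sizes chosen to exercise every path while
staying desk-sized: phantom grids of 64×80×64 (T1) and 148×16×100 (dual
echo); templates from 3 subjects with 2 affine iterations in the
orientation-invariance checks (the 10-iteration default is exercised with
fewer subjects); normative cohorts of 111 controls, image-level for the
lesion-localization experiment and profile-level for band coverage;
1000-rep null calibration and 200-rep power simulations for the
pointwise tests; 20 scan-rescan pairs. Under these conditions the full
alignment path reproduces interior CSA profile points across random rigid
poses within about 4% (the tapering ends dominate the relative error —
1 mm² of discretization on a 25 mm² slice is already 4%), the 1.96 σ band
covers held-out controls at 2.5% per side on stationary segments, and a
6-mm 50% focal lesion is flagged within ±2 mm of its true band without
disturbing the whole-hippocampus volume flag in a typical-size subject.

## Command-line interface

The profiling stages are R functions (`run_pipeline()` and the module
functions it wraps); `inst/cli/hippoaxis.R` provides a thin Rscript front
end for the file-oriented steps (`simulate`, `qt2map`, `profile`) that
read and write NIfTI. Template construction, normative building and group
comparison consume in-memory cohorts and are driven from R — for an R
package that is the natural interface, and the pipeline function is the
single entry point scripts should call.

## Known limitations

* Affine-only registration by default; deformable anatomical differences
  in real cohorts require an external nonlinear engine via the plug-in.
* The normative band is conservative at profile kinks and support edges
  (see above); covariates such as age and sex are not modelled.
* The two-point estimator is exact only for mono-exponential decay; no
  multi-echo or multi-compartment fitting.
* The exact partial-volume rule of the upstream relaxometry literature is
  not reprinted anywhere usable; the ≥ 0.99 mask-fraction rule is this
  package's deterministic reading of "exclude any partial volume voxels".
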