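---
title: "Simulating a dose-matched lung-phantom CT comparison: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a dose-matched lung-phantom CT comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package models

`lungphantom` simulates a low-dose lung-screening image-quality experiment:
two cylindrical chest phantoms containing six lung lesions (small/large
solid, part-solid, and ground-glass) are "scanned" by two scanner models —
an energy-integrating detector CT (EIDCT) and a photon-counting detector CT
(PCCT) — at five dose levels (CTDIvol 20.4, 9.8, 4.9, 2.4, 1.6 mGy) with
three repetitions each. The two scanner models share the phantom geometry
and differ in two calibrated respects: their per-material mean attenuation
(HU) and their noise-versus-dose curve. Everything downstream — ROI
statistics, contrast-to-noise ratios, a 107-feature radiomics vector per
lesion instance, PCA cluster statistics, and gated significance tests — is
computed from those simulated volumes.

The design grid is 6 lesions x 5 doses x 2 scanners x 3 repetitions = 180
lesion-measurement instances.

## The digital phantoms

Phantom 1 is a 200 mm diameter x 32 mm cylinder holding the four
solid/part-solid lesions in quarter sectors; phantom 2 is 150 mm x 40 mm
with the two ground-glass lesions in half sectors, extended by a
water-equivalent ring. Both sit inside a solid-water outer ring (230 mm
assembly diameter) standing in for the body-sized holder, which also
provides the solid-water ROI. Outside the assembly is air at -1000 HU.

Lesions are rendered as ellipsoids at the sector centroids. The largest
(in-plane, tangential) semi-axis is half the lesion's maximum 3D diameter;
the radial in-plane semi-axis is 0.75 of that, and the axial semi-axis is
`min(0.45 a, height/2 - 3 mm)`. These ratios are a modeling choice — the
reference lesions are patient-derived and irregular; an ellipsoid keeps the
printed maximum diameter exact, fits the sector geometry, and gives shape
features an analytic cross-check. Part-solid lesions are a dense core
(solid-material HU) inside a shell rendered at the *part-solid material*
HU — the value the calibrated material table assigns to ROIs placed in
the homogeneous portion of such lesions — with the core volume fraction
solved so the whole-lesion mean equals the lesion's target intensity.
(Rendering the shell at the ground-glass material instead would make the
shell nearly indistinguishable from the ground-glass lesions,
contradicting both the measured part-solid material value and the
solid > part-solid > ground-glass CNR ordering the simulation is
calibrated to reproduce.) After texture is added, each lesion is shifted by a constant so
its mask mean equals the target exactly; the 2 HU fidelity band of the
generator contract is therefore met by construction, and what the
simulation varies is noise, not calibration.

Ground-truth label masks (parenchyma, water, one label per lesion) are
produced by the same rasterization; there is no segmentation step, so masks
are identical across doses, repetitions and scanners. This removes
segmentation variability from the radiomics comparison — a deliberate
difference from a physical experiment, discussed under *Limitations*.

### Background and lesion texture

Lung parenchyma receives a band-passed Gaussian random field: white noise
smoothed at a 2 mm correlation scale, with structure smoother than 8 mm
removed (difference of Gaussians), normalized to 20 HU SD. The high-pass
step matters: with fixed ROI positions, any texture power at the ROI scale
(8 mm) would bias the handful of parenchyma ROI means by several HU and the
pooled material means would no longer estimate the configured material
values; fine-scale texture keeps ROI means unbiased while still giving
first-order and texture features non-degenerate truth structure. Lesions
receive the same field at 15 HU SD, de-meaned within each lesion mask. The
20 HU / 2 mm parenchyma values are fixed design parameters; the 15 HU
lesion amplitude is the package's own choice of a realistic intra-lesion
heterogeneity that keeps lesion ROI SDs noise-dominated.

## Noise model and scan simulation

Per-dose lung-parenchyma noise is calibrated from five printed per-dose
means per scanner through the two-parameter model
`sigma^2(D) = a/D + b` — a quantum term plus an electronic-noise floor,
which is what makes the photon-counting advantage grow toward low dose.
The coefficients minimize the *worst-case* relative deviation of
`sigma(D)` over the calibration points (a Chebyshev fit, started from the
ordinary least-squares solution on `sigma^2`, which is exact whenever the
points are exactly consistent with the model). The minimax criterion is
used because the calibration contract is a uniform 5% band across all five
doses: ordinary least squares on `sigma^2` concentrates error at the
high-dose end (14% miss for the energy-integrating points), and relative
least squares still leaves 5.2% at 1.6 mGy, while the Chebyshev fit bounds
every dose at 4.5% (EIDCT) / 3.1% (PCCT).

`simulate_scan()` adds white Gaussian noise smoothed to a 1 mm correlation
length (kernel SD = half the correlation length; the reference systems'
noise power spectra are unreported, so the correlation length is a
configurable modeling choice). The field is rescaled so that the *image*
noise — the SD measured in the 8 mm parenchyma ROIs — matches
`sigma(dose)`: the injected variance is `sigma(dose)^2` minus the ROI-scale
variance contributed by the truth texture, and the ROI-scale SD of the
smoothed field is measured directly on the reference ROI discs rather than
globally (sample SDs of correlated fields inside small discs
underestimate the marginal SD by several percent, which would otherwise
bias the calibration). The field is exactly de-meaned, so adding noise
never shifts volume means. Every condition derives its seed from the study
base seed and the (scanner, dose, repetition, phantom) indices, making the
whole study bit-reproducible.

## ROI scheme and image-quality metrics

Thirteen 8 mm ROIs per slice across the two phantoms, on three central
slices: one inside each lesion, one in the parenchyma adjacent to each
lesion (radially outward along the sector bisector), and one in the
solid-water ring. "Manual placement in homogeneous regions" is
operationalized deterministically: solid and ground-glass lesion ROIs sit
at the lesion centre (the interior point farthest from the boundary);
part-solid lesion ROIs sit in the ground-glass shell — the lesion's
homogeneous subregion — at the mid-shell point, shrunk (never below 4 mm
diameter, with a warning) where the shell is thin. Voxels belong to an ROI
when their centres fall inside the disc on that slice; statistics use the
n-1 denominator.

Material HU values are pooled over lesion sizes, slices, doses and
repetitions (mean of ROI means, SE = SD/sqrt(n)). Image noise is the mean
parenchyma ROI SD per scanner and dose. CNR uses the printed formula
`(mu_lesion - mu_background) / sd_lesion` with the lesion ROI's own SD in
the denominator, signed, with magnitudes taken at the reporting level. The
per-dose CNR aggregate "over all six lesions" is computed as the mean of
per-lesion mean |CNR| (mean of ratios); whether the reference aggregated as
mean-of-ratios or ratio-of-means is unstated, so the alternative is one
`aggregate()` call away from the per-instance `cnr.csv` table. HU
stability across doses is the absolute coefficient of variation of the five
per-dose pooled means; values are flagged unstable when the mean is within
one SD of zero (the water channel lives in this regime — its CoV is a
ratio with a near-zero denominator).

## Radiomics

The extractor computes 107 features per lesion instance: 18 first-order,
14 shape, and 75 texture features (24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM,
5 NGTDM), following the harmonized (IBSI-style) definitions with 1-based
bin labels.

* **Discretization**: fixed bin width of 25 HU anchored at the in-mask
  minimum — the de facto default of the common extraction tools;
  configurable. Anchoring at the minimum makes texture features invariant
  to global intensity shifts, which the tests assert.
* **Directions**: the 13 unique distance-1 3D offsets; GLCMs are
  symmetrized; directional features are averaged at the feature level.
  GLSZM zones, GLDM dependence counts and NGTDM neighbourhoods use
  26-connectivity.
* **Shape**: surface area and mesh volume come from a marching-tetrahedra
  iso-surface (0.5 level) of the mask indicator lightly smoothed with a
  0.5 mm Gaussian. The smoothing gives sub-voxel-accurate crossings: a
  digital 10 mm ball at 0.5 mm spacing recovers the analytic volume and
  unit sphericity within 2% (asserted in tests). Maximum diameters are
  exact maxima over surface-voxel centres, computed after reducing the
  point set to per-column extremes (which provably contain every
  convex-hull vertex). Axis lengths derive from the second-moment
  eigenvalues (4 sqrt(lambda)); degenerate masks fall back to voxel-based
  values with a warning.
* Features are computed on the 1.0 mm uniform-slice grid without
  resampling; masks are exact, so shape features are cached per lesion.

Texture matrices are built in compiled code and verified in the test suite
against exhaustive brute-force enumeration (pair/run/zone/ neighbourhood
counting in plain R) on random grids up to 8^3, 100 trials, exact
equality.

Degenerate inputs are defined, not errors: a single-level region has GLCM
maximum probability 1, zero joint entropy, correlation 1 by convention,
and NGTDM coarseness capped at 1e6.

## PCA and cluster statistics

Features are z-score standardized before PCA (without standardization the
95%-variance rule is dominated by energy-like features that are many orders
of magnitude larger than the rest; a flag disables it). The PCA is fitted
jointly on both scanners' 90-point sets — the comparison needs a common
space — and per-scanner statistics are computed on each scanner's subset.
Constant features are dropped with a warning; component signs follow the
largest-loading-positive convention so runs are deterministic. The
retained dimension `m` is the smallest count reaching 95% cumulative
variance.

Within-cluster distance is the Euclidean distance of each point to its
lesion-type centroid (three clusters, pooling sizes, doses, repetitions),
reported as mean ± SD; separability is the mean of the three pairwise
centroid distances divided by the mean within-cluster distance, all
centroid pairs equally weighted, computed in the retained (unwhitened)
component space. These follow the definitions verbatim; whether the
reference standardized features, fitted jointly, or weighted centroid
pairs equally is unreported, so those are recorded here as this package's
choices rather than inferred intent.

## Statistical framework

Two-group comparisons are paired by (ROI position, slice, repetition) at
matched dose and gated on the normality of the differences: a Lilliefors
test (KS statistic against a normal with estimated mean/SD) at the 5%
level routes to a two-tailed paired t-test when normality is not rejected
and to a two-sided Wilcoxon signed-rank test otherwise (exact for n <= 25
after dropping zero differences, normal approximation with continuity
correction beyond). The "Wilcoxon Mann-Whitney" label in the reference
procedure is read as the signed-rank test because the gate is explicitly on
paired differences; the unpaired Mann-Whitney is available via
`paired = FALSE`. Lilliefors p-values come from a seeded Monte-Carlo null
(10,000 resamples) computed once per sample size and cached — exact at any
n, and cheap in simulation loops. Degenerate cases are conventions, not
errors: all-zero differences give p = 1; constant nonzero differences route
to an exact sign test. Three-or-more group comparisons (HU across doses)
use classic equal-variance one-way ANOVA. No multiple-testing correction
is applied, matching the reference analysis. Simulation checks assert the
gated procedure's type-I error at n = 39 within binomial error of 5% over
2,000 seeded trials, and its power under a 0.5 SD paired shift against the
closed-form paired-t power.

## Problem sizes, runtime and determinism

The default study rasterizes 4 truth volumes (two phantoms x two scanners,
480 x 480 x 32-40 voxels at 0.5 x 0.5 x 1.0 mm), simulates 60 noisy
volumes, measures 1,170 ROIs and extracts 180 x 107 features — five to ten
minutes end to end on a single core, with volumes held in memory rather
than round-tripped through NIfTI. The file-based path
(`generate_study()` + `import_external()`) writes NIfTI-1 volumes/masks
and a manifest CSV and is exercised on reduced grids in the tests. The
acceptance script runs the generate + measure stages only, which is all
its targets need. Every random stream derives from one base seed;
rerunning any stage reproduces its tables bit-for-bit.

## What the generator does and does not emulate

The simulator reproduces the *statistical* structure the downstream
metrics depend on: calibrated per-material HU, dose- and scanner-dependent
correlated noise, lesion geometry with printed diameters and mean
intensities, and repeated scans. It does not model sinogram-domain
physics — beam hardening, scatter, detector spectral response, helical
cone-beam geometry, or reconstruction-kernel noise power spectra — nor
segmentation variability, patient-derived lesion morphology, or
inter-scanner registration error (volumes share one frame; an
integer-shift aligner covers imported data). Passing calibration and
directional tests therefore shows the pipeline's measurements and
statistics are correct and self-consistent, not that the simulator
predicts a physical scanner's absolute radiomics values. Texture features
in particular are sensitive to reconstruction kernel and noise spectrum,
which are modeled here only through a single correlation length.
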