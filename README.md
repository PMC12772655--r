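# lungphantom

Quantitative comparison of a photon-counting detector CT (PCCT) and an
energy-integrating detector CT (EIDCT) for low-dose lung screening,
re-created as a fully synthetic, seed-deterministic simulation study in R.

Physical evaluations of this kind scan lung-lesion phantoms on both
scanners at matched doses and compare Hounsfield-unit (HU) accuracy, image
noise, contrast-to-noise ratios (CNR), and the stability of radiomic
features. The images behind such studies are rarely shared, so the
experiment cannot be re-run from data. This package instead rebuilds the
*experiment* itself: digital phantoms calibrated to the published material
HU values and per-dose noise levels, a scan simulator, and the complete
measurement pipeline, so every downstream number is reproducible from a
single seed. It is aimed at medical-imaging scientists who want a tested
reference implementation of the measurement chain (ROI statistics, CNR,
IBSI-style radiomics, PCA cluster metrics, gated significance tests) that
also runs unchanged on real NIfTI volume/mask pairs.

## The models at the core

**Phantoms.** Two cylinders: Ø 200 mm x 32 mm with four lesions
(small/large solid and part-solid) in quarter sectors, and Ø 150 mm x
40 mm with two ground-glass lesions in half sectors, extended by a
water-equivalent ring; both inside a solid-water outer ring. Lesions are
ellipsoids with the published maximum 3D diameters (22.9-62.8 mm) and mean
intensities (-94.8 to -747.4 HU), matched exactly in the mask mean;
part-solid lesions are a solid-HU core inside a shell at the part-solid
material HU with the core volume fraction solved from the material table.

**Noise.** Lung-parenchyma noise follows

```
sigma^2(D) = a / D + b        D = CTDIvol (mGy)
```

a quantum term plus an electronic-noise floor, fitted per scanner to five
published per-dose noise means by minimizing the worst-case relative error
(all five points within 4.6%). Scans add zero-mean correlated Gaussian
noise (1 mm correlation length) rescaled so the SD measured in 8 mm
parenchyma ROIs equals `sigma(D)`.

**Metrics.** Per slice, 13 ROIs (8 mm) across the two phantoms: each
lesion, adjacent parenchyma, and solid water; pooled material means,
image noise `sigma_HU,lung`, and

```
CNR_k = (mu_HU,k - mu_HU,BG,k) / sigma_HU,k
```

per lesion `k` against its parenchyma background. Radiomics: 107 features
per lesion instance (18 first-order, 14 mesh-based shape, 24 GLCM,
16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM; 25 HU fixed bins, 13 directions).
Cluster statistics in PCA space (95% variance retained): within-cluster
distance per lesion type and separability (mean pairwise centroid distance
over mean within-cluster distance). Two-group tests are paired and gated
by a Lilliefors normality test at the 5% level (paired t vs Wilcoxon
signed-rank); dose-wise HU comparisons use one-way ANOVA.

## Worked example

```r
library(lungphantom)

# calibrated noise model for the energy-integrating scanner
pts <- subset(noise_calibration_points(), scanner == "EIDCT")
fit_noise_model(pts[, c("dose_mGy", "sigma_hu")])
#> <noise_model> sigma^2(D) = 30036.4/D + 961.6  (max |rel resid| 4.52%)

# full study: 6 lesions x 5 doses x 2 scanners x 3 repetitions
report <- run_study(study_config(base_seed = 101))
report$noise_reduction[, c("dose_mGy", "reduction_pct")]
#>   dose_mGy reduction_pct
#>       20.4           2.5
#>        9.8          10.3
#>        4.9          11.6
#>        2.4          13.5
#>        1.6          14.1
```

The reduction column is the percent decrease in mean parenchyma noise of
PCCT relative to EIDCT — the photon-counting advantage grows toward low
dose, mirroring the published 3.0% (20.4 mGy) to 13.0% (1.6 mGy) pattern.
Pooled parenchyma HU on the same run recovers the calibrated values
within 3 HU (-876.5 vs -873.9 EIDCT; -874.2 vs -871.5 PCCT), mean |CNR|
orders solid > part-solid > ground-glass at every dose, and within-cluster
distances in PCA space are smaller for PCCT in all three lesion types
(e.g. part-solid 8.75 vs 9.20).

The numbered drivers under `analysis/` run the same pipeline as a
five-stage narrative (simulate/measure, image quality, radiomics,
clusters, statistics), writing tidy tables under `results/`.

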