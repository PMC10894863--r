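# lungcbir

Content-based image retrieval (CBIR) for chest CT in obstructive lung
disease, built on quantitative imaging features, with a synthetic lung
phantom generator that makes the entire pipeline testable without patient
data.

## The problem

Patients with chronic obstructive pulmonary disease (COPD) differ widely in
how much of their airflow limitation comes from emphysema, airway-wall
disease, and vascular remodelling. Given a query CT scan, a CBIR system
retrieves the database scans with the most similar *quantitative phenotype*,
so a clinician can review how similar patients looked and fared. This
package implements such a system end to end for researchers in quantitative
chest CT: feature extraction from labelled CT volumes, similarity indexing
and retrieval, and the statistical protocol for evaluating retrieval
accuracy and reader agreement.

## The features and the distance

Each scan is summarized by 22 quantitative values in four categories:

- **Emphysema extent** — EI (%LAA-950), the percentage of lung voxels below
  −950 HU, for the whole lung, right/left lung, and the five lobes
  (8 values).
- **Emphysema size** — D-slope: 26-connected components of the
  low-attenuation mask are converted to equivalent-sphere diameters
  `d = (6V/π)^(1/3)`; the absolute slope of log₁₀ N(≥d) versus log₁₀ d is
  the power-law exponent of the hole-size distribution (whole/right/left,
  3 values). Larger D-slope = smaller holes.
- **Airway wall thickness** — Pi10: radial ray casting on a 0.1 mm
  resampled cross-sectional plane finds inner/outer wall edges at their
  half-maximum crossings; √(wall area) is regressed on internal perimeter
  over generation 3–8 bronchi and evaluated at Pi = 10 mm
  (whole/right/left, 3 values).
- **Peripheral vasculature** — VN<5 mm²: vessels of cross-section under
  5 mm² are counted where they pierce the surface 12 mm deep to the pleura
  (from a 3-D Euclidean distance transform), per cm² of that surface
  (8 regions).

For retrieval, every feature is divided by its 95th percentile over the
database; for each query–entry pair a cosine distance
`d_c = 1 − u·v/(‖u‖‖v‖)` is computed per category sub-vector and the
combined distance is the unweighted mean of the four. The top-k scans with
the smallest distance are returned.

The evaluation module implements paired-query hit rates with Wilson score
intervals, median-split subgroup comparisons with Fisher's exact test
(standard two-sided and mid-p), 5-point similarity-score summaries with
query-clustered bootstrap intervals, weighted kappa, and ICC(2,1).

## Worked example

```r
library(lungcbir)

spec <- phantom_spec(seed = 1)        # two ellipsoidal lungs, ~12% emphysema
ph   <- generate_lung_phantom(spec)
ph
#> Lung phantom: 129 x 87 x 127 voxels at 1 mm
#>   535 emphysema clusters (LAA fraction 0.1246), 12 airway tubes, 56 vessels

feats <- extract_features(ph$volume, ph$masks, ph$sites, scan_id = "phantom01")
round(unlist(feats[c("EI_whole", "Dslope_whole", "Pi10_whole", "VN_whole")]), 3)
#>     EI_whole Dslope_whole   Pi10_whole     VN_whole
#>       12.465        4.690        4.595        0.553
```

The measured emphysema index (12.465%) and D-slope (4.690) equal the
phantom's voxel-counted ground truth exactly, because the truth is defined
on the realized grid. Retrieval on a zero-noise paired cohort (50
baseline/follow-up pairs plus 500 singletons, the 550-scan database
geometry):

```r
ft  <- generate_paired_feature_table(50, 500, noise_sd = 0, seed = 1)
idx <- build_index(ft[ft$role != "followup", ])
query_index(idx, ft[ft$role == "followup", ][1, ], k = 3)
#> Query P0001_f (mode = mean):
#>  rank scan_id  distance     d_EI  d_Dslope    d_Pi10     d_VN
#>     1 P0001_b 5.551e-17 0.000000 2.220e-16 0.000e+00 0.000000
#>     2   S0334 3.651e-03 0.008707 6.459e-05 9.325e-05 0.005739
#>     3   S0019 4.942e-03 0.012310 5.282e-04 1.047e-04 0.006824
```

Every zero-noise query retrieves its own baseline at rank 1 with distance
0; `pair_retrieval_rate()` reports 100% (Wilson 95% CI 92.9–100) at
k = 1, 3, 5.

A command-line front end (`inst/cli/lungcbir.R`) exposes the same pipeline
as subcommands `phantom`, `quantify`, `index`, `query`, `evaluate`:

```sh
Rscript inst/cli/lungcbir.R phantom --out phantom_out --seed 7
Rscript inst/cli/lungcbir.R index --features phantom_out/features.csv --out index.json
```

## Limitations

Segmentation of real chest CT (lungs, lobes, airway tree, vessels) is out
of scope: real data enters as a CT volume plus label masks on the same
grid (NIfTI or MetaImage), or as a precomputed feature table (CSV). Airway
measurement sites must be supplied (the phantom provides its own). The
phantom emulates geometry and attenuation, not scanner noise texture or
reconstruction-kernel effects.
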