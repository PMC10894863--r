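---
title: "Quantitative CT features and similarity retrieval in obstructive lung disease: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CT features and similarity retrieval: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters, and numerical choices
behind `lungcbir`, in the spirit of a methods supplement: what is computed,
under which assumptions, and where the design was genuinely open.

## 1. The four feature families

### Emphysema extent (EI / %LAA-950)

`emphysema_index()` reports, per region, the percentage of lung voxels with
attenuation strictly below a threshold (default −950 HU). The comparison is
strict: a voxel at exactly −950 HU is *not* low-attenuation. This matters
only on synthetic data, where exact threshold values occur; it is
documented so the boundary semantics are reproducible. EI assumes calibrated
HU; volumes are clamped to [−1100, 3100] HU on load because densitometry is
meaningless outside the physical range. Eight regions are reported: whole
lung, right and left lung, and the five lobes. The denominator is the
parenchymal lung mask; airway lumen voxels are excluded by the mask so that
intraluminal air does not inflate EI.

### Emphysema size (D-slope)

The low-attenuation mask is partitioned into connected components.
Default connectivity is 26 (full 3-D adjacency, consistent with
size-based clustering in three dimensions); 6-connectivity is exposed for
sensitivity analysis. Each component of voxel volume $V$ becomes an
equivalent-sphere diameter $d = (6V/\pi)^{1/3}$. The cumulative count
$N(\ge d)$ is evaluated at the distinct observed diameters and
$\log_{10} N$ is regressed on $\log_{10} d$ by unweighted ordinary least
squares; the absolute slope is the D-slope. A steeper slope means the
hole-size distribution is dominated by small holes.

Numerical choices:

- Clusters below twice the voxel spacing are discarded before the fit;
  single-voxel components are indistinguishable from noise at CT
  resolution.
- No binning: the fit uses the distinct observed diameters directly, with
  equal weights. On an exact discrete power law this reproduces the
  exponent to machine precision (a unit test asserts < 1e-9).
- At least two distinct retained diameters are required; otherwise an
  `insufficient data` error is raised rather than NaN.

The OLS-on-CCDF estimator is noisy in the tail (each large cluster is one
equally weighted point): across random phantoms at ~2000 clusters its
seed-to-seed standard deviation is roughly 0.15 in our design simulations.
The recovery experiment therefore uses ~5000 clusters
(see Section 5).

### Airway wall thickness (Pi10)

`measure_cross_section()` resamples the plane perpendicular to the airway
axis at 0.1 mm (a tenfold magnification relative to typical submillimeter
CT spacing) and casts 64 radial rays from the lumen centre. On each ray:

1. The wall peak is the maximum of the *first* wall passage — from the
   first rise of ≥ 250 HU above the lumen value until the profile falls
   back by ≥ 250 HU — so that a neighbouring airway further along the ray
   is never mistaken for this wall. This windowing is our guard for
   multi-structure fields of view.
2. The inner edge is the half-maximum crossing between the lumen minimum
   and the wall peak; the outer edge is the half-maximum crossing between
   the peak and the parenchyma estimate (median HU in a window 1–3 mm
   beyond the peak). Sub-step positions come from linear interpolation
   between samples. This half-maximum rule is an approximation of
   integral-based wall-edge detection, whose full operator is defined
   outside this package; the approximation is exact for symmetric edge
   profiles.
3. Rays with insufficient wall contrast (< 150 HU above lumen or above
   parenchyma) are dropped; the site fails if more than 25% of rays fail,
   and a homogeneous volume therefore fails cleanly.

The internal perimeter Pi is the perimeter of the inner-edge polygon; the
wall area WA is the shoelace area between outer and inner polygons. `pi10()`
fits √WA on Pi by OLS over measurements within generations 3–8 and reports
the fitted value at Pi = 10 mm. Detection of airway centerlines on real CT
is *not* implemented — sites come from the phantom truth or a user site
table — because the scientific content here is the measurement and the
regression, not segmentation.

### Peripheral vessels (VN < 5 mm²)

`peripheral_surface()` computes an exact anisotropic Euclidean distance
transform of the lung mask (distance of each lung voxel to the nearest
non-lung voxel) and extracts the counting surface at depth 12 mm. Two
voxel sets represent it:

- the **iso-surface**: lung voxels at distance ≥ 12 with a 6-neighbour
  below 12 — one voxel thick along the steepest axis; used for area.
- the **slab**: voxels with distance in [12, 12 + voxel); contiguous
  through its thickness; used for connectivity.

Surface area is estimated as iso-surface voxel count × mean in-plane voxel
area × 1.2028. The correction constant is the inverse of
$E[\max_i |n_i|] = 0.8314$, the mean largest normal component of an
isotropically oriented surface (Monte-Carlo over uniform orientations):
counting one voxel per steepest-axis column underestimates true area by
exactly that factor. A spherical-lung test confirms the estimate within a
few percent.

Vessel crossings are the 26-connected components of vessel ∩ slab. The
slab is used here because the one-voxel iso-surface can split a single
oblique crossing into two components (its voxels are only guaranteed
26-connected for surface normals within 45° of an axis), whereas a vessel
piercing the contiguous slab is always one component. Each crossing's area
is the count of its *iso-surface* members × in-plane voxel area — the slab
thickness would otherwise double-count — and crossings with area strictly
below 5 mm² contribute to VN, normalized per cm² of (regional) surface.
Per-area normalization is a documented interpretation: the source
quantity is reported without units, and a count per surface area is the
only scale-free reading.

## 2. Retrieval

`build_index()` stores each of the 22 features divided by its 95th
percentile over the database. The percentile estimator is linear
interpolation between order statistics (R's `quantile(type = 7)`); the
estimator is not prescribed by the source description, so the most common
default is used and documented. Normalized values above 1 are *not*
clipped (division only). A feature constant at zero would give a zero
normalizer; it is replaced by 1 with a warning.

`query_index()` computes a cosine distance per feature category (EI,
D-slope, Pi10, VN sub-vectors) and combines the four as their unweighted
mean. The combination rule was an open design point — "cosine distances
among the four feature vectors" does not say how four distances merge — and
the unweighted mean treats the four phenotype axes symmetrically; a
concatenated-vector mode (`mode = "concat"`) is exposed for comparison.
Zero-norm sub-vectors get distance 0 if both sides are zero, else 1. Ties
are broken lexicographically by scan id so rankings are deterministic.

Two cohort-geometry decisions are also documented: normalizers are
computed from the *database only* (queries held out), and query scans are
searched against the full index including their own baseline pair — the
paired-retrieval evaluation is meaningful only if the pair is findable.

## 3. Evaluation statistics

- **Hit rates.** A query hits at k if its baseline pair appears in the top
  k. Confidence intervals are Wilson score intervals; the intervals
  printed in the source tables do not match any standard binomial
  construction we could identify, so a standard, reproducible one was
  chosen. The CI values therefore differ from the printed ones; the point
  percentages match exactly.
- **Median splits.** Queries are split at the median feature value
  (`> median` vs `≤ median`, giving 25/25 for distinct values at n = 50)
  and the 2×2 hit table is tested with Fisher's exact test. Both the
  standard two-sided p and the mid-p variant are reported: for the
  published worked example (18/25 vs 12/25) the standard two-sided Fisher
  p is 0.148, while the mid-p variant gives 0.095, matching the printed
  0.09 — the reported value is consistent only with the mid-p reading, so
  both are surfaced rather than silently choosing one.
- **Score summaries.** Percent of ratings ≥ 4 and mean scores per reader,
  rank, and pooled. Interval estimates use a query-clustered bootstrap
  (default 1000 resamples, seeded): queries are resampled with
  replacement, preserving the correlation of the five ranked ratings
  within a query. This replaces a generalized-estimating-equation fit with
  a procedure that targets the same clustering with fewer unstated
  modelling choices.
- **Agreement.** Weighted kappa uses weights $|i-j|/(c-1)$ (linear,
  default) or squared, computed from the actual score values so sparse
  category sets keep their ordinal spacing; the CI is a clustered
  bootstrap. ICC is two-way random effects, absolute agreement, single
  measures — ICC(2,1) — with the standard F-based interval; a consistency
  variant is exposed. Both linear-vs-quadratic and agreement-vs-consistency
  were open choices; the defaults are the most conservative common
  readings and the alternatives are one argument away.

## 4. The phantom: what it emulates, and what it does not

`generate_lung_phantom()` builds two ellipsoidal lungs of noisy parenchyma
(Normal, mean −850 HU, sd 15 HU) inside soft tissue, with lobar
territories cut by axial planes; emphysema as non-overlapping −1024 HU
spheres whose diameters follow a truncated Pareto law; airway tubes of
known lumen radius and wall thickness per generation; and subpleural
vessel cylinders of known cross-section.

Key construction decisions:

- **Truth is defined on the realized grid.** The per-region EI, cluster
  diameters, and D-slope stored in `truth` are computed from the voxelized
  phantom, not the analytic spec, so recovery tests are exact identities
  rather than discretization-limited approximations. Airway truth (Pi, WA
  per tube, and the Pi10 regression on them) is analytic, because the
  measurement operates in continuous space via interpolation.
- **Partial-volume edges.** Airway tubes are rasterized with a one-voxel
  linear ramp at each interface, the discrete analogue of a CT
  point-spread function. A hard binary rasterization would displace every
  half-maximum edge by up to half a voxel; with the ramp, edge detection
  recovers the true radii (the ideal-annulus test at 0.25 mm agrees with
  the analytic Pi within 2% and WA within 5%).
- **Sphere packing.** Diameters are drawn first (until the target voxel
  fraction is reached), then placed largest-first by rejection sampling,
  which keeps the realized size distribution an i.i.d. Pareto sample
  (verified by a Kolmogorov–Smirnov test at α = 0.01). Sphere centres keep
  a clearance of r₁ + r₂ + 1.75·voxel so rasterized spheres can never be
  26-connected; the cluster count is then exactly the sphere count. This
  buffer limits the achievable packing: the effective occupied fraction is
  roughly double the nominal one for diameters a few voxels across, and
  specs demanding more than ~30% effective fraction fail with a generation
  error after bounded retries, as intended for infeasible requests.
- **Vessels along the depth gradient.** Each vessel cylinder runs along the
  local gradient of the depth map, sampled at a point of the 12-mm slab,
  spanning depths 3–16 mm. Ellipsoid surface normals are *not*
  distance-gradient lines, and cylinders placed along normals cross the
  counting surface obliquely near high-curvature regions, distorting
  crossing areas; the gradient direction makes every crossing
  perpendicular and unique, so the constructed crossing count is exact
  ground truth. Placement also keeps centrelines ≥ 4 mm + 2r apart
  (crossings cannot merge) and crossing points ≥ 3 mm from lobar planes
  (lobe assignment is unambiguous).
- **Defaults.** The default spec approximates the published cohort means:
  emphysema fraction 0.122 (EI ≈ 12%), 56 vessels of 1–3.4 mm² over both
  lungs (VN ≈ 0.55/cm² of the counting surface), airway generations 3–8
  with lumen radii 2.5 → 1.0 mm. The default cluster exponent is 3.5 with
  diameters from 3 voxels to 12 mm: a steeper (more cohort-like) exponent
  of ~5 concentrates nearly all diameters at the minimum, which is both
  unresolvable at 1 mm voxels and geometrically unpackable under the
  non-overlap buffer, so the default favours a regime where the clustering
  pipeline is actually exercised. The cohort-mean D-slope of ~5 additionally
  reflects a commercial tool's unpublished binning and filtering, so
  absolute agreement with it is not a meaningful target.

What the phantom does **not** emulate: scanner noise texture and its
spatial correlation, reconstruction kernels, gravity-dependent attenuation
gradients, real airway branching geometry, or merged emphysema clusters.
Passing recovery tests on phantoms therefore validates the *computational
pipeline* — thresholds, clustering, edge detection, distance transforms,
regressions, retrieval arithmetic — not robustness to real-scanner
artefacts.

The companion generator `generate_paired_feature_table()` emulates the
cohort at the feature level: baselines drawn from marginals matching the
published population (EI mean 12.2 via a lognormal matched to mean and SD,
D-slope 5.1 ± 1.5, Pi10 4.0 ± 0.8, VN 0.6 ± 0.1), follow-ups equal to
baseline plus Normal noise truncated at zero. The default longitudinal SDs
(1.0 EI, 0.15 D-slope, 0.12 Pi10, 0.02 VN) represent stable disease over a
~3-year interval, consistent with pairs selected for unchanged findings.
Synthetic reader ratings draw reader 1 from a latent score decreasing in
retrieval distance; reader 2 copies reader 1 with probability
`concordance` and otherwise draws an independent value from the same
marginal (a distance-shuffled draw), so concordance 1 gives identical
readers and concordance 0 gives kappa ≈ 0 by construction.

## 5. Problem sizes and determinism

All randomness flows through explicit seeds; the phantom generator saves
and restores the caller's RNG state. The test suite uses small phantoms
(lung semi-axes ~16–22 mm, 0.5–1 mm voxels, seconds each). The
cluster-exponent recovery experiment uses lungs of semi-axes 32×42×85 mm at
0.5 mm spacing with a 12.5% emphysema fraction, giving ≈ 5000 clusters —
enough that the CCDF estimator's seed-to-seed spread sits well inside the
±0.2 recovery band — and runs in under a minute. The retrieval experiments
use the 550-scan database geometry (50 pairs + 500 singletons). These
sizes are the package's chosen study conditions and are fixed in the test
code.

## 6. Known limitations

- Real-CT segmentation and airway site detection are inputs, not outputs.
- The half-maximum edge rule degrades for walls thinner than about two
  voxels; at 1 mm spacing, generation-7/8 tubes are measured with visible
  bias (the phantom Pi10 tests therefore run at 0.5 mm).
- Crossing-area estimates inherit ±1-voxel granularity; vessels with true
  area near the 5 mm² cut-off can fall on either side at coarse spacing.
- The published confidence intervals for retrieval rates and the published
  subgroup p value are reproduced only under documented method choices
  (Wilson intervals; mid-p Fisher), not bit-for-bit under every reading.
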