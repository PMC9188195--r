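---
title: "Models and methods behind amyquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind amyquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyquant)
```

amyquant implements the quantification layers of an amyloid-pathology
mouse study as a tested, deterministic package: 2D histology
quantification, 3D microglia soma segmentation with methoxy-X04 content
and plaque proximity, brain-wide voxelized plaque counting over an atlas
ontology, and the differential-abundance / gene-set statistics used on
FACS-sorted microglia omics. This vignette explains the procedures, the
parameters that matter, the synthetic-data model used to validate them,
and the numerical decisions taken where the underlying conventions were
genuinely open.

## 2D section quantification

The pipeline mirrors a slide-scanner macro: per channel, median smoothing
(radius in px, default 1), local background subtraction, binarization,
and a size filter; then per-ROI statistics.

**Background subtraction.** The local background operator is not uniquely
determined by the workflow it reimplements, so two standard estimators
are exposed: a rolling-ball-style grayscale opening with a flat disc
(default, radius 50 µm converted to pixels), and a Gaussian high-pass.
The opening restores any locally linear background exactly (erosion
subtracts the maximal in-disc drop, dilation adds it back) while removing
compact bright objects smaller than the disc, which is the behaviour the
examples in the test suite pin down. EBImage supplies the morphology and
the Gaussian; intensities are scaled into [0, 1] around those calls
because EBImage clamps grayscale values.

**Thresholds.** The original macro used fixed manual thresholds. Defaults
here are per-channel Otsu over a 256-bin histogram, with a numeric
override, and the resolved threshold is recorded in the output so every
run is reproducible. The positivity convention is strict
(`value > threshold`) everywhere, in 2D and 3D.

**Object filter.** "Smaller than 10 pixels" is read strictly: a 9 px
object is removed, a 10 px object survives. Connectivity for 2D objects
defaults to 8-neighbour (the common imaging-software behaviour), with
4-neighbour available; both are checked against a flood-fill oracle.

**Plaque rings and overlaps.** Plaques are dilated by a Euclidean radius
(default 10 µm; the source workflow does not state one, so it is a
recorded parameter, not an inference). Overlap percentages use
`100·|marker ∩ dilate(plaque)| / |marker|` and
`100·|plaque ∩ marker| / |plaque|`; empty denominators (sections without
signal or without plaques) return 0 with an `empty_*` flag rather than
erroring, so batch runs complete. Per-mouse summaries are unweighted
means over sections, and areas are emitted both in px and mm² because the
original averaging unit is unstated.

## 3D microglia segmentation

**Resampling.** Volumes are resampled to isotropic voxels (default
0.5 µm) by local mean pooling: exact block means for integer factors,
area-weighted box averaging otherwise. A trailing partial voxel is
dropped rather than padded, so every output voxel is a true mean.

**Background.** The background is an isotropic Gaussian smooth of the
volume (kernel parameter interpreted as the Gaussian σ, default 10 µm),
subtracted and clipped at zero. Separable kernels are renormalized at the
edges, so constant volumes map to zero up to floating round-off.

**Random-walker completion of a bipartite threshold.** Voxels above the
high threshold are microglia, below the low threshold background, and the
intermediate voxels are assigned by the random-walker formulation: solve
the combinatorial Dirichlet problem on the 6-connected voxel lattice with
edge weights `w = exp(-β (g_i - g_j)^2)` (intensities normalized to the
volume range), seeded by the two decided classes, and accept a voxel into
the mask when its foreground probability is ≥ 0.5. The study names only a
"diffusion constant of 10"; we map that number to the edge-weight
sharpness β, the one free parameter of the standard formulation. The
linear system is solved exactly (sparse Cholesky via Matrix), which makes
the symmetric-ramp phantom split at its midplane — an analytic fact the
acceptance suite checks against an independently solved tridiagonal
system. Degenerate seedings are handled explicitly: no foreground seed
yields an empty mask with a warning, no background seed a full mask.

**Soma seeding.** Local thickness is twice the distance to the object
boundary. Discretely, the Euclidean distance transform measures to the
nearest *background voxel centre*, which under-reads a rasterized
sphere's diameter by about one voxel; we therefore add the half-voxel
boundary correction, `thickness = 2·(EDT + h/2)`. With that calibration
an 8 µm sphere reads ≈ 7.6 µm and passes the ≥ 7 µm rule while a 5 µm
sphere reads ≈ 4.6 µm and fails it, matching the intended continuous
geometry. Candidates are local maxima of the thickness map (plateaus
included); peaks are then chosen greedily in descending thickness with a
≥ 10 µm exclusion radius, ties broken by column-major voxel order so runs
are deterministic. Whether the spacing rule applies to candidate regions
or final peaks is ambiguous in the source; it is implemented at the peak
level (non-maximum suppression).

**Cell assignment and classification.** Every mask voxel joins its
geodesically nearest peak — paths through face-adjacent mask voxels, the
watershed of the distance-to-peak landscape — computed by exact per-peak
Dijkstra, with ties to the smaller peak id. Labels partition the mask;
disconnected mask components without a peak stay unassigned. Methoxy-X04
positivity is overlap of ≥ 1 voxel with the methoxy surface by default;
the FACS gate this mirrors is intensity-based, so the voxel-count
threshold is exposed. Plaque proximity uses the minimum distance from any
cell voxel to the plaque surface with a configurable cutoff (default
10 µm, recorded in every summary because it is a reporting convention).

## Brain-wide plaque maps

Full-resolution per-section binary masks (0.35 µm lateral pixels by
default) are binned into a 10 µm isotropic grid with the floor mapping
`pixel i → voxel ⌊i·lateral/grid⌋`; counts are conserved exactly. Plaque
objects are connected components of the signal voxels, "adjacent and
orthogonally adjacent" read as face (6-) adjacency by default with
26-adjacency exposed. Because sections are 100 µm apart and grid voxels
10 µm, objects structurally cannot span sections — the z resolution limit
for separating plaques equals the sectioning interval, and the test suite
asserts this as a property rather than assuming it.

Each object is assigned to the atlas structure under its centroid voxel
(majority vote over its voxels is available; the source states no rule).
Densities are emitted twice: raw objects per full structure volume, and
multiplied by `section_interval / grid_voxel` to correct for the fact
that only that fraction of each structure's depth is sampled; the source
prints plaques/mm³ without stating a correction, so both variants carry a
flag. Ontology rollup sums signal, volume and counts over descendant
leaves and recomputes densities from the sums; hemisphere restriction is
equivalent whether applied before or after summarization (checked as a
property), provided structures are hemisphere-specific labels.

## Omics statistics

The analyte path: peak areas divided by their internal standard's area
and log2 transformed; features detected in fewer than 75% of samples
removed (strictly: 70% removed, 80% kept); per-sample median scaling;
per-feature ordinary least squares on `~ genotype + batch + sex (+ SV)`
with per-feature complete cases and a minimum residual-df guard (default
3, with a recorded skip reason); empirical-Bayes variance moderation; and
the significance rule "absolute fold difference of more than 20% at FDR
below 10%", evaluated symmetrically on the log scale as
`|log2FC| > log2(1.2)` with strict inequalities. The gene path filters
genes without more than ten reads in at least the minimum replicate
size, tests against a 1.2 fold-change threshold, and calls significance
at FDR ≤ 10% (inclusive). All threshold orientations are pinned by
two-sided boundary tests.

**Moderation and the fold-change threshold test.** The variance prior is
a scaled inverse chi-square fitted by moment estimation on the log scale
(digamma/trigamma moments, Newton inversion of the trigamma); posterior
variances are the usual precision-weighted combination and moderated df
add the prior df. The threshold test uses the threshold-offset moderated
t: with `a = |coef|`, `p = P(T > (a-τ)/se) + P(T > (a+τ)/se)`; at τ = 0
it reduces exactly to the two-sided moderated t (asserted to 1e-12). Both
are authored here and cross-checked in the tests against limma's
independent implementation, which agrees to ~1e-15 on shared fixtures.
Sample-quality weighting (arrayWeights in the original workflow) is
deliberately omitted — all samples weigh equally — and surrogate
variables are accepted as covariate columns, with a simple residual-SVD
estimator provided; the full iterative estimator is out of scope.

**Repeated measures.** The methoxy(+) vs methoxy(−) comparison uses
repeated measures per animal. The default here is the transparent paired
reduction (within-subject differences, then an intercept model), valid
for the balanced one-sample-per-condition design; an optional
consensus-correlation route estimates a single intra-subject correlation
from a per-feature one-way decomposition (combined on the Fisher z scale)
and fits by GLS with a block-equicorrelated covariance. The original
random-effect estimator belongs to the cited framework and is not
reimplemented.

**Gene-set scores.** Single-sample activity scores restrict to the set's
genes, centre each gene, and project samples onto the first singular
vector of the centred matrix; weights are normalized to unit L1 mass so
the score is a weighted average, and the sign ambiguity of PC1 is
resolved by orienting the score to correlate positively with the set's
mean (centred) expression profile, with the orientation recorded. The
score therefore equals the PC1 projection up to a positive scalar, which
the tests verify against a dense eigendecomposition. Sets with a single
matched gene error by default (a fallback to that gene's centred
expression is available) — silent one-gene "sets" are usually upstream
mistakes.

**Enrichment.** The running sum walks the ranking (moderated t as the
statistic), incrementing by `|stat|/Σ_set|stat|` on set members (gene
weight exponent fixed at 1, exposed) and decrementing by `1/(N−K)`
otherwise; the enrichment score is the maximum-deviation extremum and the
leading edge contains the set members at or before a positive extremum
(at or after a negative one). Permutation p-values are out of scope — the
score and leading edge are what downstream summaries need. Leading-edge
mean-t scores are computed over the union of a set's leading edges across
all displayed comparisons, so the same gene universe underlies every
comparison and scores are comparable. Overlap tests are exact
hypergeometric upper tails.

## The synthetic-data model

The generators emulate the statistical structure the analyses assume, not
the physics of microscopy. Sections and volumes are geometric phantoms —
discs, spheres and capsules rasterized by the rule *a pixel/voxel is
foreground iff its centre lies inside the primitive*, which makes truth
areas and counts integer-exact — plus a constant-or-linear background and
additive Gaussian noise clipped at zero. A configurable fraction of
microglia is placed near plaques; methoxy content fills a concentric
sphere covering a stated volume fraction of each designated cell, with
the exact rasterized overlap recorded as truth. The toy atlas is a
block-partitioned label volume under a three-level rooted ontology with
hemisphere labels, and plaques are planted only on sampled section
planes, wholly inside single structures, and non-touching, so planted
counts are unambiguous. Analyte data are
`baseline + genotype·log2FC + batch + sex + N(0, σ²)` with
missing-completely-at-random detection per feature, and peak areas are
constructed so internal-standard normalization inverts them exactly.

What passing these tests shows is that the *computations* are correct
under their stated conventions; it does not show robustness to optical
point-spread, photobleaching, registration error, realistic microglial
morphology, or non-random missingness, none of which the phantoms model.

Default generator conditions match the study designs the statistics
assume: n = 10 per group for the calibration and power analyses (the
replicate size of the methoxy sorting experiment), 200 features with
residual σ = 0.3 log2 units for the global-null calibration, σ = 0.25
for the planted-unit-effect power check, and 100 replicate null datasets.
Imaging phantoms use 0.5–1 µm voxels, 8 µm somata, and 20³–30-plane toy
atlases — sizes chosen so the full suite runs in well under a minute per
module while still exercising every rule; the acceptance script records
the problem size `n` next to every quantity it reports.

## Numerical conventions and degenerate inputs

- Strict `>` binarization everywhere; Otsu on a flat image returns the
  flat value, giving an empty mask under the strict rule.
- Dilation includes boundary pixels at exact integer radii via a 1e-12
  relative tolerance on the squared radius.
- Component labels and NMS peaks are ordered deterministically
  (column-major first voxel; descending thickness with index
  tie-breaks).
- Geodesic ties go to the smaller peak id, in both the implementation
  and the oracle definition.
- The random walker decides ≥ 0.5 as foreground; test phantoms use an
  even number of unseeded voxels so no probability sits exactly on the
  decision boundary.
- Empty overlap denominators yield flagged zeros; empty masks yield
  empty peak tables; zero peaks yield an all-unassigned labelling with a
  warning.
- All generators take explicit seeds, scope them locally, and restore
  the caller's RNG state; identical (truth, seed) pairs are
  byte-identical.
- BH adjustment and hypergeometric tails call R's `p.adjust` and
  `phyper`; the tests verify them against a hand computation and a
  combinatorial enumeration rather than re-deriving them in package
  code.

## Known limitations

Registration, stitching, deconvolution, PSF modelling, morphology metrics
(branching, Sholl), permutation-based enrichment p-values, voom precision
weights and the full surrogate-variable and random-effect estimators are
out of scope by design. File support is TIFF (float32, with a CSV
sidecar for pixel size), NIfTI for volumes and label volumes, CSV with a
type header for tables, and GMT for gene sets; NRRD is not supported by
the installed R stack, and NIfTI serves that role.
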