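---
title: "Lysosome morphometry from RI tomograms: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lysosome morphometry from RI tomograms: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lysomorph` quantifies the 3D spatial organization of the lysosomal
compartment in single suspended cells imaged by refractive-index (RI)
tomography. A healthy cell carries lysosomes spread roughly uniformly through
the cytoplasm; in lysosomal-storage phenotypes such as Niemann-Pick type C
(NPC1 loss of function) they collapse into a dense perinuclear aggregate at
one pole of the nucleus, and the nucleus itself is pushed off-centre and
flattened. The package turns a single-cell RI volume into 17 morphometric
features that capture exactly these changes, and provides the population
statistics needed to rank the features and score treatments.

This vignette records the package's own account of the methods: the models
and their assumptions, the tunable parameters with their defaults and units,
the numerical choices that matter, and the limits of what the synthetic
phantoms can demonstrate.

## Input model and coordinate conventions

The input is one tomogram per cell: a 3D scalar field of refractive index
(dimensionless, all values at or above 1) on an isotropic or anisotropic
voxel grid with known voxel size in micrometres. Arrays are stored with axis
order `(z, y, x)`; voxel centres sit at `(index - 0.5) * voxel_size` so that
centroid computations are convention-stable, and **all geometry is computed
in physical micrometres**, never in voxel units. Volumes round-trip through
multi-page 32-bit-float TIFF (one page per z slice) or raw-encoded NRRD;
NRRD carries voxel spacings in its header, TIFF does not, so reading a TIFF
requires an explicit voxel size - the package refuses to assume one.
Compartment masks are exchanged as 8-bit label volumes (0 background,
1 cytoplasm, 2 nucleus, 3 LVC).

## Segmentation

Three compartments are segmented per cell, in order.

**Cell body.** Voxels above a threshold; by default the known medium RI plus
a margin (1.334 + 0.004), with an Otsu fallback for data without a trusted
medium level. Noise just above the medium level percolates at 26-neighbour
connectivity, so one 6-connected morphological opening removes speckle
before the largest connected component is kept; cavities are filled, one
closing step smooths the surface, and above-threshold boundary voxels
removed by the opening are reclaimed. On a noiseless piecewise-constant
phantom this recovers the generative cell mask exactly.

**Rough lysosomal volume.** Lysosomes are the highest-RI structures in the
cell, so the rough LVC (lysosomal volumes' container) is the set of cellular
voxels whose RI strictly exceeds the `lvc_quantile` quantile (default 0.80)
of this cell's own RI distribution. The threshold is always per-cell:
a fixed global threshold would ignore the RI variability between cells and
between lines. By construction the rough mask holds ~20% of the cellular
voxels, deliberately more than the true lysosomal fraction; the surplus is
removed later.

**Nucleus (CSSI).** The nucleus is grown by statistical inference over
`eps`-sided cubes (default `eps = 5`, i.e. 125 RI values per cube). The
reference cube is the cube closest to the cell centroid that is fully
cellular and free of rough-LVC voxels (ties broken by lowest `(z, y, x)`
index); excluding rough-LVC voxels keeps the reference statistically
unambiguous between the nuclear and lysosomal distributions. Candidate cubes
(at least half inside the cell) join the region when a two-sample
Kolmogorov-Smirnov test cannot distinguish their in-cell RI sample from the
reference sample at level `cssi_alpha` (default 0.05), with 6-connectivity
to the growing region enforced so the nucleus stays a single region. After
each pass the reference sample is re-pooled from the accepted region
(deterministically subsampled to at most `10 * eps^3` sorted values) and
growth repeats until stable or `cssi_max_iter` (default 10) passes. The
underlying statistical-region-growing literature does not fix the test
statistic in a way this package could reuse directly; the KS choice is a
documented surrogate - it compares whole distributions, which matches the
intent of testing "statistical relations among RI patterns", and it needs no
distributional assumptions.

Cube-level acceptance only ever admits cubes entirely inside the nucleus, so
the raw union underestimates the boundary by up to a cube diagonal. A
voxel-level recovery step therefore grows the region by 6-connected steps
(at most `eps` of them) into cellular voxels whose RI lies in the central
`cssi_refine_band` (default 0.9) quantile band of the reference sample. On
noiseless phantoms the band collapses to the exact nuclear RI and the
recovered boundary is voxel-accurate; with the default noise the nucleus
Dice stays above 0.9. Post-processing keeps the connected component
containing the reference cube, fills holes and applies one closing. If the
accepted region exceeds 70% of the cell the result is flagged
(`nucleus_floods_cell`): that is the signature of a nucleus with no RI
contrast against cytoplasm, where this method cannot work.

**Refinement.** The adaptive threshold also catches the brightest nuclear
voxels, so the final LVC is the rough mask minus the nucleus, with connected
components smaller than `min_component_voxels` (default 27, one 3x3x3 cube)
discarded as noise. An empty LVC is legal and flagged, never fatal: real
degenerate cells occur and should produce flagged rows, not abort a run.

## The 17 features

Features are grouped into three biomarkers - lysosome-nucleus (7),
nucleus-cell (5), lysosome-cell (5) - and tagged Cartesian or spherical by
the frame they are computed in (`feature_registry()` is the authoritative
table). The two headline lysosome-nucleus features:

* **NLNSA** (normalized lysosome-nucleus solid angle): the fraction of the
  full `4*pi` sphere of directions from the nucleus centroid subtended by
  the LVC. The sphere is partitioned into 1280 approximately equal-area
  cells (an 8-fold subdivided icosahedron; directions are assigned to the
  nearest cell centre, i.e. the spherical Voronoi of the cell centres); a
  cell is occupied when at least one LVC voxel-centre direction falls in it.
  1 means lysosomes fully surround the nucleus, values near 0 mean one-pole
  accumulation. Voxel centres (not voxel solid bodies) define occupancy;
  at the package's working resolutions the difference is below the binning
  resolution. Refining the partition to 5120 cells moves NLNSA by less than
  0.03 on phantoms, and the statistic agrees with a Monte-Carlo ray-casting
  estimate of the subtended solid angle to within 0.02.
* **HLVR** (half-nuclear lysosome volume ratio): the plane through the
  nucleus centroid orthogonal to the nucleus-to-LVC-centroid segment splits
  space in two; HLVR is the fraction of LVC volume in the half containing
  the LVC centroid (the "+" half, which is the reported number; the "-"
  complement is exported as an auxiliary). 0.5 means a balanced surround,
  1 a fully one-sided aggregate. If the two centroids coincide within
  1e-9 um the direction is undefined and 0.5 is returned by convention.

Angular-distribution divergences are reported as **PSSE** (percentage sum of
squared error): voxel centres of two compartments are converted to spherical
coordinates about a common origin (nucleus centroid for lysosome-nucleus and
lysosome-cytoplasm variants, cell centroid for nucleus-cell); azimuth is
histogrammed in 36 uniform bins, elevation in 18 bins uniform in
`sin(elevation)` - equal solid angle per bin, so an isotropic cloud is flat
in both histograms and a naive pole-area artifact is avoided; histograms are
normalized to unit sum and `PSSE = 100 * sum((p - q)^2) / sum(q^2)` with the
second compartment as reference; the combined Az-El value is the sum of the
two coordinates' PSSEs. The exact formula behind the published variant is
not available; this normalized form is a documented surrogate, and the
feature registry is pluggable so a replacement drops in without API change.

The remaining features are ratios and moments in physical units: centroid
displacements normalized by the cell equivalent radius
`(3 V / 4 pi)^(1/3)` (NNCCD, LNCCD, LCCCD), volume fractions (NCVR, LVF),
mean radial statistics (LRM, LNRG, NRP - the latter normalized by the
directional cell radius along the displacement, found by ray marching),
nucleus sphericity `pi^(1/3) (6 V)^(2/3) / A` with the surface area
estimated from exposed voxel faces corrected by the factor 2/3 (the
staircase bias of a digitized smooth surface), and LVC compactness LCMP =
volume over convex-hull volume. No convex-hull library is available in the
package's dependency footprint, so the hull volume is computed against a
circumscribing support polytope with 320 well-spread facet directions
(subdivided-icosahedron directions); the polytope contains the hull, so the
approximation slightly inflates the denominator - a bias of a few percent
for blob-like shapes, identical across cells and therefore immaterial for
ranking and comparisons. Centroids are unweighted voxel-centre means: masks,
not intensities, define compartments. An empty LVC turns every LVC-dependent
feature into `NA` and flags the row.

## Population statistics

* **Ranking**: per-feature Fisher discriminant ratio
  `FDR = (mean_A - mean_B)^2 / (var_A + var_B)` with sample variances - the
  classic two-class form - plus average FDR per biomarker and per frame.
  Zero pooled variance yields 0 (equal means) or a flagged `Inf`.
* **Comparison**: percentage variation of medians
  `PV = 100 * (median_treated - median_control) / median_control` (undefined
  and flagged when the control median is 0; signs flip when the roles swap),
  with a two-sided Mann-Whitney U test per feature: exact for small untied
  samples, normal approximation with tie correction otherwise (base R's
  `wilcox.test` semantics). p-values are reported per feature without
  family-wise correction, mirroring per-panel annotation practice; a
  Benjamini-Hochberg column is added and labelled as an extension.
* **Embedding**: all features are z-scored over the pooled table (mean 0,
  unit variance per column), all cells of all conditions are embedded
  jointly in 2D by t-SNE, and treatment effectiveness TE is the Euclidean
  distance between condition centroids in embedding space. The embedding is
  an exact-gradient t-SNE (perplexity 30 by default, automatically reduced
  with a warning when `3 * perplexity > n - 1`; PCA initialization; early
  exaggeration 12 for 250 of 1000 iterations; learning rate 200), written
  for desk-scale populations where the O(n^2) gradient is cheap and the run
  is deterministic given the recorded seed. t-SNE distances are not
  metric-faithful: absolute TE values are reproducible per seed only, and
  only orderings between TEs are scientifically meaningful.

## The phantom generator

Every stage is testable without microscope data through a synthetic
generator with exact ground truth. A phantom is a quasi-spherical cell in
medium: an ellipsoidal cell body (nominal radius 7.5 um with +/-5% per-axis
jitter), a quasi-spherical nucleus (radius 3.5 um), and lysosomal blobs
(default 60, mean radius 0.4 um, +/-30% jitter) whose directions from the
cell centre follow a von-Mises-Fisher-style distribution about a random pole
axis with concentration `kappa`: 0 gives the isotropic wild-type-like
arrangement, large values (clamped at 50) the one-pole NPC-like aggregate.
Radial blob positions are uniform in the cytoplasmic shell between the
nucleus surface and 0.9 cell radius; overlapping blobs merge by voxelwise
OR, matching the "container of unresolved aggregates" concept. The KO-like
preset couples `kappa = 8` with a nucleus displaced opposite the pole by 0.3
cell radii and flattened to 0.75 along it, reproducing the
nucleus-pushed-to-the-membrane morphology of the polarized phenotype.
A shell mode replaces the blobs with a complete concentric spherical shell
for analytic solid-angle cases.

Compartment RI levels default to medium 1.334, cytoplasm 1.355, nucleus
1.345, lysosome 1.395 - literature-typical values for HeLa-like cells (no
authoritative per-compartment values exist for this system), with the
ordering lysosome > cytoplasm > nucleus > medium enforced so lysosomes are
the brightest structures. Noise is i.i.d. Gaussian with sd 0.004 RI. The
generator is seed-deterministic down to the bit level, and
`generate_population()` derives per-cell seeds from one master seed.

Population generation jitters each cell's radii (+/-8%), `kappa` (+/-50%),
nucleus displacement (+/-50%) and flattening (+/-15%), all multiplicative
and uniform. The wide half-ranges are deliberate: single-cell feature
distributions overlap heavily between phenotypes in real populations, and
point-mass phantom conditions would make separability statistics
meaninglessly easy. A preset with a zero-valued parameter stays exactly
zero under multiplicative jitter.

What the phantoms do *not* emulate: imaging physics. There is no point
spread function, no missing-cone anisotropy, no reconstruction artifacts,
no spatially correlated noise, and no multi-cell fields of view. Passing
tests on phantoms therefore demonstrates the correctness of segmentation,
morphometry and statistics given tomograms whose compartments differ in
mean RI - not robustness to reconstruction artifacts of any particular
instrument.

## Problem sizes and numerical details

The test-suite and acceptance computations run at desk scale: 72^3 voxels at
0.15 um (cell radius 4.2 um, nucleus 2.0 um, 40-60 blobs of 0.4 um), which
preserves every geometric ratio of the full-scale defaults (128^3, cell
7.5 um) - in particular the ~5-voxel blob diameter and ~27-voxel nucleus
diameter - while a cell generates and segments in under a second. The
segmentation parameter-recovery check runs 20 + 20 noisy phantoms at 96^3
(cell 5.5 um, 60 blobs) and requires median Dice at least 0.8 for the
nucleus and 0.75 for the LVC; the polarization ladder for
treatment-effectiveness monotonicity uses `kappa` in {0, 2, 8} with 50 cells
per rung.

Deterministic tie-breaks and degenerate paths worth knowing: the quantile
threshold uses a strict `>` comparison (at a noiseless piecewise-constant
input this keeps exactly the voxels above the plateau value); the reference
cube tie-break is lexicographic in `(z, y, x)`; a CSSI run whose acceptance
never leaves the reference cube warns and returns the flagged
reference-cube-only nucleus; `kappa` is clamped at 50, where the von
Mises-Fisher cap half-angle is well under 30 degrees; adding a constant to
all RI values leaves every mask unchanged in Otsu mode (and every stage
after the cell mask unconditionally, since the LVC quantile and the CSSI
tests are distribution-relative).

## Known limitations

* The CSSI test statistic, the PSSE normalization and the exact membership
  of the published 17-feature set are reconstructed surrogates where the
  original definitions were not available; the feature registry isolates
  them so exact definitions can replace them without touching callers.
* CSSI requires RI contrast between nucleus and cytoplasm; the no-contrast
  failure mode is detected and flagged, not solved.
* The rough-LVC quantile deliberately over-segments cells whose true
  lysosomal fraction is far below 20%; the component-size filter removes
  most of the surplus, but a few speckle clusters can survive in noisy
  low-LVC cells, which bounds the LVC Dice near 0.8 rather than 1.
* Absolute published population values (average FDRs, PV percentages, TE
  distances) depend on a specific unreleased dataset and are out of scope;
  phantom-based checks assert signs, orderings and analytic limits only.
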