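---
title: "Estimating virtual ancestral cranial shapes on dated phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating virtual ancestral cranial shapes on dated phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoshape)
```

## The problem

Given dense 3D landmark configurations digitised on crania of living
populations and fossil specimens, and a dated phylogenetic hypothesis
(a chronogram, branch lengths in thousands of years, ka), `paleoshape`
estimates the most likely shape of any internal node of the tree — a
"virtual last common ancestor" (vLCA) — together with a confidence
envelope, renders it by warping a reference skull mesh, and compares real
specimens against the estimated ancestors in ordination and distance
analyses. The package also contains a synthetic-data generator producing
tree-structured landmark datasets with known truth, so that every stage of
the chain can be validated without access to restricted specimen data.

## The model

### Shape variables

Specimens are $k \times 3$ landmark configurations. Superimposition is
classical Generalized Procrustes Analysis: translation removed by
centering, size by scaling to unit centroid size
$CS = \sqrt{\sum_i \lVert x_i - \bar{x} \rVert^2}$, orientation by optimal
proper rotations (SVD with determinant correction, so reflections — which
would invert anatomical chirality — are never applied). The consensus is
the iterated mean, and the final sample is put in a canonical frame (the
consensus principal axes with a deterministic sign rule) so results do not
depend on specimen order or input orientation. Analyses run on Procrustes
residuals directly; the tangent-space projection is omitted, which is
standard in the small-variation regime of within-genus cranial data.

Semilandmarks on curves slide along the local tangent (central difference
of chain neighbours) and semilandmarks on surfaces within the local tangent
plane (least-squares plane of their declared neighbours). Displacements for
one specimen are solved jointly, in closed form, to minimise the
thin-plate-spline bending energy between the specimen and the sample
consensus; sliding and GPA alternate for `iterations` rounds (default 3).
Minimum Procrustes distance is available as an alternative criterion
(`method = "procrustes"`). Tangent-plane relaxation is not followed by
re-projection onto an actual mesh surface: the package operates on
landmarks, meshes are optional carriers — a documented limitation. Sliding
is done before symmetrization, and against the consensus rather than a
fixed reference; neither choice is dictated by the data model, both are the
common default of the tool family, and both are exposed as parameters
(`iterations`, `method`).

Sliding deliberately re-parameterizes semilandmarks along their tangent
directions, so after sliding a configuration is only defined up to
tangential repositioning. When a slid estimate must be compared against an
external configuration in coordinates — a new specimen, or a simulation's
known truth — the external shape should first be relaxed into the same
correspondence with `relax_to_reference()`; comparing raw coordinates
instead mixes this benign re-parameterization into the apparent error.

Bilateral asymmetry is removed by the symmetric component: each
configuration is paired with its mirrored, relabelled copy, all copies are
superimposed jointly, the joint consensus is oriented so its mid-sagittal
plane is exactly $x = 0$, and each specimen's two aligned copies are
averaged. The implementation guarantees *exact* symmetry of the output
(paired landmarks mirror across $x=0$ to machine precision) because the
consensus is projected onto the symmetric subspace before the final
alignment.

Missing landmarks are imputed in two stages: reflection of a preserved
bilateral partner across the least-squares mid-sagittal plane of the
preserved midline landmarks, then thin-plate-spline interpolation from a
complete template for whatever remains. The TPS uses the 3D kernel
$U(r) = r$ with an affine part and solves the standard bordered system
exactly (no smoothing). With this kernel the upper-left block of the
inverse bordered matrix is negative semidefinite; the package's bending
energy form is its negation, which is zero exactly on affine maps.

With landmark-independent within-population noise, no imputation method
can predict a specimen's own noise at unobserved landmarks; imputed
positions recover the *population mean* at roughly the within-population
noise scale, which is the relevant guarantee for downstream mean-shape
analyses.

### Ancestral estimation

Population mean shapes are decomposed by PCA; all non-zero components are
carried (only displays are restricted to the first three). Each PC score
evolves independently on the chronogram under Brownian motion. For tips
$y$ with phylogenetic covariance $C$ ($C_{ij}$ = shared root-to-MRCA path
length), the ML root state is the GLS estimator

$$\hat a = (\mathbf{1}^\top C^{-1}\mathbf{1})^{-1}\,\mathbf{1}^\top C^{-1} y,
\qquad
\hat\sigma^2 = \frac{(y-\hat a\mathbf{1})^\top C^{-1}(y-\hat a\mathbf{1})}{N}.$$

Every internal node is estimated by re-rooting at that node; the re-rooted
covariance is obtained directly from patristic distances,
$C^{(x)}_{ij} = \tfrac12\bigl(d(x,i)+d(x,j)-d(i,j)\bigr)$, which avoids
mutating the tree. The node variance is
$\hat\sigma^2 (\mathbf{1}^\top C^{(x)-1}\mathbf{1})^{-1}$ and the 95%
envelope is $\pm 1.96$ standard errors. The re-rooted estimates equal the
joint ML of all node states under the BM likelihood (verified against
brute-force numerical maximization in the test suite). $\hat\sigma^2$ uses
the ML divisor $N$; REML ($N-1$) is available via `reml = TRUE`. Fossil
(non-contemporaneous) tips simply enter with their true, shorter
root-to-tip path lengths.

Node score vectors are rotated back to landmark space
(mean $+$ scores $\times$ eigenvectors) and rescaled to unit centroid size,
since all reported distances are shape-space quantities and the model
carries no information about ancestor size. A reference mesh is warped onto
the ancestral landmarks by TPS to render the vLCA. Confidence envelopes are
drawn as axis-aligned ellipses in PC pairs because per-PC variances are the
only uncertainty the estimator yields.

Note one approximation worth knowing: changing the phylogenetic hypothesis
*inside* one clade (e.g. where the Oceanian branch attaches) does perturb
estimates at nodes outside that clade, because every node's GLS weights
involve all tips. The effect is two or more orders of magnitude smaller
than at the affected nodes — locality holds approximately, not as an
identity.

### Phylogenetic signal

The multivariate K statistic compares observed to Brownian-expected
partitioning of variation on the tree,

$$K = \frac{\operatorname{tr}(Z^\top Z)\,/\,\operatorname{tr}(Z^\top C^{-1} Z)}
{\bigl(\operatorname{tr}(C) - N(\mathbf{1}^\top C^{-1}\mathbf{1})^{-1}\bigr)/(N-1)},
\qquad Z = Y - \mathbf{1}\hat a,$$

with $K = 1$ the BM expectation ($K = 1$ exactly on unit-branch star
trees, where $C = I$). Significance comes from permuting tip rows;
$p = (1 + \#\{K_\text{perm} \ge K_\text{obs}\})/(1 + n_\text{perm})$ with
999 permutations by default and a mandatory explicit seed.

### Comparison analyses

Four landmark subsets (A–D) emulate the preservation of key fossils: on
the full 780-landmark template they contain 255 (full skull), 148
(calvarium), 112 and 181 landmarks; on other templates the counts scale
proportionally. Each analysis re-runs GPA on the restricted raw
coordinates (restricting *after* alignment is not the same thing, and is
deliberately not done), with the vLCAs and fossil stand-ins included in
the superimposition but "passive" — given no group. Between-group PCA is a
PCA of the unweighted group mean shapes centred on the mean of means;
individuals and passive specimens are projected onto the $g-1$ axes. Group
means live entirely in that subspace, so their score-space Euclidean
distances reproduce their full shape-space distances exactly. Distance
tables and per-group Procrustes-distance summaries (boxplot statistics)
are exported as labelled CSV.

### Surface deviation

Mesh-to-mesh differences are summarised vertex-wise: either the exact
nearest point on any reference triangle (point–triangle projection, no
approximation) or index-wise corresponding vertices for meshes sharing
provenance (two warps of the same model). Distances are signed by the
reference's area-weighted outward vertex normal interpolated at the match:
positive = outside. The report carries the signed per-vertex distances, a
50-bin fixed-width histogram, maxima and means per sign, and the standard
deviation, in mm. Both per-sign maxima are reported since a single
"maximum deviation" bound is ambiguous. Meshes are assumed pre-aligned (in
this pipeline ancestral landmark configurations are GPA-aligned before
warping); no ICP is performed.

## The built-in phylogeny presets

Four chronograms cover the working hypotheses for the genus *Homo*: `h1`
and `h2` with 29 tips — an early-*Homo* outgroup (*H. habilis*,
*H. ergaster*, *H. georgicus*), four Neandertal groups
(Early, (Near-East, (South-Europe, West-Europe))), early *H. sapiens*
(tip age 100 ka) and 21 extant populations — plus reduced variants
`h1b`/`h2b` (25 tips) without the San, Khoikhoi, Bayaka and Mbuti
populations. Dates stated by the underlying chronology: modern–Neandertal
split 600 ka, Neandertal clade root 300 ka, modern clade root 305 ka, the
Oceanian split from the African clade at 90 ka in `h1`, and the
non-African split at 75 ka in `h2`.

The remaining node ages are not fixed by any single source and were chosen
once as chronology-range midpoints (fossil tips) and population-genetics
consensus values (extant structure): tree root 2000 ka; outgroup clade
1900/1820 ka with tip ages *habilis* 1800, *ergaster* 1550, *georgicus*
1770 ka; Neandertal subclade nodes 150/100 ka with tip ages 195/50/53/55
ka; extant crown 280 ka, Khoisan and Pygmy crowns 110/120 ka, successive
African splits 220/180/150/120 ka, East-African pair 70 ka, Eurasian
structure 60/50/45/35/25/20/10 ka (with the Oceanian crown at 40 ka, and
an extra node at 47 ka in `h2` where Oceania nests inside Asia). These are
presets of convenience for simulation and method validation, not
chronological claims.

## The synthetic-data generator

`make_template()` builds an exactly bilaterally symmetric, skull-scale
point cloud on a 70 × 90 × 65 mm ellipsoid: by default 56 fixed landmarks
(8 on the midline), 4 curve chains of 29 points on the anterior (facial)
region, and 608 surface semilandmarks on the upper (calvarial) region with
6-nearest-neighbour tangent graphs — 780 landmarks, matching the dense
cranial template's proportions. `simulate_dataset()` evolves this base
shape by Brownian motion along a preset chronogram (each coordinate
independently, increment variance = rate × branch length), then draws
individuals around each tip mean with isotropic landmark-independent noise.

Default conditions emulate the study structure: preset `h1`, 10
individuals per extant population (the real sample has 245 specimens over
21 populations), a single individual for each fossil tip, rate
0.004 mm²/ka and within-population standard deviation 1 mm per
coordinate. On the ~2100 mm-centroid-size template these produce
Procrustes distances of a few hundredths of shape units between deep
clades — the magnitude reported for real *Homo* crania. Regeneration from
a seed is bit-identical, and datasets serialize to CSV + Newick + YAML +
JSON manifest.

What the generator does *not* emulate: spatially correlated
within-population variation, integration between anatomical modules,
bilateral symmetry of the evolving means (BM increments are per-coordinate
independent, so simulated taxa are measurably asymmetric), digitisation
error structure, or allometry. Passing tests on these data therefore
validate the estimation machinery — superimposition, sliding,
symmetrization, GLS ancestral estimation, calibration of envelopes — not
the biological fidelity of any particular reconstruction.

## Numerical choices

* GPA converges when the summed squared residual changes by less than
  1e-10 (cap 100 iterations; non-convergence warns, never silently).
* The canonical frame uses principal axes with an index-weighted third
  moment as the sign rule — an odd functional that survives bilateral
  symmetry, where plain coordinate skewness vanishes.
* TPS systems are solved by QR with one step of iterative refinement;
  interpolation residuals at controls stay below 1e-8. Duplicated or
  coplanar controls raise errors naming the offending points.
* The sliding system matrix is the bending-energy form restricted to the
  tangent subspace (`Be[i,j] * (u_a . u_b)`); a relative ridge of 1e-10
  guards rank deficiency. Chain endpoints and degenerate (zero-length)
  tangents leave landmarks unmoved, the latter with a warning.
* bgPCA axes and shape-PC axes canonicalize sign by making the
  largest-magnitude loading positive, so repeated runs are bit-identical.
* Kmult requires an explicit permutation seed; all generator functions
  take seeds and restore the caller's RNG state.

## Problem sizes used in validation

The packaged tests run the full chain at the study scale — 29 taxa,
780 landmarks, 10 individuals per extant taxon (218 configurations),
three sliding iterations — once per point of a three-point Brownian-rate
grid, and use reduced templates (40 landmarks) with 20 replicates for the
rate-monotonicity property and the distributional checks (200 simulations
for envelope calibration, 100 for K calibration, 500 for permutation
uniformity). These sizes give stable Monte-Carlo estimates of the
quantities being checked while each suite run stays reproducible from a
single seed.

One regime caveat: recovery error beats tip dispersion whenever the
between-taxon Brownian signal dominates the fixed within-population noise
floor (as it does at the default rate); if the rate is pushed far below
that level the dispersion shrinks with it while the noise floor does not,
and the comparison inverts — a property of the regime, not of the
estimator.

## Known limitations

* Ancestral estimates are weighted averages of tip data under BM: they
  cannot recover apomorphies of unsampled lineages, and long isolated
  branches dominate nearby nodes.
* Slid semilandmarks relax in tangent planes without re-projection onto a
  surface; for very coarse meshes this can pull points slightly off the
  anatomy.
* Between-group PCA with many variables and few groups can exaggerate
  separation; the package reports variance fractions and full-space
  distances so users can judge, but applies no correction.
* The surface-deviation sign convention (positive = outside the reference)
  is a convention; per-sign maxima are both reported for that reason.
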