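---
title: "Assessing density fits: models, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing density fits: models, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoscore)
```

## The problem

At intermediate-to-low resolution (roughly 5–20 Å), a cryo-EM
reconstruction rarely determines the placement of an atomic model
uniquely. Rigid fitting programs return many plausible placements, and
flexible fitting can overfit locally. `cryoscore` addresses the
*assessment* side of this problem: given a target density map and one or
more candidate placements of a model, quantify the agreement with a
family of complementary goodness-of-fit scores, cluster alternative fits
by how different their placements actually are, and aggregate scores into
a consensus ranking. No fitting is performed here; fits come either from
the built-in local perturbation generator or from external programs.

## Data model and conventions

A `density_map` is a cubic-voxel scalar grid with an isotropic spacing
`apix` (Å/pixel) and an `origin` giving the real-space position of the
*center* of the first voxel; voxel `[i, j, k]` sits at
`origin + apix * (i-1, j-1, k-1)`. CCP4/MRC files are read in modes 0, 1
and 2, honouring the machine stamp and the MAPC/MAPR/MAPS axis
correspondence, and always written canonically (mode 2, x-fastest,
little-endian). Anisotropic cells are rejected because every score below
assumes a single spacing. The voxel containing an atom is found by
rounding to the nearest voxel center.

An `atomic_structure` is an ordered atom table with masses from a fixed
internal element table (unknown elements fall back to carbon with a
warning). C-alpha RMSD between two placements is computed **without
superposition**: all fits live in the frame of the map, so RMSD measures
placement differences, which is exactly what fit clustering needs.
Superposing first would collapse all rigid placements of the same model
to zero.

## Simulating maps from models

`simulate_map()` places an isotropic Gaussian at each atom with standard
deviation `sigma = sigma_factor * resolution` (default sigma factor
0.225, the convention of the widely used map simulators) and amplitude
proportional to atomic mass, summed on a grid spanning the structure
plus a padding of twice the resolution. Mass weighting (rather than
uniform or atomic-number weighting) is a deliberate choice: it makes the
simulated intensity scale with scattering mass and keeps the volume
threshold (below) consistent with molecular weight. Gaussians are
truncated at 3 sigma; the omitted tail is below `1.2e-4` of the peak, so
oracle tests that ignore truncation bound their tolerance accordingly.
The default grid spacing is `resolution / 3` capped at 3.5 Å/pixel;
coarser grids undersample the Gaussian and are refused unless forced.
Intensities are not rescaled globally — CCC is affine-invariant and MI
sees only bin assignments, so normalisation would be cosmetic.

Two-map scores require a common grid; `resample_on_grid()` interpolates
the probe trilinearly at the target's voxel centers (exact on linear
fields, zero outside the probe's extent).

## The scores

Polarity differs by score: CCC, SCCC, LAP, MI, SMI and ENV are
better-when-larger; NV, NV-S and CD better-when-smaller. All scores are
deterministic.

**CCC** is the Pearson correlation of voxel intensities over the full
common grid. The full-grid definition is the primary one; a voxel mask
is exposed because experimental maps are background-dominated and a
region-restricted correlation is often the quantity of interest.
**LAP** is the CCC of Laplacian-filtered maps (6-neighbour stencil,
edge-replicating padding), which emphasises edges and is useful at
resolutions worse than ~10 Å.

**MI** bins each map independently into 20 equal-width levels over its
own intensity range (the conventional bin count for EM maps) and
computes the relative entropy between the joint and product
distributions. We report **bits** (log base 2); the base is a unit
choice only. `MI(m, m)` equals the binned entropy of `m`, which is the
maximum achievable against that target — this is why the generating fit
of a simulated map provably tops an MI ranking.

**SCCC / SMI** localise CCC and MI to one structural segment: the whole
model is blurred, and the score is evaluated only on voxels where *the
segment's own* blurred density exceeds its volume threshold (1.21 Å³
per Dalton of the segment mass). Blurring the segment alone to define
the mask is a concrete, testable rule; alternatives (e.g. fixed-radius
atom masks) differ mainly in how much neighbouring density leaks in.

**ENV** binarises the target at a threshold and counts `+1` for each
atom inside the envelope, `-2` per atom outside it (protrusions hurt
twice as much as a filled voxel helps) and `-1` per envelope voxel with
no atom within one voxel (Chebyshev) radius. The weights are exposed as
configuration; the defaults implement the asymmetric
protrusion/empty-space penalty the score is meant to encode.

**Volume threshold.** Surface-based scores need a density contour. We
use the level enclosing the molecule's expected volume at 1.21 Å³/Da —
the standard protein partial specific volume — computed once per target
per scoring run so every member of an ensemble is assessed against the
same envelope; each probe map gets its own threshold at the same volume.

**NV / NV-S.** The surface is the set of voxels at or above threshold
with at least one 6-face neighbour below it (out-of-grid counts as
below; 6-connectivity is the simplest definition an independent oracle
can reproduce exactly). Normals are the negated local density gradient,
unit-normalised: central differences by default, or — for NV-S — the
separable Sobel responses (`[1, 0, -1]` differentiation, `[1, 2, 1]`
smoothing) computed after zeroing densities below the threshold, which
concentrates the response on the envelope edge. Surface voxels with a
vanishing gradient carry no orientation and are dropped. Each target
surface point is paired with the *nearest* probe surface voxel
(Euclidean, ties to the lowest index); the score is the mean
`arccos(a·b)` over pairs, in `[0, pi]`, with the dot product clamped to
`[-1, 1]` before `arccos` for floating-point safety. Averaging is
target-driven (not symmetrised) so the score asks "is the target's
surface explained by the probe?". The original 3SOM-style normal
estimation is not reproducible from its description; the gradient
normal is a deterministic, oracle-checkable stand-in and is flagged as
such.

**CD** is the mean real-space distance from each probe surface point to
its nearest target surface point — intentionally asymmetric, and exactly
zero only when the probe surface lies on the target surface.

## Ensembles, clustering, consensus

`generate_local_ensemble()` perturbs the current placement: rotation
axis uniform on the sphere, angle uniform on `[0, max_rot]`, translation
direction uniform with magnitude uniform on `[0, max_trans]`, about the
center of mass; the canonical local-search bounds are 10 Å and 60°. The
unperturbed `model_0` is always member one. Uniform axis/angle is *not*
the uniform distribution on SO(3); for perturbative use the simple
scheme is preferable because the angle bound is exact and the marginal
distributions are obvious. Everything is reproducible from one integer
seed, and generation restores the caller's RNG stream.

Clustering is agglomerative on the pairwise C-alpha RMSD matrix of the
`top_k = 20` best fits under a chosen score. Complete linkage is the
default because it gives the flat cut an interpretable meaning — every
cluster has diameter at most the cutoff; single and average linkage are
available. The data-driven cutoff (`"mean-top20"`) is the mean pairwise
RMSD of those top fits. The *top cluster* is the non-singleton cluster
containing the best-ranked fit among fits in non-singleton clusters; if
the cut produces only singletons this is flagged rather than forced.
Whether to cluster only the top fits or the whole ensemble with a
top-20-derived cutoff is genuinely ambiguous; both are supported
(`top_k = Inf` clusters everything), with top-k-only the default since
the dendrogram of 20 fits is what one inspects in practice. Merge ties
are broken deterministically.

The Borda consensus gives fit `j` points `N - r_ij` for its rank `r_ij`
under score `i` and sums over scores; fits are re-ranked by descending
total. Within-score ties share the mean fractional rank (making the
points invariant to input order), and final ties break lexicographically
by fit id. The alternative `N - r + 1` convention differs by a constant
per score and induces the same ordering; both are available.

## The synthetic benchmark, and what it does not show

`make_toy_structure()` builds a poly-alanine with ideal helical C-alpha
geometry (2.3 Å radius, 1.5 Å rise, 100°/residue — the canonical 3.8 Å
C-alpha spacing) and five heavy atoms per residue at chain-following
offsets; the `"two-domain"` motif adds a seed-controlled hinge of
10–45°, emulating a conformational-change case.
`make_benchmark_case()` blurs such a structure into a target map and
surrounds the true placement with a random local ensemble (10 Å / 60°
bounds). The package's own benchmark scale — used in the test suite and
the acceptance script — is a 40-residue helix, 50 random fits plus
`model_0`, at 10 and 20 Å resolution; at that scale the whole
score–cluster–consensus pipeline runs in seconds.

Passing the self-fit benchmark shows that the pipeline's mathematics and
bookkeeping are right: the generating fit provably maximises CCC and MI
and zeroes NV-S against its own simulated map, so any other outcome
would be a defect. It does **not** show that the scores discriminate
well on experimental maps — toy maps have no noise, no solvent, no
B-factor falloff, no segmentation artefacts, and the toy structure has
no side chains. Conclusions about score performance on real
reconstructions must come from real data.

## Numerical choices and degenerate inputs

* Float precision: MRC mode 2 stores float32; the round trip is
  bit-exact for float32-valued grids and documented as such.
* Filters use edge-replicating padding (equivalent to mirror padding for
  radius-1 kernels), so a constant map has exactly zero gradient and
  Laplacian everywhere including edges.
* A map with no intensity spread yields MI = 0 (returned, not an error);
  a zero-variance map makes CCC undefined (an error, since any value
  would be arbitrary).
* An empty envelope (threshold above the maximum) is an error;
  zero-gradient surface voxels are dropped from NV with the count
  recorded; an all-singleton flat cut flags the top cluster as undefined.
* Atoms outside the target grid count as protrusions in ENV, with a
  warning.
* `arccos` arguments are clamped; nearest-neighbour ties resolve to the
  lowest index; agglomeration ties to the lowest-index pair — all so
  repeated runs are bit-identical.

## Limitations

Non-orthogonal cells, anisotropic voxels, half-map/FSC workflows, map
segmentation and the fitting step itself are out of scope. mmCIF input
is not implemented; PDB fixed-width (including multi-model ensembles) is
the supported structure format. The normal-estimation and
segment-masking rules are documented stand-ins where the field has no
single convention; their exact constants (volume per Dalton, ENV
weights) are exposed as parameters rather than hidden.
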