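---
title: "Image-based texture features for protein structure: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based texture features for protein structure: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protex)
```

## The representation

Everything in `protex` starts from one reduction: a structure's ordered
coordinates (α carbons for proteins, all atoms for ligands) are flattened
to the symmetric matrix of pairwise Euclidean distances, in Å, and that
matrix is treated as a grayscale image. The representation is invariant
under rigid motion and mirror images, and the characteristic textures of
secondary structure survive it: a helix produces short-period diagonal
banding, a β-sheet block contacts, a disordered walk an irregular mottle.
The texture descriptors that follow only ever see this image, so they
inherit its invariances — and its blind spots (two structures with equal
distance spectra along the diagonal band structure are indistinguishable).

Distances are mapped to intensities by per-image linear min–max scaling to
integers in [0, 255], with a constant matrix mapping to all zeros. The
mapping is deliberately parameter-free; its one consequence worth knowing
is that intensities are *relative* per image, so overall size is
normalised away and only distance *ratios* matter. A fixed clamp at an
absolute distance cap would preserve absolute scale instead; the min–max
choice keeps the full dynamic range for small ligands whose diameters vary
widely. The full symmetric matrix is imaged, not a triangle: the filters
below act on local neighbourhoods, and symmetric texture keeps their
response independent of which side of the diagonal a motif falls on.

## The descriptors

**LBP.** Each pixel's 3×3 neighbourhood is binarised against the centre:
bit 0 when the centre is strictly greater than the neighbour, bit 1
otherwise (ties count as 1 — the literal reading of "0 if the centre is
greater"). Bits are read clockwise from the top-left neighbour, top-left
most significant. The image border is zero-padded. Two conventions here —
bit significance and the tie rule — are underdetermined by the verbal
definition; both are fixed once, documented, and exercised by worked
examples in the tests (a window of nine equal pixels codes to 255, a
strictly dominant centre to 0, a lone top-left tie to 128).

**Uniform patterns.** A code is uniform when its 8-bit string, read
circularly, has at most two 0↔1 transitions; enumeration gives exactly 58
such codes. The 59-bin histogram gives each uniform code its own bin in
ascending order plus one catch-all. Transition counts are always even,
which the property tests assert across all 256 codes.

**Gabor filtering.** The real (cosine) Gabor kernel with λ = 10 px,
θ = 0, ϕ = 0, γ = 0.02 and σ = 5 px is correlated with the image under
zero padding. Three choices are ours: the rotation convention
(x′ = x cos θ + y sin θ, y′ = −x sin θ + y cos θ; x along columns), the
kernel side (31 ≈ 6σ + 1, beyond which the Gaussian envelope is
negligible), and min–max rescaling of the response back to [0, 255] so
the LBP stage sees valid intensities (clamping is the config-exposed
alternative; rescaling loses no ordering information, which is all LBP
uses).

**SRM.** The image is tiled with non-overlapping 3×3 blocks; inside each
block every row r is replaced by ⌊(r·B)/100⌋, clamped to 255. Division is
integer (the worked examples the transform is defined by show integer
cells). Because 128 mod 3 = 2, the last two rows and columns of a
128×128 image are not covered by a complete block; they pass through
unchanged rather than being padded, so no fabricated intensities enter
the histogram.

**NBS.** Each 3×3 block is subtracted from the block centred one pixel to
its right. Since all differences are taken from the original image and
the sliding blocks overlap in all but one column, the transform collapses
to the per-pixel closed form `out(x, y) = max(0, in(x, y) − in(x, y+1))`,
with the last column zero. Only the horizontal neighbour is used; the
"neighbouring centres" notion would also admit vertical and diagonal
neighbours, but the defining description is written in terms of column
overlap, so the horizontal reading is implemented and flagged here.

**Atom-bond features.** Composition percentages over an element
vocabulary, atomic masses of the first 100 atoms in file order
(zero-padded), and percentages of close-contact pairs at or under a
threshold. Defaults: vocabulary [C, N, O, S] (the heavy atoms of the
standard amino acids — a fixed vocabulary keeps vector lengths
reproducible across datasets, where a dataset-derived "unique atoms" scan
would not), threshold 2.0 Å (covers covalent heavy-atom bond lengths),
prefix 100. With these defaults the group is 4 + 100 + 10 = 114 long; a
dataset-scan mode (`scan_element_vocabulary()`) recovers the
dataset-derived behaviour when wanted. A structure with no close contacts
gets an all-zero bond block rather than an error, which keeps small
ligands usable.

**Scaling policy.** The hybrid descriptor uses A and B from the
native-size image and D and E from the 128×128 bicubic rescale, C being
image-free — the combination that reflects how the groups are evaluated
individually (A best non-scaled, D/E defined on scaled images). The
resampler is the separable Keys cubic-convolution kernel (a = −0.5) with
half-pixel centre alignment and edge replication; it reproduces constants
and linear ramps exactly (up to rounding) and is the identity on
already-128×128 images. 1×1 images are rejected: a single-atom structure
has no pairwise texture, which is also why single-atom ligands are
excluded at ingestion.

## Class imbalance and the classification harness

SMOTE brings each minority class up to the majority count: the
oversampling percentage is (x − y)/y · 100 for majority count x and class
count y, the synthetic count is round(percent/100 · n), base samples are
used as evenly as possible, and each synthetic point is s + u(nn − s)
with nn uniform among the 5 nearest same-class neighbours and u uniform
on [0, 1]. Balancing is applied strictly after the train/test split, to
the training partition only; the harness returns a per-row `synthetic`
flag and the experiment object audits that no synthetic row can reach a
test fold (test folds index original rows by construction, and the audit
counts violations rather than assuming them).

Classifiers are delegated to established implementations — `e1071::svm`
(polynomial kernel, cost 1, exponent 1: the Weka SMO PolyKernel default
that the original experiments in this line of work ran under),
`randomForest` (100 trees), `class::knn` (linear search, no distance
weighting, k = 1), `e1071::naiveBayes` — except AdaBoost, for which no
implementation is installed here; a standard SAMME boosting loop over
`rpart` trees stands in as the `adaboost` spec. Features are min–max
normalised with training-fold ranges before fitting. Multi-class
sensitivity/specificity/F1 are one-vs-rest, aggregated by class-support
weighting (the single-number multi-class summaries this mirrors do not
state their averaging; support weighting is the convention that reduces
to the plain binary definitions).

## The binding model

`binding_model()` implements similarity-based binding prediction: similar
proteins are assumed to bind similar ligands. For a query pair (p, l),
the ligand side finds the k = 3 nearest training proteins to p (under
the category's own metric), joins them through the positive interaction
list to their *related ligands*, and measures l's distance to that set;
the protein side mirrors this through the ligand neighbourhood. Eight
distance categories vote — side × {Euclidean, Manhattan} × {distance to
the centroid, mean of member distances} — the maximal reading of "all
categories of distances"; a two-votes-per-side mode is available. A
category votes positive when its distance is strictly below its
threshold; a side with no related structures abstains; the majority of
non-abstaining votes decides, ties resolving to positive (the model's
stated priority is sensitivity); if every vote abstains the pair is
reported `undecidable` rather than silently labelled.

Thresholds are the least pinned-down part of the procedure and are
implemented as described: for every training pair, the category distance
is computed with the related set derived from the pairs of the *opposite*
label (negatives' relations for a positive pair and vice versa), and the
threshold is the grand mean of these distances. Positives-only and
negatives-only protocols are config-exposed. The grand-mean protocol has
a structural consequence worth stating plainly: the threshold sits at the
mean of a mixture of cross-relation distances, so the model separates
well only when the negative (cross-group) distance distribution is
concentrated — if some group pairs are much closer than others, the
below-mean pairs will be voted positive. This is a property of the
algorithm, not of the implementation, and it shaped the synthetic data
design below.

## What the synthetic data emulates — and what it does not

The generators produce PDB-format text with the same fixed-column dialect
the parser reads, so every stage is exercised end to end.

`synthetic_protein()` emulates SCOPe-like single-domain files: a CA trace
along an ideal α-helix (radius 2.3 Å, rise 1.5 Å, 100°/residue — the
canonical ~3.8 Å consecutive-CA spacing) or a fixed-step random walk,
with isotropic Gaussian coordinate noise and N/O backbone decoy atoms so
composition features have something to count. Helix vs. walk is the
class-prediction testbed: their distance-map textures differ the way
ordered and disordered folds do, and all five classifiers separate them
essentially perfectly, with a label-shuffle control at chance.

`synthetic_binding_dataset()` plants the statistical structure the
binding algorithm assumes — groups within which every protein binds every
ligand. Its design is dictated by the threshold analysis above: the
groups must be *exchangeable and near-equidistant in feature space*, or
the grand-mean threshold misclassifies the closer group pairs regardless
of how clear the separation is. Geometric group signatures (parameter
sweeps, random template shapes, random coordinate offsets) all fail that
requirement — the LBP-histogram response to coordinate perturbations is
strongly anisotropic, so equally-sized coordinate offsets produce feature
distances varying several-fold. The frozen design therefore carries the
group signal chemically: all structures share one geometry (a
128-residue helix, so the scaled feature groups need no interpolation; a
16-atom extended chain for ligands) plus 0.002 Å member noise, and each
group leans towards its own dominant element from the near-equal-mass
pool B, C, N, O, F — ligands through their atom elements, proteins
through 6 decoration atoms per residue on residues 35+, i.e. after the
100-atom mass prefix, so the mass-sequence block stays family-neutral.
Distinct dominant elements place all group pairs at equal distances in
the composition and bond blocks under both metrics, which is exactly the
regime the threshold protocol can calibrate. `separation` blends the
element bias from uniform (0, no signal) to pure (1); the recovery
experiment reaches sensitivity and specificity ≥ 0.9 at separation 1 and
collapses to chance at 0.

What this does *not* emulate: real side chains, sheets, multi-chain
files, heteroatom noise, chemically plausible ligand connectivity, or —
most importantly — binding signal carried by *shape*. Passing the
recovery test shows the algorithm recovers a planted similarity structure
its assumptions match; it says nothing about performance on real
protein–ligand complexes, where group structure is absent and cross-pair
distances are heterogeneous — conditions under which the grand-mean
threshold is expected to trade specificity for sensitivity.

## Numerical and edge-case choices

* Histograms are raw counts (they sum to the pixel count), never
  normalised; the harness's min–max normalisation happens on training
  folds only.
* `matrix_to_image` on a constant matrix returns zeros; `rescale_image`
  rejects inputs smaller than 2×2; filters require at least 3×3.
* k-nearest ties break by identifier order, so every pipeline stage is
  deterministic given its seed; seeds are threaded explicitly and derived
  sub-seeds stay within 32-bit range.
* SMOTE with all-identical samples returns identical synthetics
  (zero-length segments), not an error; `percent = 0` returns an empty
  matrix.
* `cluster_negative_pairs()` k-means-clusters positive pair features
  (clustering method unspecified in the source procedure; k-means is the
  centroid method its description implies) and errors, naming the
  cluster, when a cluster exhausts its candidate unseen pairs.
* Unknown element symbols in mass lookup raise an error naming the
  symbol; elements missing from the element columns fall back to the
  atom-name initial.

## Problem sizes

The shipped experiments use sizes chosen so the whole suite reruns
comfortably on a laptop: the binding recovery uses 5 groups × 20 proteins
+ 20 ligands (200 structures, 744-dimensional hybrid features, 100
positive and 100 negative training pairs, 100 held-out pairs), the class
experiment 60 helices + 40 walks of 40–60 residues with 256-dimensional
group-A features under 10-fold cross-validation, and the oracle suites
100 random instances per operation. These are deliberate working sizes
of the synthetic study, not statements about the scale the method
supports; feature extraction is linear in the number of structures.

## Known limitations

* Only the first MODEL and altloc 'A' of a PDB file are read; mmCIF is
  out of scope.
* The atom-bond group's default vocabulary gives 114 features; matching a
  dataset-derived vocabulary (e.g. one producing 116) requires the scan
  mode, and the hybrid length changes accordingly.
* Gabor filtering is single-scale, single-orientation by design; no
  multi-orientation bank.
* The NBS filter is horizontal-only (see above).
* The binding model stores all training features and does linear-scan
  neighbour search; it is meant for datasets in the thousands, not
  millions.
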