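---
title: "Evolutionary segmentation of density maps: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary segmentation of density maps: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoseg)
```

This vignette is the package's own account of its method: what is being
optimized, what the tunable parameters mean, what the synthetic phantoms do
and do not emulate, and where the design was genuinely open and a choice had
to be made.

## The segmentation model

A density map is a 3D scalar grid with a contour threshold; the voxels
strictly above the threshold are the *foreground*, the molecular envelope.
A segmentation is a labelling of the foreground by positive integers, ideally
one label per protein subunit.

The baseline segmenter is an immersion watershed on the density itself:
voxels are visited in decreasing density order, a voxel with no labelled
6-neighbour seeds a basin (it is a local maximum), any other voxel joins the
basin of its highest labelled neighbour. Density ties break by voxel index,
so the result is deterministic. Watershed on noisy maps over-segments — each
noise bump grows a basin — and the standard remedy is scale-space grouping:
smooth the density with a Gaussian of width σ, recompute basins of the
smoothed field, and merge regions whose seed maxima land in the same smoothed
basin, for s rounds (rounds compound, so the effective scale grows with s).
Grouping is monotone: the segment count never increases, and background is
never touched.

The refinement stage is a genetic algorithm over segmentation states:

* the initial population holds 30 random watershed states, each drawn with
  σ ~ Uniform[1, 4] (continuous — it is a smoothing width) and
  s ~ Uniform{1, 2, 3, 4} (integer — it counts grouping rounds);
* 30 parents are sampled per generation with probability proportional to
  fitness and paired round-robin (1st with 2nd, 3rd with 4th, ...) into 15
  pairs, each yielding one offspring;
* with probability 0.9 the offspring is a crossover — segments from the
  union of both parents' segment sets are drawn uniformly and stamped onto
  still-unlabelled voxels until the foreground is covered, so each offspring
  segment is a (possibly truncated) parental segment — otherwise it is a
  copy of one parent;
* with probability 0.1 the offspring is mutated: a merge (unite one segment
  with a uniformly chosen face-adjacent neighbour) or a split (replace one
  segment by its intersection with a fresh random watershed restricted to
  its voxels), chosen with equal probability;
* the loop stops after 200 generations or 20 consecutive generations
  without a new best fitness, and the best individual ever seen is returned
  even if replacement has discarded it.

Two replacement policies are provided. *Generational* replacement builds the
next population from the 15 offspring plus 15 fresh random states, so the
whole population can turn over; this explores aggressively and produces the
characteristic per-generation score fluctuations. *Elitist* replacement keeps
the 15 best individuals and adds the offspring, making the best-score
trajectory non-decreasing.

## The fitness classifier

Fitness is the probability that a segmentation is "ideal", under a
supervised classifier over a 121-component feature vector: component 1 is
the segment count, then for each of up to 60 segments — sorted by
decreasing volume so the encoding is invariant to label permutation — a pair
(volume proportion, Euler–Poincaré characteristic). Unused components are
zero; with more than 60 segments the 60 largest are encoded and component 1
reports the capped value. The Euler characteristic is computed on the closed
cubical complex of the voxel set, χ = V − E + F − C: a solid blob scores 1,
a tunnel subtracts 1, an enclosed cavity adds 1. The cubical-complex
convention was chosen because it has an exact brute-force oracle (explicit
cell enumeration), which the test suite runs on 200 random voxel sets.

Training data is augmented from annotated maps, 20 samples per map: 10
*bad* samples are independent random watershed states (random σ, s — the
same distribution the optimizer's population is drawn from), and 10 *good*
samples are the ground truth with one uniformly chosen segment split
two-way. The two-way split applies the split mutation's mechanism (random
watershed restricted to the segment, largest piece versus the rest); when
repeated grouped draws keep collapsing the pieces the raw watershed pieces
are used, and a segment whose restricted watershed has a single basin (a
perfectly smooth region) is skipped in favour of another segment. Splitting
one truth segment keeps good samples near-ideal while preventing the
classifier from keying on the exact ground-truth count.

Four model families sit behind one train/score interface: a random forest
(default; CART trees, gini impurity, bootstrap resampling, mtry = √d for
`max_features = "auto"`), ridge logistic regression, a linear L2-SVM with
Platt-scaled probabilities, and a one-hidden-layer ReLU network. Grid search
is cross-validated (5 stratified folds by default; the fold count is
configurable since no canonical value exists) and selects the grid point
with the highest mean held-out area under the ROC curve; the forest's
default grid includes 1200 trees. The forest, SVM and network are
implemented inside the package — no classification-forest or kernel package
ships with the supported R stack — and the SVM family is linear only: an
RBF kernel without a kernel library would be a re-implementation out of
proportion to its role here. AUC is computed by trapezoidal integration of
the empirical ROC; the Mann–Whitney rank statistic serves as the independent
oracle in the tests.

## Evaluation metrics

Because segment identifiers are arbitrary, the prediction is first matched
to ground truth by the one-to-one label assignment maximizing total
intersection-over-union. The assignment is solved as an optimal linear
assignment problem (Hungarian algorithm via `clue`), which is equivalent to
searching all label permutations; the test suite verifies the equivalence
against exhaustive permutation on 100 random instances with up to 6 labels.
Two aggregations are reported: *all slots* — mean IoU over max(p, t) slots
with unmatched slots contributing 0, penalizing over- and under-segmentation
symmetrically — and *matched only* — mean IoU over matched pairs, ignoring
surplus segments. The denominator choice in "all" mode is a documented
convention; nothing canonical exists.

Homogeneity H is voxel-level precision: voxels of matched predicted segments
inside their matched truth segment are true positives; all other predicted
voxels — including every voxel of an unmatched predicted segment, which has
no correct home — are false positives. Proportion P is the mean, over truth
segments, of the number of distinct predicted segments overlapping each.
Consistency C reports that split count for one designated subunit. Two
variants exist because the method's sources describe C both as the maximum
split count and as the split count of the largest-volume subunit — and
published result tables contain a case (C = 1 with P = 3.35) that is
impossible under the maximum reading, since max sᵢ ≥ mean sᵢ. The
largest-volume variant is therefore the default and the maximum variant an
option; the package asserts the disambiguating property in its tests.

## The phantom generator

Phantoms stand in for curated map + atomic-model pairs. Each subunit is a
union of 2–4 isotropic Gaussian blobs (radius 3–5 voxels; the Gaussian sd is
half the radius) offset up to ±0.4 subunit radii from the subunit center;
subunit centers are placed sequentially at 1.2 × the sum of nominal radii
from a randomly chosen existing subunit — the factor compensates the blob
offsets, which extend each subunit beyond its nominal radius — so adjacent
subunits touch through a fuzzy density boundary, the failure mode that
motivates the split mutation. The resolution blur (default σ = 1.5 voxels)
is folded into each blob analytically (sd² adds), which is exact for
Gaussian kernels. Additive Gaussian noise (default sd = 0.05 of the
pre-noise peak) creates the local maxima that make watershed over-segment.

The contour threshold emulates an author-recommended contour:
max(0.15, 5 · noise_sd) × pre-noise peak. The noise-aware floor matters:
a contour at ~3 noise-sd leaves hundreds of 1–3-voxel solvent specks above
threshold, and since neither scale-space grouping nor the merge mutation can
cross background, dust would dominate every segment count. Recommended
contours in practice are chosen precisely so the envelope is clean, which is
what the rule models. A thin fringe of boundary specks (clean density just
below threshold, pushed above by noise) remains — as it does in real maps —
and is inherited by every candidate segmentation.

Ground truth assigns each pre-noise foreground voxel to the subunit whose
blob field is largest there, ties to the lowest subunit index: deterministic
and recomputable by brute force. With defaults, a noiseless 5-subunit
phantom is recovered exactly by fine-scale watershed, and progressively
coarser grouping merges neighbouring subunits — the scale behaviour the
grouping stage assumes.

What the phantoms do *not* emulate: electron-scattering physics, B-factor
falloff, non-Gaussian reconstruction noise, resolution anisotropy, and the
compositional variety of real assemblies. A green end-to-end test therefore
establishes that the optimizer beats its watershed baseline on maps with
realistic topology and noise structure — not that it reproduces
published real-map scores, which depend on deposited maps and structures.

## Ground truth from atomic models

For real data, each model chain is one subunit: foreground voxels take the
label of the chain with the nearest atom in physical coordinates, voxels
farther than a 5 Å cutoff (configurable; the value keeps solvent noise
unassigned) stay background, and exact ties go to the lower chain index.
Dataset curation accepts entries with at least 2 subunits, resolution within
4.5–10 Å, and a map-to-model volume ratio within [0.8, 1.2] (inclusive
bounds; the model volume is the voxel count within the cutoff of any atom).

## Numerical choices and degenerate inputs

* Grids are R arrays indexed [x, y, z] with x fastest — byte-identical to
  the MRC column/row/section layout, so volumes round-trip without
  permutation. Densities are stored as MRC mode 2 float32; label volumes as
  float32 with integral values (classic MRC has no 32-bit integer mode) and
  are rounded on read.
* Watershed connectivity is the 6-neighbourhood, matching the cubical-complex
  convention of the Euler characteristic.
* An empty foreground is an error for segmentation and feature encoding; an
  empty prediction scores 0 matched IoU.
* A merge mutation with no adjacent segment pair, and a split mutation whose
  restricted watershed keeps yielding one region after 5 redraws, are
  identities (logged by the offspring attributes), not errors.
* Improvement in the stopping rule means strictly higher best fitness; with
  a constant fitness the loop runs exactly `patience` generations.
* All-equal or all-zero fitness makes parent selection uniform.
* Seeds: every stochastic entry point takes a seed; phantoms restore the
  caller's RNG state, while `run_evolution(seed = )` seeds the session RNG
  the way base R model-fitting functions do.

## Known limitations

* Disconnected foreground components can never be merged, by construction;
  segment counts are bounded below by the component count of the mask.
* The optimizer's fitness is only as good as the classifier: on maps far
  from the training distribution (much larger grids, many more subunits)
  the forest saturates near probability 0 and the search degrades to a
  random walk. Training on phantoms of comparable scale avoids this.
* The linear SVM family underperforms the forest on the non-linear feature
  geometry; it is provided for completeness of the model-family interface.
* Scale-space grouping associates regions through their seed maxima only —
  fast and standard, but a region whose seed sits on a noise ridge can be
  routed to the wrong smoothed basin at very coarse σ.
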