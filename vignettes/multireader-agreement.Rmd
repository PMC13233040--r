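---
title: "Multireader agreement: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multireader agreement: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mragree)
```

This vignette is the package's account of the statistics it computes: the
model and its assumptions, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the design decisions taken where more than one reasonable
choice existed.

## The model

### Calls, agreements, objects

A *call* is one putative object delineated by one reader on one image —
a pixel mask, a bounding box, or both. When several readers annotate the
same image, their calls must be reconciled into *consensus objects* before
any group-level agreement can be quantified. An object carries the count
`k` of readers who called it, from 1 (a call nobody else matched) to the
number of readers `N`.

Two calls from different readers agree on an object when their pixel-level
overlap — intersection over union (IOU) or the Dice–Sørensen coefficient
(DSC), or bounding-box IOU for detection-style comparisons — reaches a
threshold. The comparison is inclusive (`score >= threshold`). True
negatives do not exist in object detection (there is no countable set of
"correctly not called" objects), so specificity-style analyses are off the
table from the start; everything is built from calls and agreements.

### Pairwise matching: agreement matrix and non-maximum suppression

For one reader pair on one image the package computes the M×N *agreement
matrix* of overlap scores between all calls. Sub-threshold entries are set
to zero, and a pair `(i, j)` is retained only when its score is the maximum
of row `i` *and* of column `j` among the survivors. This thresholded
non-maximum suppression handles *fragmenting*: when reader B draws two
calls across one call of reader A, only the best-overlapping fragment
counts as the agreement; the other fragment remains a call supported by one
reader. Readers carry no confidence scores — every call has equal weight —
so suppression is driven purely by the overlap metric.

Exact score ties are possible (two fragments overlapping a call equally).
The tie-break is deterministic: among tied row maxima the smallest column
index wins; among tied column maxima the smallest row. Any rule would do
statistically; a fixed one makes results reproducible to the bit.

With `tp` retained pairs and `n_A`, `n_B` calls, the familiar two-reader
indices follow from `tp`, `fn = n_A − tp`, `fp = n_B − tp`. Swapping the
readers swaps FP and FN but leaves both indices unchanged, so pairs are
unordered and an image has `N(N−1)/2` unique comparisons. When neither
reader called anything the indices are *undefined* and reported as `NA`,
never silently 0 or 1 — a silent default would bias image-level means.

### Linking across readers: the match matrix

Retained pairs from all `N(N−1)/2` comparisons are linked into consensus
objects as connected components of the graph whose nodes are calls and
whose edges are retained pairs; unmatched calls become singleton objects.
Every call belongs to exactly one object (*call conservation*), which is
what makes the multireader indices well defined.

Transitive matching can conflict with the one-call-per-reader-per-object
constraint: A0–B0 and B0–C0 and C0–A1 can all pass suppression, pulling two
A-calls into one component. The resolution implemented: while a component
violates the constraint, delete its lowest-score edge (ties broken by the
order in which pairs were enumerated) and relink. This destroys the least
well-supported links first and, because raising the IOU threshold also
removes the lowest-scoring matches first, it keeps the object count
monotone in the threshold in practice. A message reports every conflict
that fires, so silent repartitioning never happens.

### The multireader indices

With `C_j` the calls of reader j and `O_k` the objects called by exactly k
readers:

* multireader Jaccard `J = (ΣC − ΣO) / ((N−1)·ΣO)`
* multireader Sørensen `S = N·J/(N−1+J) = N(ΣC−ΣO) / ((N−1)²·ΣO + ΣC−ΣO)`

`S` is implemented through the closed form on the right, which is an exact
ratio of integers; the test suite verifies the relation `S = N·J/(N−1+J)`
to machine precision and verifies that for `N = 2` both quantities are
bit-for-bit equal to `TP/(TP+FP+FN)` and `2TP/(2TP+FP+FN)`. Both indices
live in `[0, 1]`, `S ≥ J` always (algebraically `S−J = J(1−J)/(N−1+J)`),
both equal 1 under perfect agreement and 0 when no two calls match, and
both are undefined when an image has no calls at all.

Computation is strictly per image, with image-level aggregation (mean and
two-sided 95% t-interval of the mean) afterwards; undefined images are
excluded from aggregation and their count is reported. Pooling counts
across images before forming the ratio is a different estimator — offered
explicitly as `pooled_multireader_index()`, never used implicitly.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `threshold` | 0.5 | minimum pairwise overlap for an agreement; 0.25/0.5/0.75 span lenient-to-strict conventions and results should always be read across several values |
| `metric` | `mask_iou` | `mask_dsc` is monotone in IOU (`dsc = 2·iou/(1+iou)`) so it reorders nothing but rescales; `bbox_iou` is for comparisons with box-only detectors |
| `min_calls` | — | curation stringency, 1..N; 1 keeps every consensus object, N keeps unanimous ones |
| `level` | 0.90 | one-sided confidence level of the noninferiority bound |
| `n_boot` | 10000 | bootstrap replicates for that bound; the bound is deterministic given `seed` |
| `conf` | 0.95 | two-sided level of image-aggregation intervals |

Reader-profile parameters are discussed with the generator below.

## The synthetic cohort

`generate_scene()` places randomly oriented ellipses (pairwise disjoint at
pixel level, placed by rejection sampling) in an empty image;
`simulate_reader()` then corrupts the scene independently per reader:

* `miss_rate` — probability a true object is not called (false negative);
* `fp_rate` — expected spurious calls per image (Poisson), placed off the
  true objects;
* `jitter_px` — boundary perturbation: per object, a morphological
  dilation or erosion by a disc of radius drawn uniformly from
  `−jitter_px..jitter_px`;
* `fragment_rate` — probability a call is split into two along a random
  chord through its centroid, the simplest mechanism that reproduces
  fragmenting geometry.

The reference study size is 50 images of 512×512 px with about 20 nuclei
of semi-axis 5–15 px each and five readers — a typical desk-scale
nucleus-annotation exercise. The default error profile
(`miss_rate = 0.08`, `fp_rate = 3`, `jitter_px = 1`,
`fragment_rate = 0.05`) was fixed once, by a pilot grid, to make the
cohort's agreement levels match what trained-novice annotators typically
achieve on nucleus segmentation: mean pairwise Jaccard around 0.6 and
multireader Jaccard around 0.45 at IOU 0.5, declining steeply by IOU 0.75.
The profile has not been adjusted since; experiments that need a
discordant reader triple `miss_rate` and `fp_rate`.

Substream seeding is counter-based: the top-level seed derives one stream
per scene and one per (image, reader) pair. Consequences worth relying on:
cohorts are bytewise reproducible; readers with equal profiles are
exchangeable in distribution; and adding a reader never perturbs the other
readers' annotations, so with-/without-candidate experiments are
ceteris paribus.

What the generator does **not** emulate — and therefore what passing tests
do and do not show about real data:

* every image has the same object count and density, so between-image
  variance is far below that of real tissue patches; statistical power on
  synthetic cohorts is optimistic;
* blobs are convex ellipses; real nuclei touch, overlap, and have lobed
  boundaries, making real fragmenting and jitter messier than the model;
* reader errors are independent across readers and objects, whereas real
  readers share systematic biases (e.g. all missing the same dim nucleus);
* there are no intensity images at all — only masks, which is all the
  metrics ever see.

## Numerical and edge-case decisions

* **Coordinates**: row-major 0-based pixel grid; `x = col`, `y = row`;
  bounding boxes inclusive at both ends with area
  `(xmax−xmin+1)·(ymax−ymin+1)`, matching label-image indexing.
* **Inclusive threshold**: `score >= threshold` survives, so reported
  "IOU ≥ t" table headers mean exactly what they say.
* **Undefined values** propagate as `NA` and are excluded (and counted) in
  aggregation, never imputed.
* **Consensus mask of an object**: the *medoid* member call — the one with
  the highest mean pairwise IOU to the other members, ties broken by reader
  order. This preserves a boundary a reader actually drew instead of
  fabricating pixels by voting; singletons use their own mask.
* **Layered consensus** stores labels, not binary masks, so touching
  objects within a layer stay separable; where two consensus masks overlap
  within a layer the later label wins (the overlap is reported by the
  label counts, not silently merged).
* **Same-reader overlapping calls** are representable in the JSON format
  and preserved; label images cannot express them, and rendering such
  calls to a label image warns about the collapse.
* **Polygon rasterization**: a pixel is foreground when its center lies
  inside or on the polygon boundary — deterministic and checked against an
  independent winding-number implementation in the tests.
* **Statistical tests are delegated** to `stats::wilcox.test()` (normal
  approximation, continuity-corrected) and `stats::kruskal.test()`; the
  package contributes the comparison protocol (what is compared, one- or
  two-sided, and the Bonferroni count), not the tests themselves.
* **Noninferiority bound**: the construction of the one-sided 90% interval
  for the mean per-image difference is genuinely open; the default is a
  seeded percentile bootstrap over images (distribution-free, consistent
  with the otherwise nonparametric protocol), with a t-based alternative
  (`method = "t"`) reported by the same function. On normal differences
  the bootstrap bound tracks the closed form `mean − 1.2816·σ/√n`, which
  the test suite verifies by simulation.

## Known limitations

**Group-size dependence.** The multireader index is not invariant to group
size: under a heavy unique-call load (many spurious or idiosyncratic
calls), removing *any* reader slightly raises the index, because each
reader contributes singletons to `ΣO`. On large homogeneous cohorts a
rank test can detect that generic shift for perfectly ordinary readers,
especially at lenient thresholds. The leave-one-out procedure therefore
follows the conservative multiplicity convention of correcting across
exclusions *and* thresholds jointly (`m_comparisons = 15` for five readers
at three thresholds); a genuinely discordant reader still stands out by
orders of magnitude in p-value. Interpret a *borderline* exclusion with
the mean shift in hand, not the p-value alone.

**Curated ground truth is one reader's boundary.** Curation selects medoid
member masks; it does not average boundaries. Stringency filters object
membership, not boundary quality.

**Scale of validation.** The test suite exercises cohorts up to the
reference size (5 readers × 50 images × ~20 objects, with 20 replicate
cohorts for the outlier-detection power check) and exhaustive or
brute-force oracles only on small structures (agreement matrices to 4×4,
two-reader reductions on hundreds of random fixtures). These sizes were
chosen as the smallest at which the distributional claims stabilize;
behavior on cohorts orders of magnitude larger is extrapolation.

**Formats.** Label images are single-channel TIFF (16-bit, labels to
65535) or PNG (8-bit, labels to 255); multichannel images, ROI archives,
and DICOM are out of scope. The instance-JSON schema (polygons, row-major
RLE, or bboxes) is documented in `?read_instance_json`.
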