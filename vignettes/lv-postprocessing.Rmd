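---
title: "Hallucination removal and trabecular quantification for left-ventricle segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hallucination removal and trabecular quantification for left-ventricle segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvclust)
```

## The problem

Left-ventricular non-compaction (LVNC) is a cardiomyopathy characterised
by excessive trabeculation of the ventricular wall. A quantitative
diagnosis can be derived from a multi-class segmentation of short-axis
cine MRI into compacted external layer (EL), internal cavity (IC) and
trabecular zone (TZ): the trabecular volume percentage

$$\mathrm{VT\%} = 100 \cdot \frac{V_{TZ}}{V_{TZ} + V_{EL}}$$

with a patient called LVNC-positive when VT% *strictly* exceeds 27.4.
Note the internal cavity is excluded from the denominator: the ratio
contrasts spongy against compacted myocardium only, so the call is
invariant to cavity size and — being a ratio — to any uniform rescaling
of the voxel geometry.

Segmentation networks solve the per-pixel problem well but occasionally
hallucinate a second ventricle-like region, most commonly by mislabelling
the right ventricle. A single hallucinated region on a single slice can
shift VT% by several percentage points, so post-processing that reliably
isolates the one true ventricle per stack is what makes the automatic
diagnosis trustworthy. That post-processing is the core of this package.

## Cluster generation

Within one slice, every connected set of non-background pixels is a
candidate ("cluster"). Generation proceeds in three steps:

1. **Top components.** Keep the `top_k` (default 3) largest connected
   components. The true ventricle is almost always among the largest
   blobs; anything beyond the third-largest is noise by construction.
2. **Core-driven splitting.** A component may accidentally bridge two
   anatomically distinct objects through a thin EL band. If the IC+TZ
   core of a cluster falls apart into several connected components, the
   cluster is split into one sub-cluster per core component and each EL
   pixel joins the sub-cluster containing its *nearest pixel* (Euclidean
   distance, ties to the larger sub-cluster). We deliberately use
   nearest-pixel rather than nearest-centroid distance: EL forms a ring
   around the core, and ring pixels are often closer to the far core's
   centroid than to their own, so centroid assignment would shred the
   annulus.
3. **Mini-cluster merging.** Fragments smaller than `merge_fraction`
   (default 5 %) of the largest cluster are merged, smallest first and
   re-evaluated after every merge, into the cluster nearest by minimum
   pairwise pixel distance. Labels are conserved through split and merge:
   the multiset of (pixel, label) pairs in the retained components is
   invariant, which the test suite checks property-style.

Connectivity is 8-connected by default (diagonal contact counts), the
more permissive standard for blob-like anatomy; 4-connectivity is
available via `cluster_config()`. Note that merging by *nearest* cluster
can in principle produce a spatially disconnected union (the merged
fragment need not touch its host); we accept this, since the merge
expresses "these pixels belong with that object", not a topological
claim.

## Cluster selection

Selection links candidates across the ordered slices of one patient. The
anatomical prior is that the ventricle moves slowly from slice to slice
while hallucinations appear erratically, so the track of one cluster per
slice minimising the total distance between consecutive centroids is
found by dynamic programming over the per-slice candidate lists. The DP
is exact; the test suite verifies it against exhaustive enumeration on
hundreds of random instances. Cost ties prefer the larger total cluster
size, then the lexicographically smallest choice — a deterministic
tie-break that favours the ventricle over smaller mimics when both tracks
are stationary.

The track is then validated by overlap. We define

$$\mathrm{overlap}(A,B) = 100\cdot\frac{|A \cap B|}{\min(|A|,|B|)}$$

with the min-size denominator so that the measure is symmetric and does
not penalise the natural apex/base taper (a small end-slice ventricle
fully contained in its neighbour scores 100). If every adjacent pair in
the track overlaps by at least `overlap_threshold` (default 20 %), the
track is accepted. Otherwise each chosen cluster is scored by how many of
the other chosen clusters overlap it above threshold ("valid overlaps"),
and the earliest slice with the fewest valid overlaps is added to the
skip list; skipped slices are removed from the chain, their neighbours
becoming adjacent, and the search restarts.

On first acceptance the surviving slices are pinned ("fixed") and the
skip list is cleared: previously skipped slices get a second chance to
join the now-trusted track, but pinned slices can no longer be skipped.
On second acceptance, or when no skippable slice remains, the procedure
stops and skipped slices are emitted blank — a blank slice is an explicit
"ventricle not detected" statement, preferable to reporting a
hallucination's volume. The census of valid overlaps is taken among the
currently chosen clusters only (one per non-skipped slice), not among all
candidates of all slices: the census refines the current track, and the
alternative reading would let never-chosen candidates veto it. This
interpretation is isolated in one code block so it can be swapped.

The two-pass structure bounds the iteration count by twice the slice
count, which the suite asserts on random inputs.

## Quantification and evaluation

`compute_volumes()` multiplies per-label pixel counts by the voxel volume
$s_x \cdot s_y \cdot (\text{thickness} + \text{gap})$, defaulting to
(1.5, 1.5, 8, 2) mm when no geometry travels with the stack. Whether
volumes are weighted per slice or pooled is immaterial for VT% under
uniform geometry — the voxel volume cancels from the ratio — so pooled
counts are used and raw pixel-count mode is available.

Dice coefficients are computed per class, pooled over a patient's slices,
with the both-empty case defined as 1 (perfect agreement on absence —
required for blank slices, where an empty prediction against an empty
reference is a correct statement). Per-slice Dice is exposed separately
for positional analyses; both aggregations are provided because either
may be wanted when averaging over a population. The helper
`normalized_slice()` maps a slice index to [0, 1] via
$(s - \min)/(\max - \min)$, so stack ends are exactly 0 and 1 — low-Dice
slices concentrate at the ends, where trabeculation is sparse and small
errors dominate the score. Diagnostic confusion-matrix metrics (accuracy,
recall, precision, F1) report zero-denominator ratios as absent rather
than zero.

## Network contracts

The segmentation networks themselves (training, weights, attention
variants) are out of scope; what the package pins down is testable
without training: the resolution wrapper must map an H×W input (divisible
by 4) to an internal H/4×W/4 working shape and restore H×W on output —
800×800 ↔ 200×200 in the reference setting; the deep-supervision loss is
the fixed linear combination `0.25·L1 + 0.25·L2 + 0.5·L3 + 0.75·L4 +
L_output`, weighting decoder heads progressively toward the final output;
and the transfer-learning freeze partitions a tagged parameter inventory
so that exactly the encoder path is frozen, idempotently. The wrapper
description records batch normalisation with leaky-ReLU (negative slope
0.01) blocks as specified for the wrapper stage, even though the network
variants use instance normalisation internally.

## The synthetic phantom

No suitable public dataset of LVNC segmentation stacks exists, so the
package generates its own ground truth. A phantom slice is schematic, not
anatomically realistic: an EL annulus around an inner disc whose outer
45 % carries a crown of alternating TZ wedges ("spokes") over IC, the
remainder pure IC. The spokes make TZ contiguous with both EL and IC, so
the IC+TZ core is a single component on clean slices, while dedicated
test fixtures construct multi-core clusters to exercise the splitting
branch. The radius tapers linearly toward both stack ends (default 35 %
shrink), emulating the apex/base taper that motivates the min-size
overlap denominator.

Defaults — 200×200 px (the network's working resolution), 10 slices,
50 px outer radius, 12 px wall, voxel geometry (1.5, 1.5, 8, 2) mm —
were chosen once as representative of a mid-ventricular short-axis stack
at this resolution and are not tuned.

Hallucinations are stamped as `rv_mimic` (an EL ring with IC core — the
classic mislabelled right ventricle), `el_fragment` (pure-EL debris,
where most real cluster-induced changes occur) or `mini_cluster` (a tiny
TZ blob that exercises the 5 % merge rule). Every stamped pixel is
recorded, so removal is checked exactly rather than via a proxy score;
stamping a distractor over the true ventricle is a validation error, so
recorded masks and truth are disjoint by construction. `degrade_phantom()`
flips a seeded fraction of region-boundary pixels to a neighbouring label
to emulate the raggedness of raw network output.

What the phantom does *not* emulate: true anatomical shape variation,
intensity images (only label maps), partial-volume effects, hallucinations
that touch the true ventricle, and inter-observer label noise. Passing the
phantom suite therefore demonstrates the algorithmic properties
(optimality, conservation, termination, exact removal of *separated*
hallucinations) — not clinical performance on hospital data, which
requires the private datasets and trained networks and is explicitly not
reproduced here.

## Numerical choices and limitations

* All pixel coordinates are (row, col), 0-based slice indices, 1-based
  in-R matrix indexing internally; centroids are real-valued means.
* Component and DP ties are broken deterministically (size, then
  lexicographic centroid/choice order), making the whole chain a pure
  function of input and configuration; distance ties in EL reassignment
  and merging use a 1e-9 tolerance.
* The skip-list clearing before the second pass follows the reading that
  the list is emptied when survivors are fixed; pinned slices constrain
  the DP and cannot be skipped again. The two-pass bound is the most
  conservative terminating reading of the loop-exit rule.
* Slice ordering direction (apex-first vs base-first) is irrelevant: all
  steps are symmetric under stack reversal, but order must be consistent
  within a patient, which the PNG index naming and NIfTI axis convention
  guarantee.
* NIfTI headers carry no slice-gap field; geometry round-trips as pixel
  spacings plus the effective pitch (thickness + gap), which is the only
  geometric quantity the volume computation uses. Header spacings are
  stored at the format's float32 precision.
* Problem sizes in the test and acceptance runs — 200 random DP
  instances, cohorts of 100 phantoms at 200×200×10 — were chosen as the
  package's own verification scale; every check is exact at that scale,
  so larger cohorts add runtime, not information.
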