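# lvclust

Post-processing and quantification toolkit for multi-class left-ventricle
segmentation stacks from short-axis cardiac MRI.

Segmentation networks that delineate the left ventricle occasionally
*hallucinate*: they label a second, spurious ventricle-like region — most
often the right ventricle — alongside the true one. For left-ventricular
non-compaction (LVNC) screening this matters directly, because the
diagnostic statistic is a volume ratio computed from the segmentation.
`lvclust` removes such hallucinations with a two-stage clustering
procedure, quantifies the trabecular volume fraction, and applies the LVNC
decision rule, together with the evaluation metrics (per-class Dice,
diagnostic confusion-matrix summaries) needed to assess the pipeline.

Label convention: `0` background, `1` compacted external layer (EL),
`2` internal cavity (IC), `3` trabecular zone (TZ).

## The method

**Cluster generation** (per slice): any connected set of non-background
pixels is a candidate cluster. The three largest components are kept; a
cluster whose IC+TZ core splits into several connected components is
divided into one sub-cluster per core component, with each EL pixel
reassigned to the sub-cluster containing its nearest pixel; finally any
sub-cluster smaller than 5 % of the largest is merged into its nearest
neighbour.

**Cluster selection** (per patient): across the ordered slices, dynamic
programming finds the sequence of one cluster per slice minimising the
total Euclidean distance between consecutive centroids. The sequence is
validated by the overlap of each adjacent pair,

    overlap(A, B) = 100 · |A ∩ B| / min(|A|, |B|)  ,

and any slice that cannot be reconciled (fewest over-threshold overlaps
with the other chosen clusters, threshold 20 %) is placed on a skip list
and emitted as blank — the ventricle is declared undetected there. After a
consistent sequence is found, surviving slices are pinned and skipped
slices get one second chance against the pinned track (two passes total).

**Quantification**: per-class volumes are pixel counts times the voxel
volume `sx · sy · (slice thickness + gap)`, and the trabecular fraction is

    VT% = 100 · V_TZ / (V_TZ + V_EL)  ,

with an LVNC call when VT% strictly exceeds 27.4 %.

The package also pins down architecture-level contracts of the
segmentation network that are testable without training: the
800 → 200 → 800 px resolution-wrapper shape rule, the deep-supervision
loss `L = 0.25·L1 + 0.25·L2 + 0.5·L3 + 0.75·L4 + L_output`, and the
encoder-freeze partition used for transfer learning. A synthetic phantom
generator draws schematic ventricle stacks with known ground truth and
controllable hallucinations, so the whole pipeline is testable without
patient data.

## Worked example

```r
library(lvclust)

# a 10-slice phantom with a jittering right-ventricle mimic, degraded
# with boundary label noise to emulate raw network output
cfg <- phantom_config(seed = 7, distractors = list(
  distractor_spec("rv_mimic", center = c(45, 160), radius = 15, jitter = 3)))
ph    <- generate_phantom(cfg)
noisy <- degrade_phantom(ph$stack, rate = 0.03, seed = 7)

out <- postprocess_stack(noisy)
out$result
#> selection_result: 10 slices, 0 blank (none), 2 iteration(s)

compute_volumes(out$stack)
#> volumes (mm^3): EL 582075.0, IC 379620.0, TZ 206752.5; VT% = 26.21

diagnosis_record(out$stack$patient_id, compute_volumes(out$stack)$vt_percent)
#> patient phantom0007: VT% = 26.21 (threshold 27.4) -> no LVNC

dice_per_class(out$stack, ph$stack)
#> Dice EL 0.928  IC 0.912  TZ 0.996  mean 0.945
```

The mimic track is rejected on every slice (no blank slices are needed
here: every slice retains its true ventricle), and the measured VT% of
26.21 sits next to the phantom's analytic ground truth of 26.23 — the
residual is the boundary noise, not the post-processing. On the noise-free
stack the recovery is exact.

A command-line front end wrapping the same functions ships in
`inst/cli/lvclust.R` (`synth`, `postprocess`, `quantify`, `evaluate`,
`diagnostics` subcommands).

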