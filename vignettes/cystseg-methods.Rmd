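---
title: "Methods: automated kidney-cyst segmentation in T2-weighted MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated kidney-cyst segmentation in T2-weighted MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In autosomal-dominant polycystic kidney disease (ADPKD) fluid-filled cysts
progressively replace kidney parenchyma.  Total kidney volume (TKV), total
cyst volume (TCV) and the cystic index (TCV/TKV) are imaging biomarkers of
disease burden, conventionally obtained by manual tracing of coronal
T2-weighted MR slices — hours of expert work per scan.  `cystseg`
implements a fully automated alternative: a two-channel 2-D convolutional
encoder–decoder that labels cyst voxels slice by slice, given the MR image
and a kidney mask, together with the complete agreement-evaluation suite
used to compare automated against manual tracings (Dice, Jaccard,
sensitivity, precision, Hausdorff distance, TCV percent difference, linear
regression, Bland–Altman analysis).

Because no clinical MR dataset ships with the package, a synthetic phantom
generator provides geometrically controlled stand-ins with exact
ground-truth masks, which makes the entire pipeline — preprocessing,
training, cross-validation, ensembling, evaluation — trainable and testable
end to end on a laptop CPU.

## The segmentation model

The network maps a 256×256×2 input (normalized image slice; binary kidney
mask slice) to a per-pixel cyst probability.  Supplying the kidney mask as
a second input channel lets the model learn that cysts live inside kidneys
without any hard constraint; how well that works is itself a tested
property (held-out predictions outside the kidney must stay below 5 % of
positives).

Architecture, as configured by `network_config()`:

* three encoder blocks, each `conv → dropout(0.1) → batch norm → conv →
  max-pool(2×2)`, with kernel sizes 7×7 → 5×5 → 3×3 down the encoder and
  the reverse up the decoder — larger kernels at higher resolution learn
  larger, more complex filters;
* a 3×3 bottleneck block, channel widths doubling per level
  (`base_filters` 32 → 64 → 128 → 256 at full scale; 8 → 16 → 32 → 64 at
  test scale);
* a decoder that mirrors the encoder: nearest-neighbour 2× upsampling
  followed by a convolution of that level's kernel size, then an additive
  (ResNet-style) skip connection from the matching encoder level — a 1×1
  convolution projects the encoder feature map so channel counts agree —
  and a second convolution;
* a 1×1 convolution with sigmoid output.

Design points the architecture description leaves open, decided here and
treated as package conventions: ReLU activations after every convolution;
dropout between the two convolutions of a block, batch normalization after
it, in the literal order given above; "same" zero padding throughout so
additive skips meet at equal resolution; three resolution-reducing levels,
implied by the three-entry kernel schedule.

The forward and backward passes are written explicitly (Rcpp/Armadillo
im2col convolution kernels, R-side layer composition) and the backward pass
is verified against numerical differentiation in the test suite to a
relative tolerance of 1e-4.

## Training

* **Loss** — soft Dice, `1 − (2Σpt + s)/(Σp + Σt + s)` summed over every
  pixel of the batch, smoothing constant `s = 1` (unstated in the source
  protocol; any small positive value keeps the empty-vs-empty case defined
  and the loss in [0, 1]).
* **Optimizer** — Adam, initial learning rate 1e-3, batch size 8, decay
  1e-5.  "Decay" is interpreted as the additive schedule
  `lr_t = lr0 / (1 + decay · t)` per update step, the convention of the
  framework family the protocol derives from.
* **Checkpointing** — after every epoch the validation measure is computed
  and the weights with the best value are retained.  The validation measure
  is hard volume-level Dice at threshold 0.5, averaged over validation
  cases after reassembling slice predictions into volumes (empty-vs-empty
  counts as 1).  A slice-level measure would be an equally defensible
  reading; volume-level matches how the final model is scored.
* **Batching** — slice samples are shuffled across cases each epoch; only
  slices intersecting the kidney mask are used for training, since an
  all-background slice carries no gradient for a target confined to
  kidneys.  Inference processes every slice so volumes reassemble
  completely.  No data augmentation.
* **Determinism** — one seed drives initialization, shuffling and dropout
  through R's RNG; identical configuration and seed reproduce training
  bit-for-bit (there are no nondeterministic kernels in this
  implementation).

## Data splitting

`stratify_cases()` ranks cases by TKV and allocates them by systematic
strided sampling with seeded within-stratum shuffling: the sorted list is
cut into as many contiguous strata as there are slots, and one random
member of each stratum goes to each partition.  By default allocation is
additionally stratified by fat saturation, preserving the 70 % / 30 %
fat-saturated mix in every partition (60 cases, 20 held out → 14
fat-saturated test cases).  The acceptance suite checks that the TKV
distribution of the hold-out set and of every fold is statistically
indistinguishable from the remainder (Wilcoxon rank test, p > 0.05, 60
phantoms spanning cystic index 0.005–0.9).

## Ensembling

The three fold models are fused by literal per-voxel majority vote on their
binarized outputs (member threshold 0.5, vote threshold 2-of-3), not by
averaging probabilities.  Intersecting the fused mask with the kidney mask
is available as `apply_kidney_mask = TRUE` but is **off** by default: the
protocol this package follows treats kidney masking as hypothetical
post-processing, and leaving it off makes the two-channel constraint
observable.  Predictions computed on the 256×256 processing grid are mapped
back to the native grid by nearest-neighbour resampling.

## Preprocessing

Each volume is normalized in two steps computed over **all** voxels: rescale
so the 95th percentile equals a common level (`target_p95`, default 1000
arbitrary units), then standard scaling to zero mean and unit standard
deviation.  The standardization makes the percentile level immaterial — the
output is invariant to any positive rescaling of the input — which the test
suite asserts to 1e-5.  Slices are resampled to the processing grid with
cubic convolution (Keys kernel, a = −0.5) for intensities and nearest
neighbour for masks; cubic output is deliberately not clipped.
Normalization precedes resampling; the order only matters at the level of
interpolation error.

## The phantom generator

`generate_case()` emulates the features of coronal T2 abdominal MR that the
pipeline actually exercises, not MR physics:

* two ellipsoidal kidney bodies with mild random axis jitter;
* spherical cysts with random centers inside the kidney, clipped to it, so
  containment is exact by construction; radii 2–15 mm, with the
  deficit-matching radius taking over as the target cystic index is
  approached (placement stops within 10 % relative of the target or raises
  a feasibility error naming the binding constraint);
* a minority of cysts (default 15 %) rendered T2-dark ("complex" cysts),
  the rest T2-bright;
* background either dark (fat-saturated) or bright with high variance
  (non-fat-saturated); additive Gaussian noise (σ = 30 intensity units).

Intensity levels (background 50 / 400, parenchyma 300, bright cyst 800,
complex cyst 100, arbitrary units) are free choices; only their ordering is
contractual, and no quantitative intensity statistics of real scans are
available to validate them against.  Gaussian rather than Rician noise is a
deliberate simplification: adequate for testing the pipeline, not for
simulating MR magnitude images.  Phantoms contain no renal pelvis, vessels,
liver cysts, bias fields or motion artifacts, so passing tests demonstrate
pipeline correctness and learnability on controlled geometry — they say
nothing about clinical accuracy on real MR, which requires real cohorts.

`generate_cohort()` spaces cystic-index targets geometrically across the
severity range (severity spans two orders of magnitude) and fixes the
fat-saturated count to `round(fraction × n)`.

## Problem sizes used by the tests and the acceptance script

The packaged checks run at test scale: 64×64×16 phantom grids, 8 base
filters, 26-case cohorts (20 train/validation, 6 held out), 3 folds, 15
epochs.  Fifteen epochs keep a full cross-validated run on one CPU core in
the ten-minute range; best-validation checkpointing retains the strongest
epoch regardless of where in the schedule it falls.
The learnability cohort spans cystic index 0.02–0.7 rather than the full
0.005–0.9: at 64×64 test resolution a 0.5 % cystic index is carried by a
handful of voxels near the resolution limit, the analogue of the microcysts
that clinical protocols also exclude.  The full-scale configuration
(256×256, 32 base filters, 200 epochs) is exposed through the same
`network_config()`/`train_config()` defaults but is a GPU-scale
undertaking.

## Numerical conventions and degenerate inputs

* Overlap metrics with a zero denominator (e.g. two empty masks) are
  undefined and propagate as `NA`, never as 0; cohort summaries exclude
  them and report the excluded count.
* The Hausdorff distance is the exact symmetric max–min Euclidean distance
  over all mask voxels in 3-D **voxel-index units** (anisotropic spacing
  deliberately ignored — the reported unit is voxels); it is an error on
  empty masks.  No percentile variant is provided.
* TCV percent difference is signed and reference-denominated:
  `100·(test − ref)/ref`.
* Bland–Altman limits use the sample standard deviation (n − 1); the
  analysis is computed on the cystic-index fraction and plotted as percent.
* Cohort summaries report mean ± sample standard deviation.
* Masks read from NIfTI binarize any nonzero value to 1; masks are written
  as unsigned 8-bit, volumes as 64-bit float, and all processing happens in
  voxel index space — orientation matrices are preserved but never used.
* Batch-norm uses ε = 1e-5 and running-statistic momentum 0.1; Adam uses
  ε = 1e-8.  Max-pool ties resolve to the first maximum in column-major
  order.

## Known limitations

Phantom realism as above; 2-D slice-wise processing (no 3-D context across
slices); no per-cyst instance separation or counting; no DICOM ingestion;
the kidney mask is an input, not a product, of the pipeline.
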