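# cystseg

Fully automated semantic segmentation of kidney cysts in coronal
T2-weighted MR volumes of patients with autosomal-dominant polycystic
kidney disease (ADPKD), for imaging scientists who need total cyst volume
(TCV) and cystic index without hours of manual tracing per scan.

In ADPKD, cysts progressively replace kidney parenchyma; total kidney
volume (TKV), TCV and the cystic index TCV/TKV are the standard imaging
biomarkers of disease burden. `cystseg` implements:

* a **two-channel 2-D encoder–decoder network** — input is a 256×256×2
  matrix (normalized MR slice + binary kidney mask), output the per-pixel
  cyst probability. Encoder blocks are conv → dropout(0.1) → batch-norm →
  conv → max-pool(2×2) with kernel sizes 7×7 → 5×5 → 3×3 down the encoder
  and reversed up the decoder; skip connections are additive
  (ResNet-style); training uses the soft Dice loss
  1 − (2Σpt + s)/(Σp + Σt + s) with Adam (lr 10⁻³, decay 10⁻⁵, batch 8)
  and best-validation checkpointing. Forward and backward passes are
  implemented from first principles (Rcpp/Armadillo) and verified against
  numerical differentiation;
* **TKV-stratified splitting** into a hold-out test set and k
  cross-validation folds (optionally also stratified by fat saturation);
* a **majority-vote ensemble** of the three fold models (per-voxel 2-of-3
  vote on binarized member outputs);
* the **evaluation suite**: Dice, Jaccard, sensitivity, precision, exact
  3-D Hausdorff distance in voxel units, TKV/TCV/cystic index, signed TCV
  percent difference, ordinary least-squares regression with 95 %
  confidence bands, Bland–Altman analysis, and qualitative overlays;
* a **synthetic phantom generator** (ellipsoidal kidneys, spherical
  bright/complex cysts, fat-saturated or non-fat-saturated background)
  with exact ground truth, so the whole pipeline trains and evaluates on a
  CPU without clinical data;
* NIfTI-1 input/output for volumes and masks.

## Worked example

Train a test-scale model on phantoms and evaluate the held-out cases:

```r
library(cystseg)

cohort <- generate_cohort(26, severity_range = c(0.02, 0.7),
                          fat_sat_fraction = 0.7, seed = 1)
plan <- stratify_cases(cohort, n_test = 6, n_folds = 3, seed = 1)

folds <- run_cross_validation(
  plan, cohort,
  network_config(base_filters = 8, input_shape = c(64, 64)),
  train_config(epochs = 15, seed = 1))
ens <- ensemble_model(lapply(folds, `[[`, "model"))

ids <- vapply(cohort, function(cs) cs$image$case_id, "")
test_cases <- lapply(plan$test_ids, function(id) {
  cs <- cohort[[match(id, ids)]]
  cs$cyst_by_source$auto <- predict_case(ens, cs)
  cs
})
evaluate_test_set(test_cases, "auto", "truth")
```

On one CPU core this takes roughly ten minutes and prints:

```
Cohort agreement summary (mean ± sd):
  dice                        0.854 ± 0.237  (n = 6)
  jaccard                     0.793 ± 0.281  (n = 6)
  sensitivity                 0.820 ± 0.296  (n = 6)
  precision                   0.971 ± 0.035  (n = 6)
  hausdorff_vox               4.067 ± 4.399  (n = 6)
  tcv_percent_difference    -15.035 ± 31.471  (n = 6)
```

The large spread is driven by the mildest-severity case: small, few-voxel
cysts near the resolution limit are the hardest to segment, so per-case
Dice ranges from near-perfect on severe disease down to much lower values
on minimal disease.

Dice/Jaccard measure voxel overlap with the ground-truth cyst mask,
sensitivity and precision its recall/purity, the Hausdorff distance the
worst boundary disagreement in voxels, and the TCV percent difference the
signed volumetric error relative to the reference tracing. The same
pipeline is scriptable from a shell via `inst/cli/cystseg.R`
(subcommands `make-phantoms`, `split`, `train`, `predict`, `evaluate`).

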