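# lesionfuse

Segmentation-guided multi-task classification of 3-D lesion volumes with
radiomics fusion.

`lesionfuse` is for researchers who have volumetric medical images (e.g.
diffusion-weighted MRI of acute stroke), a binary per-patient outcome
(e.g. underlying atrial fibrillation), and a lesion mask, and who want a
fully seeded, desk-scale implementation of the two-branch idea:

* a **3D U-Net segmentation branch** learns a voxelwise lesion map and, as
  a by-product, *prior attention* maps — the squashed channel means of its
  encoder scales — that multiplicatively steer a parallel
  **3D CNN classification branch** toward the lesion
  (`features · (1 + attention)`);
* **radiomics features** (first-order, shape, GLCM, GLDM, GLSZM, NGTDM —
  36 features computed from their definitions inside the ROI) are weighted
  by a learnable softmax self-attention gate and fused with the CNN's
  semantic vector in an MLP.

Three softmax heads — radiomics-only, CNN-only, combined — are trained in
two stages with composite losses

```
stage 1:  L_dice + L_cnn          (extractors + CNN head)
stage 2:  L_rad  + L_com          (attention + radiomics head + fusion MLP)
```

under Adam with the exponential schedule `lr(t) = lr0 · 0.98^t`
(defaults `lr0 = 1e-4`, 25 + 25 of 50 epochs, batch 8), fivefold
patient-level cross-validation with minimum-validation-loss checkpointing,
and cross-fold ensemble prediction. Evaluation reports AUC
(Mann–Whitney), stratified-bootstrap 95% CIs, and
sensitivity/specificity/accuracy/PPV/NPV at the max(sens + spec)
operating point, plus subgroup breakdowns. Interpretability comes as
Grad-CAM saliency over the classification branch and feature-significance
ranking (FSR, cohort-averaged attention weights). Because the clinical
cohorts behind the method are private, the package ships a synthetic
lesion-phantom generator whose two classes differ in neighbourhood
gray-tone texture and lesion elongation, so the whole pipeline is testable
end-to-end.

The backprop for the two-branch network is hand-derived (verified against
finite differences in the test suite) over Rcpp/RcppArmadillo conv3d /
pool / upsample kernels; no deep-learning framework is required.

## A worked example

```r
library(lesionfuse)

cohort <- generate_cohort(phantom_params(), n_per_class = 6, seed = 42)
cohort[[1]]
#> <lf_study S001> label=0 volume=[32x64x64] lesion voxels=3726

round(extract_feature_vector(cohort[[1]])[
  c("firstorder_range", "shape_elongation", "ngtdm_contrast")], 3)
#> firstorder_range shape_elongation   ngtdm_contrast
#>            0.590            6.121            0.133

cfg <- lf_config(epochs_stage1 = 2, epochs_stage2 = 8, lr0 = 1e-3,
                 batch_size = 4, n_boot = 200)
fit <- lesionfuse(cohort, cfg)      # fivefold two-stage training
print(fit)
#> <lesionfuse> 5-fold fitted model on 12 studies (config 3268dce8)
#>   out-of-fold combined-head AUC: 1.000

summary(fit, n_boot = 200)
#> <lf_metrics p_rad> AUC 1.000 [1.000, 1.000] | sens 100.0% spec 100.0% ...
#> <lf_metrics p_cnn> AUC 0.556 [0.222, 0.834] | sens 16.7% spec 100.0% ...
#> <lf_metrics p_com> AUC 1.000 [1.000, 1.000] | sens 100.0% spec 100.0% ...

predict(fit, generate_cohort(phantom_params(), n_per_class = 2, seed = 7))
#>   study_id label     p_rad     p_cnn     p_com
#> 1     S001     0 0.3025052 0.4766453 0.2663129
#> 2     S002     1 0.6871636 0.4804675 0.7083992
#> ...
```

The out-of-fold AUCs say the phantom classes are recovered perfectly by
the radiomics and combined heads even at this toy training budget (2
stage-1 epochs on 12 studies), while the CNN head — which must learn its
features from voxels — is still near chance; the acceptance-scale run
below trains it into the 0.9+ range. `shape_elongation` is an anisotropy
ratio (≥ 1; the 6.1 above reflects a two-lesion mask whose union is
elongated), and `ngtdm_contrast` is the neighbourhood gray-tone contrast
that the class-1 checkerboard texture drives up. `coef(fit)` returns the
FSR significances (they sum to 1), `plot(fit)` draws the three ROC
curves, and `run_pipeline()` / `inst/cli/lesionfuse.R` run the same
machinery from manifests on disk with all artifacts (fold plan,
checkpoints, loss curves, scores, metrics JSON, FSR CSV, saliency NIfTI)
written to a run directory.

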