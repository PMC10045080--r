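# histofuse

Hybrid deep + handcrafted feature fusion for five-class lung and colon
histopathology image classification.

Early-stage lung and colon tumours look alike under the microscope, and
no single feature family separates the five standard classes (colon
adenocarcinoma, colon benign, lung adenocarcinoma, lung benign, lung
squamous cell carcinoma) reliably. `histofuse` implements the full
fused-feature pipeline for this setting, end to end and testable
without any external data:

- **Enhancement** — gray-world colour balance, a 16-pixel neighbourhood
  averaging filter (`z_i = (1/N) Σ x_{i−j}`, N = 15 with the centre
  excluded), and contrast-limited adaptive histogram equalisation
  (CLAHE) on the luminance channel.
- **Handcrafted descriptors (244)** — single-level orthonormal Haar
  wavelet subband statistics (12), local binary pattern histograms with
  `LBP_{R,P} = Σ_p s(g_p − g_c) 2^p`, P = 15, binned to 203, a 16-bin
  fuzzy colour histogram with c-means memberships
  `u_k ∝ (1/d_k²)^{1/(m−1)}`, and 13 Haralick statistics of symmetric
  grey-level co-occurrence matrices averaged over the four angles
  0°/45°/90°/135°.
- **Deep-style features** — max/average pooling and global average
  pooling primitives, a backbone adapter contract, and a deterministic
  seeded pseudo-backbone producing 4096-dimensional vectors.
- **Reduction and fusion** — covariance PCA with a deterministic sign
  convention, fitted on training rows only, and three fusion
  strategies: per-branch PCA then concatenation (455 + 455 = 910),
  concatenation then PCA (740), and PCA-reduced deep + raw handcrafted
  (455 + 244 = 699).
- **Classifier** — one hidden layer of 20 tanh units, five outputs,
  cross-entropy (softmax) or MSE (logistic) loss, full-batch training
  with validation-failure early stopping (`max_fail = 6`), gradient and
  history capture.
- **Evaluation** — one-vs-rest sensitivity, precision, accuracy,
  specificity and ROC AUC (trapezoid = Mann–Whitney with ties at ½) per
  class with macro averages, error histograms and regression
  diagnostics.
- **Synthetic fixtures** — a five-class texture generator (blobs,
  smooth, stripes, speckle, checker, each with a distinct base colour)
  with a separability knob in [0, 1], so the whole pipeline is
  verifiable against data whose class structure is known by
  construction.

## Worked example

The recovery experiment generates 100 synthetic images per class at
64 × 64, enhances them, extracts the 244-dimensional handcrafted
descriptor, PCA-reduces it, trains the classifier with early stopping
and evaluates on the held-out stratified test split:

```r
library(histofuse)
res <- run_synthetic_pipeline(n_per_class = 100, size = 64,
                              separability = 1, seed = 7)
print(res$report)
```

```
Confusion matrix (rows = true):
           predicted
true        colon_aca colon_bnt lung_aca lung_bnt lung_scc
  colon_aca        17         3        0        0        0
  colon_bnt         0        20        0        0        0
  lung_aca          0         0       20        0        0
  lung_bnt          0         0        0       19        1
  lung_scc          0         0        0        0       20

Per-class metrics (%):
     class sensitivity precision accuracy specificity    auc
 colon_aca          85    100.00       97      100.00  99.88
 colon_bnt         100     86.96       97       96.25 100.00
  lung_aca         100    100.00      100      100.00 100.00
  lung_bnt          95    100.00       99      100.00  99.25
  lung_scc         100     95.24       99       98.75 100.00

Average ratio (%):
sensitivity   precision    accuracy specificity         auc
      96.00       96.44       98.40       99.00       99.83

Overall accuracy: 96%
```

The confusion matrix counts the 100 test images (20 per class); the
per-class rows are the one-vs-rest reductions of that matrix, and the
"average ratio" row is their unweighted macro average. At
`separability = 0` the five generating distributions coincide and the
same pipeline falls to the 20% chance level — the package's built-in
negative control. Setting `separability` between 0 and 1 interpolates
the class structure continuously.

A thin command-line front end over the same functions lives in
`inst/cli/histofuse.R` with subcommands `simulate`, `enhance`,
`extract`, `reduce`, `fuse`, `train` and `evaluate`.

## Package layout

- `R/dataset_io.R` — manifests, stratified splitting, feature store
- `R/enhancement.R` — gray-world, averaging filter, CLAHE
- `R/handcrafted.R` — DWT, LBP, FCH, GLCM/Haralick, 244-vector
- `R/deep_features.R` — pooling, adapter contract, pseudo-backbone
- `R/reduction_fusion.R` — PCA and the fusion strategies
- `R/ann.R` — classifier, training history, diagnostics
- `R/evaluation.R` — confusion matrix, metrics, ROC/AUC
- `R/synthetic.R` — five-class texture generator
- `vignettes/feature-fusion-methods.Rmd` — models, parameters, design
  decisions and limitations
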