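---
title: "Feature fusion for histopathology classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature fusion for histopathology classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histofuse)
```

## The problem

Histopathological diagnosis of lung and colon tumours rests on the visual
texture and colour of stained tissue sections: glandular adenocarcinoma,
benign tissue and squamous cell carcinoma differ in micro-pattern,
coarseness and staining statistics, but early-stage classes look similar
enough that single feature families are easily confused. `histofuse`
implements a hybrid pipeline for the five-class lung/colon setting
(colon adenocarcinoma, colon benign, lung adenocarcinoma, lung benign,
lung squamous cell carcinoma): images are enhanced, described both by
deep-style convolutional features and by four classical handcrafted
descriptors, reduced by PCA, fused, and classified by a small
feed-forward network. Every stage is exercisable on synthetic fixtures,
so the package's correctness does not depend on any external image
download or pretrained weights.

## Enhancement

Three stages run in a fixed order; intermediate values stay in floating
point and are quantized back to 8-bit integers once, at the end, to
minimise rounding loss.

1. **Gray-world colour balance.** Each channel is scaled by
   (global mean / channel mean) and clipped to $[0, 255]$, so channel
   means coincide up to clipping. An all-black channel is left alone
   with a warning rather than divided by zero.
2. **Neighbourhood averaging.** Each pixel is replaced by the mean of
   its $N$ configured neighbours, $z_i = \frac{1}{N}\sum_{j=0}^{N-1}
   x_{i-j}$. The default is a 16-pixel ($4 \times 4$) window with the
   centre excluded, $N = 15$. An even window has no symmetric centre, so
   the default anchors the window with the centre pixel at its top-left
   cell; a conventional centred $3 \times 3$, $N = 9$ mode is also
   provided. Borders use reflective padding, which avoids the dark halo
   a zero pad would create.
3. **CLAHE.** Contrast-limited adaptive histogram equalisation: the
   image is divided into tiles (default $8 \times 8$), each tile's
   histogram is clipped at `clip_limit` (default 0.01, a fraction of the
   tile pixel count) with the excess redistributed uniformly, and each
   pixel is mapped by bilinear interpolation between the four
   surrounding tile mappings. The equalisation acts on the luminance
   channel with the RGB channels rescaled proportionally (chroma
   preserved); a per-channel mode exists since the convention is
   genuinely open. Tiles holding a single intensity map to themselves,
   so constant regions pass through unchanged, and the sub-level
   residual of each intensity is carried through the mapping, which
   makes the chain exactly lossless on constant images. With one tile
   and an unbounded clip limit the operation reduces to plain histogram
   equalisation, which is how the implementation is cross-checked.

## Handcrafted descriptors (244 features)

All four descriptors operate on the enhanced image; texture descriptors
use the BT.601 luminance (weights 0.2989/0.5870/0.1140), the colour
histogram uses RGB directly. The concatenation order is fixed:
DWT (12) | LBP (203) | FCH (16) | GLCM (13) = 244.

**Wavelet subband statistics (12).** A single-level orthonormal Haar
transform splits the image into LL/LH/HL/HH subbands; each contributes
its mean, population variance and standard deviation. The orthonormal
convention conserves squared energy exactly (a test asserts this at
1e-9), and population variance makes the statistics well defined even
for degenerate $1 \times 1$ subbands. Odd image dimensions are cropped
by one pixel.

**Local binary patterns (203).** Each pixel's code is
$\sum_{p=0}^{P-1} s(g_p - g_c)\,2^p$ with $s(x) = 1$ for $x \ge 0$
(ties count as 1, the standard convention) and $P = 15$ neighbours
sampled counter-clockwise on a radius-$R$ circle with bilinear
interpolation; $R = 2$ is the conventional radius for circa 16
neighbours. Sampled values are rounded at 1e-8 before thresholding, a
stated convention that stabilises exact ties between the centre and an
interpolated neighbour. The $2^{15}$ possible codes are binned into 203
equal-width bins — the descriptor's published length is 203, which does
not correspond to any uniform-pattern taxonomy of $P = 15$, so
equal-width binning over the full code range is the neutral reading and
the bin count remains configurable. The histogram is normalised to sum
to 1.

**Fuzzy colour histogram (16).** Sixteen colour prototypes are obtained
once per seed by fuzzy c-means over the 64 centres of a fixed
$4 \times 4 \times 4$ RGB lattice (clustering via `e1071::cmeans` with a
seeded initial draw, hence deterministic). Each pixel then spreads unit
mass over all bins with the standard fuzzy c-means membership
$u_k \propto (1/d_k^2)^{1/(m-1)}$, fuzziness $m = 2$; a pixel exactly at
a centre takes full membership there (the continuity limit). The
histogram of membership mass is normalised to sum to 1.

**GLCM / Haralick (13).** The luminance is quantized to 8 gray levels;
co-occurrence matrices at distance $d = 1$ and angles
0°/45°/90°/135° are symmetrised and normalised, and the 13 classical
Haralick statistics are averaged over the four angles (13 published
values with four angles implies angle averaging rather than
concatenation). Entropies use log base 2 with $0\log 0 = 0$; the
correlation of a zero-variance (single-level) matrix is defined as 0;
sum variance is taken about the sum average.

## Deep-style features

The pooling primitives are the textbook ones: window max or mean at
stride $p$ with no padding, and global average pooling of each feature
map to its spatial mean. Real pretrained backbones are deliberately out
of scope; instead a **backbone adapter** contract (name, fixed
`output_dim`, deterministic `extract`) lets any source of fixed-length
image features plug in, and the package ships a **pseudo-backbone**: a
seeded bank of random $3 \times 3 \times 3$ convolution kernels,
rectification, max pooling, a second per-map convolution stage with
average pooling, global average pooling, channel colour moments, and a
seeded random projection to `output_dim` (default 4096, the published
deep-feature width). Global average pooling of a small map bank cannot
itself reach 4096 dimensions, so the random projection supplies the
published width while keeping extraction a pure function of
`(seed, output_dim)`; downstream stages see exactly the dimensions they
would see with a real backbone.

## Reduction and fusion

PCA is covariance PCA (mean-centred, unscaled) via the singular value
decomposition, with a deterministic sign convention (largest-magnitude
loading positive) so artifacts are bit-reproducible; a correlation-PCA
option exists for mixed-scale inputs. Models are fitted on training
rows only and applied unchanged to validation and test rows — fitting on
all rows would leak held-out information. Component counts default to
the published sizes (455 per deep branch, 740 for the pooled merge) and
are capped at $\min(n_\text{train} - 1, d)$ with a message for small
synthetic runs; the counts are configuration values, since no variance
criterion was published for them.

Three fusion strategies produce the published widths:

| strategy | construction | width |
|---|---|---|
| `separate` | PCA of one deep branch | 455 |
| `merge_after_pca` | PCA each branch, concatenate | 455 + 455 = 910 |
| `merge_before_pca` | concatenate, then one PCA | 740 |
| `cnn_plus_handcrafted` | PCA deep branch + raw handcrafted | 455 + 244 = 699 |

The `cnn_plus_handcrafted` strategy standardises each branch per-feature
on training statistics before concatenation: the 455 PCA scores have
variances on the scale of the deep features and would otherwise drown
the 244 handcrafted features.

## Classifier

A single hidden layer of 20 tanh units feeding 5 output units. (The
source description "20 hidden layers" is read as one hidden layer of 20
units — the training diagnostics it accompanies are those of a shallow
toolbox network, and 20 genuine layers of unspecified width would not
train as described; depth remains configurable.) Both losses are
implemented: cross-entropy with softmax outputs (the default, matching
the cross-entropy training curves) and mean squared error with logistic
outputs. Inputs are standardised internally on training statistics.

Training is full-batch gradient descent with momentum 0.9 and a
bold-driver step rule (the rate grows 5% per improving epoch and halves,
with momentum reset, when the training loss rises), which keeps the
whole trajectory deterministic for a fixed seed. Stopping follows the
validation-failure idiom: training halts after `max_fail = 6`
consecutive epochs without a validation-loss improvement, when the
gradient norm falls below 1e-6, or at the epoch budget; the returned
weights are the best-validation snapshot. The history records training,
validation and optional test loss, gradient norm and the failure counter
per epoch. Analytic gradients for both losses are verified against
central finite differences at 1e-5 in the test suite. Weight
initialisation is seeded uniform $\pm 1/\sqrt{\text{fan-in}}$.

Diagnostics mirror the standard toolbox set: a 20-bin error histogram of
target minus output over the observed error range (per split), and a
regression diagnostic — the Pearson correlation of flattened targets and
outputs, in percent.

## Evaluation

The $5 \times 5$ confusion matrix (rows true, columns predicted, classes
in fixed alphabetical order) is reduced one-vs-rest per class:
sensitivity $TP/(TP+FN)$, precision $TP/(TP+FP)$, accuracy
$(TP+TN)/\text{total}$ on the reduced binary problem, specificity
$TN/(TN+FP)$, all in percent. A 0/0 ratio is reported as missing, never
as 0 or 100. AUC is the area under the one-vs-rest ROC curve by
threshold sweep with trapezoidal integration, which equals the
Mann–Whitney pair statistic with ties counted one half (the test suite
checks this equivalence exactly against an $O(n^2)$ pair count). A
published "AUC = TP rate / FP rate" shorthand is not an area and is
deliberately implemented as the standard ROC AUC. Macro averages
("average ratio") are unweighted means over the five classes; table
rounding (2 decimals, half away from zero) is applied only at display.

## Splitting

The two-level stratified split holds out `floor(n * 0.2)` of each class
for testing, then rounds `0.2` of the per-class remainder to the nearest
count for validation, training keeping the rest — for 5000 images per
class this yields 1000 test, 800 validation and 3200 training images per
class, an exact partition. Records are shuffled per class under the
given seed before slicing, so the assignment is a pure function of
(manifest order, fractions, seed). Whether the original study shuffled
or stratified was not stated; stratification with a seeded shuffle is
the reproducible choice.

## Synthetic fixtures

The generator emulates five image classes whose separability is
controllable, not tissue biology. Each class pairs a base colour with a
texture family — glandular-like Gaussian blobs, smooth, stripes,
speckle, checker — chosen so that every descriptor family has signal to
detect: colours separate the fuzzy colour histogram, co-occurrence
contrast separates checker from smooth, micro-patterns drive the LBP
histogram, and multi-scale energy drives the wavelet statistics. A
`separability` parameter in $[0, 1]$ linearly interpolates each class's
colour offset and texture amplitude toward a common mid-grey smooth
profile, so at 0 the five classes are exchangeable by construction and
any classifier is reduced to the 20% chance level. Defaults are 100
images per class at $64 \times 64$ pixels, colour jitter 6, noise
standard deviation 8 — a desk-scale regime in which the full pipeline
runs in well under a minute.

What passing tests show, and what they do not: recovery of synthetic
classes demonstrates that every stage is wired correctly and that the
descriptors capture the signal families they were designed for; it says
nothing about accuracy on real stained tissue, which differs in stain
variability, resolution, artefacts and intra-class heterogeneity from
any synthetic texture.

## Numerical choices and problem sizes

- Histogram outputs are asserted to sum to 1 within 1e-9; Haar energy
  conservation at 1e-9; full-rank PCA reconstruction at 1e-8; gradient
  checks at 1e-5.
- Oracle-equivalence suites (LBP, GLCM, pooling, metrics, AUC) run over
  100 seeded random instances at image sizes up to $16 \times 16$,
  where integer counts must match exactly.
- The dimension-contract checks use 475–750 synthetic images at
  $32 \times 32$ — the smallest sizes at which the published component
  counts (455, 740) are attainable, since PCA rank is bounded by
  $n - 1$.
- The recovery experiment uses the generator defaults (100 images/class,
  $64 \times 64$, separability 1 and 0, seed 7) with PCA capped at the
  244 handcrafted dimensions and the classifier at its defaults.

## Known limitations

- The pseudo-backbone is a deterministic stand-in with the right
  interface and dimensions, not a trained feature extractor; fusion
  results on real data require plugging real backbones into the adapter
  contract.
- The fuzzy colour prototypes are fitted on a fixed RGB lattice, not on
  image data, trading adaptivity for determinism.
- Equal-width LBP binning is one defensible reading of the published
  203-bin histogram; rotation-invariant and uniform-pattern variants
  are out of scope.
- The classifier is full-batch and in-memory; it is sized for feature
  matrices up to tens of thousands of rows by a thousand columns, not
  for raw-image learning.
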