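---
title: "Binary multimodal monograms: model, assumptions and design choices"
author: "marblix authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary multimodal monograms: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marblix)
```

## The problem

Digitized pathology archives and immunogenomic profiling both produce, per
patient, a single high-dimensional embedding: a pooled whole-slide-image
(WSI) feature vector `f` from a vision backbone, and an immune-repertoire
(TCR/BCR) feature vector `g` from a sequence model, each 768-dimensional
by default. Case retrieval -- "find archived patients similar to this one"
-- needs a representation that (a) fuses both modalities, (b) is tiny
enough to index millions of cases, and (c) supports a cheap distance.
marblix addresses this with the *monogram*: an 8 × 8 binary matrix (64
bits) per patient, searched by Hamming distance.

The package operates strictly downstream of feature extraction: it takes
per-patient embedding pairs plus a diagnosis label and produces codes,
archives and retrieval evaluations. Patch selection, tissue segmentation,
repertoire reconstruction and the pretrained backbones that produce `f`
and `g` are out of scope.

## The model

### Stage 1: harmonization

Embeddings from unrelated backbones live on unrelated scales, so each
dimension of each modality is min-max rescaled to [0, 1]. Three choices
here are deliberate:

* **Per-dimension, not per-vector.** Each embedding coordinate is a
  different learned feature; rescaling them jointly would let
  high-variance coordinates dominate the autoencoder loss.
* **Fitted on the training fold only**, and applied to held-out data with
  the training statistics. Fitting on all data would leak test-set range
  information into training. Held-out values outside the training range
  are clipped to [0, 1] so downstream layers never see inputs outside the
  range they were trained on.
* **Constant dimensions map to 0** (with a warning at fit time): a
  dimension with `max == min` carries no information, and 0/0 must not
  produce NaN.

### Stage 2: cross-modal latent association

Two "hybrid" autoencoders are trained, each reconstructing the *other*
modality: `A_I` maps `f -> g` and `A_S` maps `g -> f`. Both use an
encoder of dense widths 512 and 256, a 128-unit bottleneck, and a decoder
of widths 256 and 512 ending at the target dimension, minimizing mean
squared error with Adam. `A_I` trains 150 epochs at learning rate 1e-5;
`A_S` trains 50 epochs at 1e-4. The encoders' bottlenecks give the
aligned latents `u = E_I(f)` and `v = E_S(g)` used by everything
downstream; decoder weights never influence the latents.

Cross-reconstruction is the point, not a proxy: a bottleneck that must
predict the other modality keeps only cross-modally informative features
and discards modality-private noise. It also yields a built-in coherence
check -- if the modalities are unrelated, the trained model cannot beat
the column-mean predictor on held-out data, and the package's tests
verify exactly that contrast on coupled versus decoupled synthetic
cohorts (tolerance 1e-2 on the MSE margin for the null case).

Architecture choices the underlying description leaves open, fixed here:

* **Hidden activation: rectifier; output layer: linear.** Targets are in
  [0, 1] after rescaling, so an unbounded linear output is safe and keeps
  the regression unbiased. Both are configurable in spirit via
  `autoencoder_spec()` widths/epochs/rates.
* **Inputs *and* targets rescaled.** Normalization precedes association
  learning, so both sides of each reconstruction use harmonized scales.
* **Output bias initialized at the training targets' column means.**
  Weight matrices use fan-scaled (Glorot) uniform initialization, but a
  zero output bias would start every reconstruction near 0 while targets
  average near 0.5; with small fixed learning rates and fixed epoch
  counts, much of the training budget would be spent recalibrating the
  output mean. Starting at the mean predictor makes any training progress
  attributable to cross-modal structure -- which is what the coherence
  check is meant to measure.
* **Minibatches of 32 rows, reshuffled each epoch; no early stopping.**
  Epoch counts are fixed; the per-epoch loss curve is retained for
  diagnostics and convergence checks rather than for stopping decisions.

### Stage 3: monogram learning

For each patient the two 128-dim latents are fused by their outer
product `M = u ⊗ v` (a 128 × 128 rank-1 grid of all pairwise latent
interactions), flattened row-major to 16 384 values, and passed through
dense layers of widths 1024 and 256 (rectifier) to a 64-unit tanh
output, reshaped row-major into the 8 × 8 *real monogram*. Binarization
thresholds each value to a bit, giving a code space of 2^64 ≈ 1.8 × 10^19
distinct monograms.

The fusion network is trained with the triplet margin loss

$$L(a, p, n) = \max\{\, d(a,p) - d(a,n) + \alpha,\; 0 \,\}$$

where `a` is an anchor patient, `p` a same-diagnosis patient, `n` a
different-diagnosis patient, and `d` the Euclidean distance between the
64 real-valued monogram entries. Conceptually the model has three
weight-sharing branches; implementing it as one network applied to all
three triplet members enforces the sharing exactly (the package still
asserts bit-identical outputs across "branches" in its tests).

Design decisions in this stage:

* **Hard triplet mining.** Per anchor: the *farthest* same-label sample
  as positive and the *nearest* different-label sample as negative,
  measured by Euclidean distance on the concatenation `[u; v]`. The
  concatenated latents exist before the fusion model does and are stable
  across epochs, making mining reproducible; ties break toward the
  lowest row index. Triplets are refreshed every epoch (re-mined in hard
  mode, re-sampled in random mode). Anchors whose class has a single
  member are skipped with a warning.
* **Distances on real-valued monograms during training.** The binary
  branch is a hard sign function with zero gradient almost everywhere;
  no straight-through estimator is used. Binarization is applied only at
  inference.
* **Margin α = 1** by default, configurable.
* **Binarization threshold θ = 0** (strictly-greater sign rule: positive
  → 1, zero or negative → 0). A 0.5 threshold is sometimes suggested for
  this construction, but tanh outputs are symmetric about 0 and a 0.5
  cut would bias codes heavily toward 0; θ is configurable for anyone
  who wants the alternative.
* **Row-major flatten and reshape**, fixed and documented: it affects
  only the layout of bits in the code, not the semantics, but the archive
  format depends on it (bit (i, j) sits at position 8(i−1)+(j−1) from the
  most significant bit of the 16-hex-character code).
* **Full-batch updates by default.** The first dense layer holds
  latent_dim² × 1024 ≈ 17M parameters, so every gradient update pays a
  full-size gradient materialization and optimizer pass regardless of
  batch size; many small batches multiply that fixed cost while adding
  gradient noise. One Adam step per refreshed triplet set per epoch
  (150 epochs at learning rate 1e-5, as in stage 2's convention) gives a
  better-conditioned gradient at a fraction of the per-epoch cost.
  `monogram_spec(batch_size = 32)` restores minibatching.
* **Adam update in compiled code.** The optimizer step for the fusion
  layer is a single fused in-place C++ pass; doing it with R vector
  arithmetic would allocate several 17M-element temporaries per update.
* **Zero-distance guard.** When an anchor and its positive (or negative)
  produce identical real monograms, the unit vector in the gradient is
  undefined; that term is dropped for that triplet rather than dividing
  by ~0.

### Retrieval and evaluation

The archive stores `(patient_id, label, 64-bit code)`; search is an
exhaustive Hamming scan (at 64 bits and archive sizes in the thousands,
approximate indexing would add machinery without measurable benefit).
Evaluation is leave-one-out: each record queries the archive with itself
removed and is classified by majority vote over the top-k neighbors
(top-1 and MV@3/5/10), scored by macro-averaged precision/recall/F1 over
the classes present in the ground truth plus accuracy. Macro averaging
matters because realistic cohorts are imbalanced (e.g. a rare subtype
with a tenth of the cases of a common one): accuracy can look strong
while the rare class is never retrieved correctly.

Two rules the evaluation needs but the underlying description does not
fix, chosen for determinism:

* **Distance ties** rank by ascending patient id.
* **Vote ties** go to the tied label whose first occurrence ranks best.

"Real monogram" retrieval ranks by Euclidean distance on the 64 tanh
values with the same vote machinery, quantifying what binarization
costs. The unimodal baselines rank by Euclidean distance on the
min-max-rescaled raw embeddings -- rescaled rather than raw so that the
baseline and the pipeline see identically harmonized inputs. XOR maps
(`xor_map()`, `dissimilarity_heatmap()`) localize *which* of the 64 code
features differ within and between subtypes; the count of nonzero cells
in a map is exactly the Hamming distance.

### Cross-validation protocol

`run_experiment()` assigns patient-level stratified folds (per-class
counts within ±1 across folds; every patient in exactly one fold), fits
scalers, both autoencoders and the fusion network on the training fold
only, and evaluates the held-out fold leave-one-out. Two-fold
cross-validation is the default, matching the protocol used for
three-class cohorts whose rarest subtype is too small for five folds;
five folds suit large two-class cohorts. Every sub-seed derives from the
master seed, so a rerun with the same seed is bit-identical; the leakage
guard (train/test id disjointness) is asserted inside the driver and
again from the emitted manifests in the tests.

## The synthetic cohort generator

`generate_cohort()` exists so the whole pipeline can be exercised and
validated without access to protected patient data. It emulates the
*structure* the pipeline relies on -- two coupled views of one latent
patient state with class-dependent means -- using the simplest model the
cross-modal autoencoders can provably exploit:

* per patient of class c: a shared latent `z ~ N(mu_c, I_s)` with
  `s = 16` by default;
* modality embeddings `f = A z + eps_f`, `g = B z + eps_g`, with mixing
  maps `A` (768 × s) and `B` (768 × s) drawn once per cohort with
  `N(0, 1/s)` entries, and isotropic noise with sd 0.5;
* class means `mu_c` at *distinct vertices of the ±class_sep hypercube*
  in the latent space (`class_sep = 2` by default). This is the standard
  construction for synthetic classification benchmarks: the per-
  coordinate shift magnitude is `class_sep`, so two classes differing in
  m latent coordinates sit `2·class_sep·sqrt(m)` apart. With the default
  s = 16, typical pairs differ in about half the coordinates, giving
  strongly separable classes -- deliberately so, since the pipeline's
  end-to-end validation asks whether monograms *preserve* recoverable
  structure, and the real cohorts this emulates (cancer subtypes with
  distinct morphology and immune profiles) are themselves strongly
  separable.
* default size 3 classes × 100 patients: large enough that fold-level
  retrieval statistics are stable, small enough that the full
  cross-validated pipeline trains in minutes on one CPU. Per-class
  counts accept a vector for imbalanced designs.

The `coupling = "independent"` mode is the matched null: the sequence
modality redraws its latent under a random *permutation* of the cohort's
class assignments, which preserves g's marginal distribution exactly
(same mixture, same mixing map) while removing both the cross-modal
coupling and g's association with the true labels. This is the cohort on
which cross-reconstruction must *fail* to beat the mean predictor.

What the generator does **not** emulate -- and therefore what passing
tests do not establish about real data: heavy-tailed and correlated
feature noise from real backbones, hospital- or scanner-specific batch
structure, label noise, partially overlapping subtypes, and modality
dropout. Linear-Gaussian coupling is also far kinder to the autoencoders
than real WSI-repertoire relationships; success here demonstrates
correctness of the machinery, not clinical performance.

## Validation surface and problem sizes

The test suite validates every operation against an independent oracle
(bit-loop Hamming counts, nested-loop outer products, hand-computed
confusion matrices, exhaustive triplet search on cohorts ≤ 50,
full-sort retrieval rankings), checks the closed-form triplet-loss
cases, and asserts the statistical contrasts above (coherence,
intra- vs inter-class Hamming, loss decrease, leakage, determinism).
End-to-end checks run at the default study size (3 × 100 patients,
768-dim modalities, 2 folds, default schedules); unit tests use
scaled-down cohorts (tens of patients, ~40-dim embeddings, 16-dim
latents) with faster schedules (learning rate 1e-3, tens of epochs),
since they test mechanics, not the default operating point.
`scripts/acceptance.R` re-runs the default-scale experiment and the
coherence contrast from scratch and writes the resulting numbers as
JSON.

## Known limitations

* At the default learning rates and epoch counts, the fusion network
  moves its weights only a small fraction of their initialization scale;
  on strongly separable cohorts much of the binary codes' discriminative
  power is inherited from the latent separation through the (initially
  random) projection, with triplet training providing refinement. Harder
  cohorts (lower `class_sep`, higher `noise_sd`) may need more epochs or
  a larger learning rate than the defaults.
* Hard mining with a fixed latent space yields the same triplet set each
  epoch (refreshing only matters in random mode or if the mining space
  changed); this mirrors the mining-on-latents design rather than
  mining on the evolving monograms.
* The per-batch hospital/batch-effect shift present in some real
  cohorts is not simulated.
* Two modalities only; the fusion is specifically bimodal (outer
  product), not n-ary.
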