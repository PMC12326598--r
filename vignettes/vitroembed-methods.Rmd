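---
title: "Biologically informed molecular embeddings for imbalanced toxicity endpoints"
author: "vitroembed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biologically informed molecular embeddings for imbalanced toxicity endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Preclinical and clinical liver-toxicity endpoints (drug-induced liver
injury, DILI) are hard to model from chemical structure alone: labeled
datasets are small (hundreds of compounds), severely imbalanced (toxic
positives are a few percent of observations), and the relationship
between structure and organism-level toxicity is indirect. Two ideas
address this jointly in `vitroembed`:

1. **Biologically informed pretraining.** A bidirectional transformer
   encoder over SMILES tokens is pretrained not only on masked-token
   recovery and physicochemical-descriptor regression (which teach it
   chemistry), but also on a large panel of binarized in vitro assay
   outcomes (which teach it how molecules interact with biological
   targets). The in vivo endpoints of interest are downstream of exactly
   these cellular interactions, so embeddings that encode them transfer
   better than purely chemistry-trained ones.
2. **An imbalance-aware loss family.** Binary cross-entropy treats every
   observation equally and lets abundant negatives dominate training.
   The package's primary objective is the *weighted focal loss*, which
   both up-weights positives by an interpolated inverse class ratio and
   down-weights well-classified (easy, mostly negative) examples.

## The loss family

For task $p$ with observed positive/negative counts $N_{p+}, N_{p-}$,
the positive weight is

$$ w^+_p = \alpha \frac{N_{p-}}{N_{p+}} + (1 - \alpha), \qquad
   \alpha \in [0, 1], $$

so $\alpha = 0$ gives unweighted training and $\alpha = 1$ the full
inverse-ratio balancing. The weighted focal loss over molecules $n$ and
tasks $p$ with labels $y_{np}$ and logits $f_{np}$ is

$$ \mathcal{L}^{w}_{FL} = \sum_{n,p}
   w^+_p \left(1 - \sigma(f_{np})\right)^\gamma y_{np}
   \left(-\log \sigma(f_{np})\right) +
   \sigma(f_{np})^\gamma (1 - y_{np})
   \left(-\log(1 - \sigma(f_{np}))\right). $$

The focusing exponent $\gamma \ge 0$ multiplies each entry's
cross-entropy by the probability mass currently assigned to the *wrong*
class, raised to $\gamma$: confidently correct entries contribute almost
nothing, so optimization concentrates on the hard minority. The family
collapses exactly to focal loss at $\alpha = 0$, to weighted BCE at
$\gamma = 0$, and to plain BCE at $\alpha = \gamma = 0$; the test suite
asserts these identities to $10^{-10}$ on random sparse panels.

Three conventions are worth stating:

* **Sign.** The loss is implemented as a non-negative quantity (the
  negative log-likelihood form), so that the BCE reduction holds and
  per-class log-losses are positive.
* **Missing labels are first-class.** Assay panels are sparse; `NA`
  entries contribute zero loss and exactly zero gradient, and all class
  counts (hence weights) are computed over observed entries only.
* **Reduction.** The default reduction is the mean over observed entries,
  which makes magnitudes comparable across batch sizes; `reduction =
  "sum"` gives the literal double sum.

Numerically, all log-probabilities go through the stable log-sigmoid
(`plogis(..., log.p = TRUE)`); probabilities are never clipped.

The per-class log-loss diagnostic (`classwise_logloss()`) reports, per
task, the mean $-\log \sigma(f)$ over positives and
$-\log(1 - \sigma(f))$ over negatives. A wide gap between the two is
the signature of a network biased toward the majority class.

## Encoder and pretraining

The encoder is a standard pre-norm transformer: token plus learned
position embeddings (layer-normalized), $L$ blocks of multi-head
self-attention and a GELU feed-forward (each wrapped in residual
connections), and a final layer norm. The full-scale configuration is
12 layers, 12 heads, 768 hidden units, maximum sequence length 128; a
desk preset (`encoder_config_tiny()`: 2 layers, 4 heads, 64 hidden) is
used throughout the test suite. SMILES are tokenized with a regex
grammar (bracket atoms, two-letter halogens, ring digits and bond
symbols as single tokens) and wrapped in begin/end markers.

Three heads sit on the encoder:

* **MaskingHead** — linear layer, GELU + layer norm, one further encoder
  block, and a projection to the vocabulary; trained with masked-token
  cross-entropy.
* **PhysChemHead** — one hidden layer estimating the normalized
  physicochemical descriptor vector; trained with mean squared error
  (squared Euclidean norm per molecule, mean over the batch).
* **InvitroHead** — one hidden layer producing one logit per in vitro
  task; trained with the weighted focal loss at fixed $\alpha = 1$,
  $\gamma = 2$ (no tuning at the pretraining stage).

Each batch is processed twice (*dual pass*): once with 15% of
non-special tokens replaced by the mask token (feeding the masking
head) and once clean (feeding the physchem and in vitro heads). The
combined objective is the arithmetic mean of the enabled head losses;
disabling the in vitro head recovers the purely chemistry-trained
masked-language-model objective without touching the encoder
architecture.

Training uses Adam with linear warmup (1% of steps) followed by linear
decay to zero, the usual convention for BERT-style pretraining; a
constant schedule is available. Batches are length-bucketed (sequences
of similar length grouped within shuffled blocks) so padded width tracks
content. The per-epoch history records validation physchem loss,
masked-token accuracy and in vitro macro-AUPR.

Two choices the architecture leaves open were resolved as follows:

* **Pooling.** The molecule-level representation is, by default, the
  first-position (begin-marker) state passed through a learned tanh
  layer, the conventional sentence summary; mean pooling over non-pad
  positions is available (`pooling = "mean"`) and is what the synthetic
  experiments use, since with a 2-layer encoder the averaged state is a
  markedly stronger readout than a single position.
* **Masking policy.** All selected tokens become the mask token; the
  BERT-style 80/10/10 replace/random/keep split is behind
  `bert_style = TRUE`.

### Numerical implementation

There is no automatic differentiation in this stack, so forward and
backward passes are written out analytically. The transformer block has
two interchangeable implementations: a pure-R reference and a compiled
(RcppArmadillo) fast path; the test suite asserts they agree to machine
precision and validates the full model gradient against central finite
differences. GELU uses the sigmoid approximation
$x\,\sigma(1.702x)$, which is numerically indistinguishable for
training purposes and several times cheaper than the exact Gaussian-cdf
form. Attention masks padding by setting key scores to $-10^9$ before
the softmax.

## Downstream protocol

The pretrained encoder is frozen. Embeddings for downstream molecules
(`extract_embeddings()`) feed a multitask MLP head: one hidden layer
with batch normalization, ReLU and dropout, whose output is
concatenated with the input (a skip connection) before the final
linear layer and sigmoid. The head is trained with the same weighted
focal loss family; `fit_downstream()` runs the full protocol — the
designated test fold is held out before any tuning, candidate
hyperparameters (including $\alpha$ and $\gamma$) are scored by inner
K-fold cross-validation on macro validation AUPR, the winner is
retrained on all non-test data, and the test fold is scored once.
Early stopping (patience 10 epochs on validation AUPR) is available
when a validation set is supplied.

Baselines (`fit_baselines()`): a per-task random forest on 1024-bit
ECFP6 fingerprints with `mtry` tuned by inner CV, and the same
multitask MLP head on fingerprints, under the identical split protocol
and metric schema.

Splits are scaffold-disjoint: molecules are grouped by Bemis-Murcko
framework (ring systems plus linkers, retaining multiply-bonded
substituents such as carbonyl oxygens; acyclic molecules form singleton
groups), and whole groups are greedily packed largest-first into K
folds. The designated test fold is the one holding the most distinct
scaffold groups — the hardest, most chemically diverse generalization
target.

## Evaluation

AUPR is the primary metric, computed by step-wise interpolation over
achieved recall levels (the average-precision estimator; linear
interpolation between PR points is optimistically biased and is not
used). ROC-AUC uses the rank-based Mann-Whitney estimator, MCC a fixed
0.5 threshold. `imbalance_sensitivity()` reports the Spearman
correlation between per-task AUPR and positive ratio — a model whose
performance merely tracks prevalence has learned little beyond the
base rate — and `logloss_gap_report()` tabulates the per-class
log-losses with a 95% covariance-ellipse summary (the ellipse is a
normal-theory construction, labeled as such).

## The synthetic corpus generator

No external chemical or assay data ship with the package; every claim
is tested on corpora from `generate_corpus()`. Design:

* **Molecules** are assembled from a curated fragment inventory — 20
  ring systems, 10 linkers, ~30 terminal chains, all within the organic
  element subset — as prefix + ring (+ linker + ring) + suffix strings.
  This guarantees chemical validity (every generated SMILES survives
  the ingestion filters unchanged), bounded length, and a realistic
  scaffold-group size distribution for split testing.
* **In vitro tasks** follow a logistic model on fingerprint-bit
  features. Each task draws a few single bits and several bit
  *conjunctions* (both substructures must co-occur) from a shared pool,
  mirroring pharmacophore logic — binding typically requires several
  features together — and making activity a non-additive function of
  composition. The structural log-odds are standardized to sd
  $\beta = 2.5$ against logistic noise (sd $\approx 1.81$), the
  intercept is calibrated on the realized sample so observed prevalence
  hits the target, and count-exact, label-stratified flips (1%) and
  missingness (30%) keep that calibration at every seed. Latent
  activities are stored alongside the labels for oracle checks.
* **In vivo tasks** have log-odds equal to a standardized
  coupling-weighted sum of a few latent in vitro activities (scaled so
  the coupled signal is about twice the logistic noise at
  `coupling = 1`) and small prevalences drawn from [0.02, 0.2],
  mimicking DILI-endpoint imbalance. At `coupling = 0` the labels are
  independent of structure. The generator also emits dose/time readout
  and ordinal severity tables whose any-exceedance / max-severity
  pooling reproduces the binary labels exactly, so the label-building
  operations are tested against a known ground truth.

What the generator does **not** emulate: real assay value
distributions, inter-laboratory variance, activity cliffs beyond pair
conjunctions, tautomerism/stereochemistry, or the ontology structure of
adverse-event vocabularies. Passing tests demonstrate the machinery and
its statistical behavior, not performance on real chemistry.

## Desk-scale experiments

Two end-to-end experiments anchor the test suite; both run on one CPU.

* **Class-bias reproduction.** A 2000-molecule corpus with one task at
  prevalence 0.05; the fingerprint MLP head is trained under BCE,
  weighted BCE, focal and weighted focal losses and evaluated on the
  held-out scaffold fold. Held-out evaluation matters: on the training
  fold a 128-unit head separates the task completely and every loss
  collapses toward zero, so the bias phenomenon is only visible out of
  sample. The positive-class log-loss falls strictly in the order
  BCE > BCE$^w$ > FL$^w$ and the positive/negative gap shrinks
  accordingly.
* **Embedding utility** (`embedding_utility_experiment()`). One
  2000-molecule corpus with 20 in vitro tasks; a chemistry-only (mask +
  physchem) base encoder is pretrained once and then continued, per
  training seed, in two modes — with and without the in vitro head —
  mirroring the practice of warm-starting biologically supervised
  pretraining from a masked-language-model checkpoint. The frozen
  embeddings feed the downstream head on five coupled in vivo tasks,
  trained on a single scaffold fold (~400 molecules — in vivo data is
  scarce relative to pretraining, as it is in practice) and evaluated
  on the scaffold-disjoint remaining ~1600 molecules, which keeps the
  AUPR estimate precise enough to resolve transfer margins of a few
  thousandths. A coupling-zero control reuses the same embeddings on
  structure-independent labels, where neither mode should hold an
  advantage; it sits at zero, validating the measurement. A candid
  caveat on what the desk-scale run shows: because synthetic in vitro
  labels are, by construction, functions of molecular structure, the
  chemistry-only objectives already expose most of the same structural
  features to the downstream head (a fresh head decodes the planted in
  vitro tasks about equally well from either embedding), so the
  measured in vivo transfer margin at this scale is positive on every
  seed but very small — well under 0.01 AUPR, an order of magnitude
  below the published effect. The full advantage of biologically
  informed pretraining is expected to emerge where in vitro supervision
  covers chemistry far beyond the downstream corpus — the
  million-compound regime, not the desk one; the experiment function
  exposes the schedule so larger runs can probe this.

## Known limitations

* Descriptor inventory is ~30 OpenBabel/structural descriptors, not the
  ~200 of RDKit-based pipelines; the descriptor dimension is
  configurable and normalization statistics always come from the
  training split only.
* The desk-scale encoder is orders of magnitude below the scale at
  which in vitro pretraining shows its full effect; the synthetic
  experiments demonstrate the machinery and direction of the effect,
  not its published magnitude.
* Aromatic canonical SMILES are used throughout (no kekulization
  option) and stereochemistry is not enumerated.
* MCC's 0.5 threshold is a convention; calibrate probabilities before
  reading it quantitatively.
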