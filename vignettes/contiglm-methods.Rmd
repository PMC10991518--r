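---
title: "Masked modeling of gene order: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked modeling of gene order: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Microbial genomes are not bags of genes. The genomic neighborhood a gene
occurs in — which families flank it, in which order and orientation — is
shaped by selection on co-regulation (operons), co-function, and horizontal
transfer. `contiglm` treats a contig as a *sentence* whose *words* are genes:
each gene token is a fixed protein-family embedding concatenated with an
orientation flag (+0.5 forward / -0.5 reverse), and a transformer encoder is
trained with a masked-token objective to reconstruct hidden genes from their
genomic context. Everything downstream — operon recovery from attention,
contextualized gene and contig embeddings, context-variance, paralog
matching — reads information out of that trained encoder.

## Model

**Tokens and labels.** Input embeddings are z-scored per feature and clipped
to ±10 (clipping keeps rare outlying features from dominating early
training). The regression target for a masked gene is deliberately lower
dimensional than the input: the embedding's first `k_pc` PCA-whitened
component scores concatenated with the orientation flag
(`label_dim = k_pc + 1`; 99 + 1 at full scale, 16 + 1 at desk scale).
Whitening makes the squared-error loss isotropic across label coordinates.
Component signs are fixed by forcing each component's largest-magnitude
loading positive, so refits are reproducible. Normalizer and projector are
always fitted on the training corpus only.

**Encoder.** A post-layer-norm transformer encoder: an affine input adapter
maps `input_dim = E + 1` to the hidden width, then each block applies
multi-head self-attention followed by a GELU feed-forward, each with residual
connection and layer norm. Attention uses learned relative key-query position
terms: with per-layer table \(R\) indexed by the clipped signed offset
\(\delta(i,j)\),

\[ s_{ij} = \frac{q_i k_j^\top + q_i R_{\delta(i,j)}^\top + k_j R_{\delta(i,j)}^\top}{\sqrt{d_h}} . \]

`max_rel_distance` defaults to the maximum contig length (30), so every
pairwise offset gets a distinct embedding and the clipping branch never
activates at the supported lengths. Padding tokens are excluded from the
computation altogether, so attention mass on padded keys is exactly zero and
outputs are invariant to batch composition.

**Multi-prediction head.** More than one gene can legitimately occupy a
genomic niche, so the head makes `n_pred = 4` label-space predictions per
masked position plus 4 logits forming a likelihood simplex, all from one
joint affine map of the final hidden state. The loss is

\[ \mathrm{MSE}(\text{closest prediction}, \text{label})
   + \alpha\,\mathrm{CE}(\text{likelihoods}, \text{closest index}), \qquad \alpha = 10^{-4}, \]

where *closest* is the L2-nearest prediction (ties broken toward the lowest
index, for determinism). The MSE is averaged over masked positions *and*
label dimensions, so `alpha`'s meaning does not drift with batch size or
label width; the reduction is a documented choice, as is treating the argmin
index as a constant in the gradient. The likelihood head is trained only
through the cross-entropy term; because AdamW adapts per-parameter step
sizes, the small `alpha` still produces a usable confidence signal (the
high-confidence accuracy check below measures exactly this).

**Masking.** Each gene is masked independently at rate 0.15, with the whole
(E+1)-vector — orientation slot included — set to −1. The paper-style
single corruption mode is used (no BERT-style 80/10/10 split). A contig whose
draw masks nothing is redrawn until at least one gene is masked, so every
example contributes loss; this floors the per-contig rate and biases the
marginal rate upward by about +0.1 percentage points at length 30 (and
visibly more at length 15, which is why the rate check in the tests uses
30-gene contigs). The masking question the description leaves open —
exact-fraction versus Bernoulli masking — is resolved as Bernoulli with the
floor, and the bias is measured rather than hidden.

**Training.** AdamW (decoupled weight decay 0.01 on weight matrices only),
global gradient-norm clip at 1.0, linear warmup to the peak learning rate.
The post-warmup schedule is not otherwise specified; both a constant rate
and linear decay to zero are provided, and the desk recipe holds the rate
constant (on this corpus decay gave no measurable benefit). Validation splits
hold out whole contigs; the checkpoint kept is the best validation
pseudo-accuracy. Training runs in double precision: half-precision is a
throughput optimization for GPU clusters and would only cost determinism
here.

## Evaluation metrics

*Pseudo-accuracy*: a masked prediction is correct when it is strictly nearer
(L2, in full label space including the orientation coordinate) to the masked
gene's own label than to any other gene label in the same subcontig; ties
count as incorrect (conservative and deterministic). The prediction scored is
the highest-likelihood one, matching the confidence analysis; best-of-n is
reported as a secondary diagnostic. *Absolute accuracy* applies the same rule
against the label universe of a whole genome, masking each gene singly; since
the universe contains each subcontig's labels, it can never exceed
pseudo-accuracy. When every label in a subcontig is exchangeable with the
prediction's information set, the expected pseudo-accuracy is exactly
\(1/L\) — this analytic null anchors the calibration tests.

## The synthetic corpus: what it emulates, and what it does not

The generator plants every statistical structure the analyses assume, with
ground truth:

- **families** with isotropic Gaussian within-family noise (`noise_scale`;
  0 gives bit-identical occurrences, driving exact-zero variance tests);
- **context rules**: first-order family successor distributions —
  deterministic chains make contexts informative, and two-successor rules
  with equal mass create the genuinely ambiguous niches that justify a
  four-way head;
- **operon blocks**: contiguous, co-oriented, never split across contigs;
- **interacting pairs**: planted strictly as "X immediately followed by Y,
  forward", nowhere else, giving exact paralog-matching truth;
- **contig classes** with distinct family-usage weights for the taxonomy
  probe.

The canonical study corpus (`demo_corpus()`) fixes these choices: 120
families in 32 dimensions, noise s.d. 0.05, four deterministic five-family
chains plus one ambiguous rule, contig lengths uniform on 15–30, eight
planted pairs (pair probability 0.1), 2000 contigs.

Two of its choices deserve explanation because they depart from the simplest
design, and both exist to preserve at desk scale a property that holds
trivially at full scale: *an untrained encoder's attention should carry
essentially no operon information*.

1. **Operon composition is diverse.** Blocks are three-gene walks on a
   deterministic successor graph over an 80-family operonic pool (one
   designated successor per family), rather than a couple of fixed
   templates, and pool families also occur freely as background singles.
   With a handful of fixed templates, a logistic regression on the untrained
   model's eight adjacent-pair attention values can simply memorize which
   family pairs are operonic — attention entries are deterministic functions
   of the token embeddings, so they act as a hash of the pair identity, and
   memorization generalizes across cross-validation folds because the same
   pairs recur. That failure mode is an artifact of low diversity: a real
   corpus has far too many distinct operonic pairs for 190 scalar features
   to memorize. The design question is how to decouple what the encoder
   needs (determinism: a masked block gene pinned down by its neighbor) from
   what the memorizer needs (few recurring pair types): a deterministic
   graph over a *large* pool does both, yielding 80 distinct operonic family
   pairs — each fully predictive, each recurring a few dozen times, together
   beyond the linear memorization capacity of an 8-feature classifier
   (a 40-family pool, by contrast, measurably re-opens the memorization
   channel).
2. **Orientations form strand runs.** Background genes keep the previous
   gene's orientation with probability 0.93 and an inserted block continues
   the current run, the way operons sit inside directons. With independent
   coin-flip orientations, "both genes co-oriented" alone separates operonic
   pairs well above prevalence — again information an untrained model's
   features expose. Strand runs are also the more faithful model: in real
   microbial genomes most adjacent gene pairs are co-directional.

Even so, a small residue of operon information remains linearly accessible
from untrained attention at this scale (a few hundredths of average
precision above prevalence, varying with the initialization seed); the
corresponding negative control should be read with that floor in mind.

What the generator does *not* emulate: nucleotide sequence, intergenic
spacing, codon structure, paralogous family similarity structure (centers
are i.i.d. isotropic, so between-family similarity carries no phylogenetic
signal), genome-scale gene-content correlations, or any real protein
language model geometry. Passing recovery tests on this corpus demonstrates
that the machinery — model, training, metrics, statistics — extracts planted
structure of the intended kinds at the intended scales; it does not
demonstrate biological performance on real embeddings.

## Desk scale

The desk model is 4 layers × hidden 128 with two 64-dimensional heads per
layer (mirroring the full-scale 1280/10 = 128 per-head width), `n_pred = 4`,
17-dimensional labels; training is 2400 AdamW steps of 24 contigs with 50
warmup steps to 1e-3 decaying linearly afterwards, on a 2000-contig corpus
with a 10% validation split.
These sizes were chosen so the complete study — corpus, training, and all
recovery analyses — runs comfortably on a single CPU core, and they are the
configuration under which the package's reported numbers are produced. The
training recipe differs from the full-scale one only in scale (the published
run used batch 3000 and 5000 warmup steps to 1e-4 over ~1.3M steps on GPUs).

## Downstream statistics: conventions and numerics

- **Attention symmetrization** uses \((A + A^\top)/2\), which preserves total
  attention mass; the pair feature for the operon analyses is the single
  symmetrized entry \((i, i+1)\) per layer/head — the minimal faithful
  reading of "the attention corresponding to the gene pair".
- **Per-head correlation** pools pairs across contigs into one global
  Pearson correlation per head (the alternative — averaging per-contig
  correlations — weights short contigs heavily and discards cross-contig
  contrast); p-values are Bonferroni-adjusted across heads. Constant heads
  are reported as missing rather than zero.
- **Logistic regressions** (operon classifier, taxonomy classifier) are
  ridge-regularized at a fixed, recorded `lambda = 1e-3` with standardized
  features; regularization keeps separable folds finite and the value is
  part of the result object. Cross-validation is stratified 5-fold; average
  precision uses the step-wise (scikit-learn-style) interpolation.
- **Gaussian KL.** The closed form
  \(\tfrac12[\mathrm{tr}(\Sigma_1^{-1}\Sigma_0) - k +
  (\mu_1-\mu_0)^\top\Sigma_1^{-1}(\mu_1-\mu_0) +
  \ln(\det\Sigma_1/\det\Sigma_0)]\) is computed via Cholesky factors; a
  singular covariance triggers a ridge of `1e-6 · trace/k` added to *both*
  covariances (so self-divergence stays zero), with a warning recording the
  ridge. Preprocessing follows the published pipeline: per-set Mahalanobis
  outlier removal at the chi-squared 0.975 quantile, then one PCA fitted on
  the pooled filtered sample so both distributions live in a common reduced
  space. The printed source formula contains two evident typographical slips
  (a "det 0" denominator and a stray μ subscript); the standard form above is
  what is implemented.
- **Context variance** follows the 10 × 100 sampling protocol (10
  independent samples of 100 occurrences, mean pairwise Euclidean distance,
  averaged), excluding occurrences at the first or last contig position;
  genes under the occurrence threshold are skipped with a message, and the
  per-gene distribution is summarized by excess kurtosis and skew.
- **Linear probes** are a single affine layer with softmax, trained by Adam
  on cross-entropy with early stopping (patience 10 epochs on a 20% held-out
  split) — the probe's training procedure, not a library classifier, is the
  specified instrument. Replicate refits provide error bars, and per-class
  F1 comparisons use two-sided t-tests with Benjamini–Hochberg correction
  across classes.
- **Paralog matching** builds the three-token test contig (mask, query
  forward, mask), scores each flank's highest-likelihood prediction against
  the candidate labels by L2, and counts a query correct if *either* flank
  retrieves the true partner (the flank reading of "either of the proteins
  closest"). The chance null replays the identical matching with standard
  normal prediction vectors, 1000 iterations.

## Known limitations

- The desk-scale corpus is first-order Markov with i.i.d. family centers;
  none of the analyses here say anything about real ESM2 geometry. Real
  embeddings enter only through the corpus reader / embedding container
  interface.
- The untrained-attention operon control has the capacity floor discussed
  above; at desk scale it sits within a few hundredths of prevalence rather
  than exactly at it.
- `absolute_accuracy` is quadratic in genome size (every gene masked singly
  against the full label universe) and is intended for small genomes.
- The homology-aware validation split of the full-scale study (70% identity
  exclusion) requires a sequence-similarity oracle; the desk pipeline holds
  out whole contigs at random instead, which is the correct hygiene for a
  synthetic corpus without sequences.
- Whether the final "hidden layer" includes the closing layer norm is an
  implementation degree of freedom; here layer `n_layers` is the encoder's
  final output (after its layer norm), and layer 0 is the projected input.
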