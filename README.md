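# contiglm

Masked language modeling of gene order in microbial contigs, in R.

Microbial genes live in informative neighborhoods: operons group co-regulated
genes on one strand, functional modules recur across genomes, and horizontal
transfer moves genes between contexts. `contiglm` models a contig as an
ordered sequence of gene tokens — each a fixed protein-family embedding plus
an orientation flag (+0.5 / −0.5) — and trains a transformer encoder with a
masked-token objective to reconstruct hidden genes from their genomic
context. The trained encoder then serves as an instrument: its attention
patterns predict operonic linkage, its hidden states give *contextualized*
gene and contig embeddings, and those embeddings support function probes,
context-variance analysis, and paralog matching.

## The model

A gene token `x ∈ R^(E+1)` is z-scored and clipped to ±10. The training label
of a gene is deliberately compact: its `k` PCA-whitened component scores
concatenated with the orientation flag (`k + 1` features). The encoder is a
post-layer-norm transformer with learned relative key-query position terms,

```
s_ij = ( q_i·k_j + q_i·R[δ(i,j)] + k_j·R[δ(i,j)] ) / sqrt(d_h),
```

and each masked position is decoded by one affine head into `n_pred = 4`
label-space predictions plus a likelihood simplex over them. The loss is

```
MSE(closest prediction, label) + α · CrossEntropy(likelihoods, closest index),   α = 1e-4,
```

with *closest* = L2-nearest prediction. Quality is measured by
*pseudo-accuracy* — a masked prediction is correct when it is nearer to the
masked gene's own label than to any other gene label in the same subcontig —
and by *absolute accuracy* against a genome-wide label universe. The
transformer, its backward pass, and AdamW are implemented directly in R
matrix code (see the gradient finite-difference tests).

The package also contains a first-class synthetic-corpus generator
(`sample_corpus()` and friends) that plants gene families, operon blocks,
deterministic and ambiguous context rules, strand runs, contig classes, and
interacting gene pairs — with ground truth — so that every downstream
statistic has a recovery test.

## Worked example

```r
library(contiglm)

# canonical desk-scale study: 2000 synthetic contigs, 4-layer/128-hidden model
study <- desk_study(n_contigs = 2000, seed = 1)

# held-out masked-gene recovery
vb  <- mask_batch(study$val_contigs, 0.15, study$proj, seed = 999)
out <- glm_forward(study$model, vb)
as.numeric(pseudo_accuracy(out$predictions, vb))
#> [1] 0.3919668            # exchangeable-label baseline is 1/22.5 = 0.044
confidence_report(out$predictions, vb, tau = 0.75)
#> $high_conf_fraction
#> [1] 0.02493075
#> $high_conf_accuracy
#> [1] 0.8333333
#> $overall_accuracy
#> [1] 0.3919668

# operon recovery from attention
pf <- pair_attention_features(study$model, study$val_contigs[1:150])
head(head_operon_correlation(pf), 3)
#>   head layer head_index       rho      p_value   p_adjusted
#> 8 L4H2     4          2 0.2795197 4.122751e-58 3.298201e-57
#> 6 L3H2     3          2 0.2594766 4.782925e-50 3.826340e-49
#> 5 L3H1     3          1 0.2014186 1.951042e-30 1.560834e-29
train_operon_classifier(pf)[c("ap_mean", "ap_sd", "prevalence")]
#> $ap_mean
#> [1] 0.5392101
#> $ap_sd
#> [1] 0.01706573
#> $prevalence
#> [1] 0.3260938
```

The numbers above were produced by this code at the defaults (seed 1): the
trained model recovers masked genes at ~9× the exchangeable baseline, its
high-confidence predictions are far more accurate than its average
prediction, individual attention heads correlate with the planted operon
structure well beyond their permutation null, and the all-heads classifier
predicts operonic linkage well above the 0.33 operon prevalence.

## Command line

A thin CLI wraps the same functions for shell pipelines:

```sh
contiglm simulate --out corpus/ --n-contigs 2000 --seed 1
contiglm train    --corpus corpus/ --checkpoint model.rds
contiglm eval     --corpus corpus/ --checkpoint model.rds --out eval.json
contiglm embed    --corpus corpus/ --checkpoint model.rds --out embeddings/
contiglm operon   --corpus corpus/ --checkpoint model.rds --operons corpus/operons.tsv
```

## Package layout

- `R/synthetic-corpus.R` — family catalogs, operon templates, context rules,
  interacting pairs, corpus sampling (`demo_corpus()` is the canonical study
  configuration).
- `R/corpus-io.R` — normalization, PCA-whitened labels, masking, the on-disk
  corpus format (JSONL index + binary embedding container, TSV fixtures,
  operon pair tables).
- `R/glm-model.R`, `R/glm-forward.R` — the transformer encoder, forward and
  hand-written backward passes, the multi-prediction loss.
- `R/train.R` — AdamW training loop, pseudo/absolute accuracy, confidence
  analysis, checkpoints.
- `R/inference.R` — contextualized and masked-context embeddings,
  symmetrized attention maps, contig pooling, pair attention features.
- `R/downstream-*.R` — head-operon correlation, cross-validated operon and
  taxonomy classifiers, Gaussian KL with Mahalanobis/PCA preprocessing, KL
  ratio, context variance, linear probes, paralog matching, silhouette.
- `vignettes/contiglm-methods.Rmd` — model assumptions, parameter choices,
  what the synthetic corpus does and does not emulate, numerical
  conventions, limitations.
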