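# Canonical desk-scale study: one place defining the model / training /
# corpus conventions used by the worked examples, the recovery analyses and
# the reproduction script.

#' Desk-scale model configuration
#'
#' Four layers with hidden width 128 and two 64-dimensional attention heads
#' per layer (the closest multi-head analog of the full-scale 1280/10 = 128
#' per-head width), four predictions per masked position, and labels built
#' from 16 whitened principal components plus orientation (label_dim 17) over
#' 32-dimensional family embeddings (input_dim 33).
#'
#' @export
desk_config <- function() {
  glm_config(n_layers = 4L, hidden = 128L, n_heads = 2L, n_pred = 4L,
             input_dim = 33L, label_dim = 17L, max_rel_distance = 30L)
}

#' Desk-scale training configuration
#'
#' 2400 AdamW steps of 24 contigs with 50 warmup steps to a peak learning
#' rate of 1e-3 held constant afterwards, 15% masking, a 10% held-out
#' validation split, and the likelihood weight at its published value 1e-4.
#'
#' @param seed integer seed for the split, shuffling and masking.
#' @export
desk_train_config <- function(seed = 1L) {
  train_config(total_steps = 2400L, batch_size = 24L, warmup_steps = 50L,
               peak_lr = 1e-3, mask_rate = 0.15, alpha = 1e-4,
               val_fraction = 0.1, eval_every = 100L, lr_decay = "constant",
               seed = seed)
}

#' Run the full desk-scale study
#'
#' Generates the canonical corpus ([demo_corpus()]), fits the normalizer and
#' the 16-component label projector on it, trains the desk model, and returns
#' every artifact needed by the downstream analyses.
#'
#' @param n_contigs corpus size (default 2000).
#' @param seed integer master seed.
#' @param quiet suppress training progress.
#' @return list: `corpus` (raw `synthetic_corpus`), `contigs` (normalized),
#'   `norm`, `proj`, `model` (trained), `untrained` (same init, untrained),
#'   `train_result`, `val_contigs` (normalized held-out split).
#' @export
desk_study <- function(n_contigs = 2000L, seed = 1L, quiet = FALSE) {
  corpus <- demo_corpus(n_contigs = n_contigs, seed = seed)
  norm <- fit_normalizer(corpus)
  contigs <- normalize_corpus(corpus, norm)
  proj <- fit_label_projector(contigs, k_pc = 16L)
  model0 <- init_model(desk_config(), seed = derive_seed(seed, 41))
  res <- train_glm(model0, contigs, proj, desk_train_config(seed = seed),
                   quiet = quiet)
  ids <- vapply(contigs, function(ct) ct$contig_id, character(1))
  list(corpus = corpus, contigs = contigs, norm = norm, proj = proj,
       model = res$model, untrained = model0, train_result = res,
       val_contigs = contigs[ids %in% res$val_ids])
}

#' Noise-free probe contigs for the context-variance analysis
#'
#' Builds `n_contexts` distinct 15-gene contigs, each with the probe family
#' at position 8 and fixed random flanks from the chain families; occurrence
#' sets replicate these context types up to `n_occurrences`. Because
#' embeddings are noise-free family centers and a context type is
#' bit-identical across its occurrences, a single-context family has exactly
#' zero variance, and variance grows with the number of distinct contexts.
#'
#' @param study a [desk_study()] result (normalizer and catalog are reused).
#' @param n_contexts number of distinct context types.
#' @param n_occurrences total occurrences to distribute over the types.
#' @param seed integer seed for the flank draws.
#' @return occurrences x hidden matrix of contextualized embeddings of the
#'   probe family, one row per occurrence.
#' @export
context_probe_embeddings <- function(study, n_contexts, n_occurrences = 108L,
                                     seed = 1L) {
  catalog <- study$corpus$catalog
  fam <- rownames(catalog$centers)
  probe <- fam[2]
  flank_pool <- setdiff(fam[1:20], probe)
  contigs <- with_seed(derive_seed(seed, 51), {
    lapply(seq_len(n_contexts), function(k) {
      flanks <- sample(flank_pool, 14L, replace = TRUE)
      fams <- c(flanks[1:7], probe, flanks[8:14])
      genes <- lapply(seq_along(fams), function(i) {
        gene_record(sprintf("p%d_%d", k, i), catalog$centers[fams[i], ], 0.5,
                    family_id = fams[i])
      })
      subcontig(sprintf("probe_ctx%d", k), genes)
    })
  })
  contigs <- lapply(contigs, function(ct) {
    ct$genes <- lapply(ct$genes, function(g) apply_normalizer(study$norm, g))
    ct
  })
  per_type <- vapply(contigs, function(ct) {
    contextual_embeddings(study$model, ct)[8, ]
  }, numeric(study$model$config$hidden))
  t(per_type)[rep_len(seq_len(n_contexts), n_occurrences), , drop = FALSE]
}
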