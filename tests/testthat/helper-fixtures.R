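# Small fixtures shared across test files; everything is generated in code.

tiny_config <- function(n_layers = 2L, hidden = 16L, n_heads = 2L,
                        n_pred = 3L, input_dim = 9L, label_dim = 5L, ...) {
  glm_config(n_layers, hidden, n_heads, n_pred = n_pred,
             input_dim = input_dim, label_dim = label_dim, ...)
}

# A small normalized corpus + projector + model sized for fast tests.
tiny_setup <- function(n_contigs = 12L, seed = 42L) {
  catalog <- build_family_catalog(8L, 8L, noise_scale = 0.1, seed = seed)
  corp <- sample_corpus(catalog, n_contigs = n_contigs, len_range = c(6L, 10L),
                        seed = seed + 1L)
  norm <- fit_normalizer(corp)
  contigs <- normalize_corpus(corp, norm)
  proj <- fit_label_projector(contigs, k_pc = 4L)
  model <- init_model(tiny_config(), seed = seed + 2L)
  list(catalog = catalog, corp = corp, norm = norm, contigs = contigs,
       proj = proj, model = model)
}

# Hand-built prediction_set for metric tests.
make_prediction_set <- function(predictions, logits, positions) {
  structure(list(predictions = predictions,
                 likelihood_logits = logits,
                 likelihoods = exp(logits - apply(logits, 1, max)) /
                   rowSums(exp(logits - apply(logits, 1, max))),
                 positions = positions),
            class = "prediction_set")
}

# Pooled counts of the family immediately following each occurrence of a
# trigger family.
successor_counts <- function(corp, trigger) {
  succ <- character(0)
  for (ct in corp$contigs) {
    fams <- contiglm:::contig_families(ct)
    idx <- which(fams == trigger)
    idx <- idx[idx < length(fams)]
    succ <- c(succ, fams[idx + 1L])
  }
  table(succ)
}
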