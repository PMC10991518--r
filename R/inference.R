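# Extraction of contextualized embeddings, masked-context embeddings,
# symmetrized attention maps, and pooled contig embeddings.

#' Contextualized per-gene embeddings of one contig
#'
#' Runs unmasked inference and returns the selected hidden layer's state for
#' every gene. Layer 0 is the affine-projected input (pre-encoder); the
#' default is the last encoder layer, taken as the final block output with
#' its closing layer norm applied.
#'
#' @param model a trained model.
#' @param contig a normalized [subcontig()].
#' @param layer layer index in 0..n_layers (default: last).
#' @return L x hidden matrix.
#' @export
contextual_embeddings <- function(model, contig, layer = NULL) {
  nl <- model$config$n_layers
  if (is.null(layer)) layer <- nl
  if (layer < 0 || layer > nl) stop_param("contextual_embeddings: layer out of range")
  batch <- as_batch(list(contig))
  out <- glm_forward(model, batch, need_hidden = TRUE)
  out$hidden[[layer + 1L]]
}

#' Context-only embeddings at masked positions
#'
#' Masks the requested positions (whole token set to -1) and returns the
#' hidden state at each, so the representation carries only information that
#' flows in from the context — the replaced gene's own embedding cannot
#' propagate.
#'
#' @param model a trained model.
#' @param contig a normalized [subcontig()].
#' @param positions integer positions to mask.
#' @param layer layer index (default last).
#' @return length(positions) x hidden matrix, rows in `positions` order.
#' @export
masked_context_embeddings <- function(model, contig, positions, layer = NULL) {
  L <- length(contig$genes)
  nl <- model$config$n_layers
  if (is.null(layer)) layer <- nl
  if (any(positions < 1L | positions > L)) {
    stop_param("masked_context_embeddings: positions out of range")
  }
  if (length(unique(positions)) == L) {
    warning("masked_context_embeddings: all positions masked; the result is context-free")
  }
  mask <- rep(FALSE, L)
  mask[positions] <- TRUE
  batch <- build_batch(list(contig), list(mask), proj = NULL)
  out <- glm_forward(model, batch, need_hidden = TRUE)
  out$hidden[[layer + 1L]][positions, , drop = FALSE]
}

#' Attention maps of one contig
#'
#' Runs unmasked inference and returns per-layer/head attention matrices.
#' Symmetrization takes the arithmetic mean of a matrix and its transpose,
#' preserving the total attention mass.
#'
#' @param model a trained model.
#' @param contig a normalized [subcontig()].
#' @param symmetrize return `(A + t(A)) / 2` per head.
#' @return nested list `maps[[layer]][[head]]`, each an L x L matrix.
#' @export
attention_maps <- function(model, contig, symmetrize = TRUE) {
  batch <- as_batch(list(contig))
  out <- glm_forward(model, batch, need_attn = TRUE)
  lapply(out$attns, function(layer) {
    heads <- layer[[1]]
    lapply(heads, function(A) if (symmetrize) (A + t(A)) / 2 else A)
  })
}

#' Mean-pooled contig embedding
#'
#' `contextualized`: mean over gene positions of the last hidden layer;
#' `context_free`: mean of the raw input embeddings (no orientation slot).
#' Padding never enters (single-contig inference has none).
#'
#' @param model a trained model (ignored in `context_free` mode).
#' @param contig a normalized [subcontig()].
#' @param mode pooling source.
#' @return numeric vector (`hidden` or E long).
#' @export
contig_embedding <- function(model, contig, mode = c("contextualized", "context_free")) {
  mode <- match.arg(mode)
  if (!length(contig$genes)) stop_param("contig_embedding: empty contig")
  if (mode == "context_free") {
    return(colMeans(contig_embedding_matrix(contig)))
  }
  colMeans(contextual_embeddings(model, contig))
}

#' Collect contextualized embeddings of family occurrences
#'
#' Batched unmasked inference over a corpus, grouping the selected layer's
#' hidden states by gene family. Occurrences at contig edges (first or last
#' position) are excluded by default, matching the variance analysis.
#'
#' @param model a trained model.
#' @param contigs normalized contigs.
#' @param families optional family subset.
#' @param layer hidden layer (default last).
#' @param exclude_edges drop first/last positions.
#' @param chunk contigs per forward pass.
#' @return named list family -> occurrences x hidden matrix.
#' @export
collect_family_embeddings <- function(model, contigs, families = NULL,
                                      layer = NULL, exclude_edges = TRUE,
                                      chunk = 32L) {
  nl <- model$config$n_layers
  if (is.null(layer)) layer <- nl
  acc <- list()
  for (start in seq(1L, length(contigs), by = chunk)) {
    take <- start:min(start + chunk - 1L, length(contigs))
    batch <- as_batch(contigs[take])
    out <- glm_forward(model, batch, need_hidden = TRUE)
    Hs <- out$hidden[[layer + 1L]]
    for (k in seq_along(take)) {
      ct <- contigs[[take[k]]]
      L <- length(ct$genes)
      keep <- if (exclude_edges) seq_len(L)[-c(1L, L)] else seq_len(L)
      fams <- contig_families(ct)
      for (i in keep) {
        f <- fams[i]
        if (is.na(f)) next
        if (!is.null(families) && !(f %in% families)) next
        acc[[f]] <- c(acc[[f]], list(Hs[out$ranges[[k]][i], ]))
      }
    }
  }
  lapply(acc, function(rows) do.call(rbind, rows))
}

#' Adjacent-pair attention features for operon analysis
#'
#' For every adjacent gene pair (i, i+1) of every labeled contig, collects the
#' symmetrized attention value at entry (i, i+1) from each layer/head, giving
#' a pair x (n_layers * n_heads) feature matrix with the operon label.
#'
#' @param model a trained model.
#' @param contigs normalized contigs whose `operon_pairs` are set.
#' @param chunk contigs per forward pass.
#' @return list: `features` (matrix, columns named `L<layer>H<head>`),
#'   `labels` (logical), `pair_index` (contig_id, i).
#' @export
pair_attention_features <- function(model, contigs, chunk = 16L) {
  contigs <- Filter(function(ct) !is.null(ct$operon_pairs), contigs)
  if (!length(contigs)) stop_param("pair_attention_features: no labeled contigs")
  nl <- model$config$n_layers
  nh <- model$config$n_heads
  feats <- list()
  labels <- logical(0)
  pair_index <- list()
  for (start in seq(1L, length(contigs), by = chunk)) {
    take <- start:min(start + chunk - 1L, length(contigs))
    batch <- as_batch(contigs[take])
    out <- glm_forward(model, batch, need_attn = TRUE)
    for (k in seq_along(take)) {
      ct <- contigs[[take[k]]]
      L <- length(ct$genes)
      n_pairs <- L - 1L
      Fm <- matrix(0, n_pairs, nl * nh)
      col <- 0L
      for (l in seq_len(nl)) {
        for (h in seq_len(nh)) {
          col <- col + 1L
          A <- out$attns[[l]][[k]][[h]]
          S <- (A + t(A)) / 2
          Fm[, col] <- S[cbind(seq_len(n_pairs), seq_len(n_pairs) + 1L)]
        }
      }
      feats[[length(feats) + 1L]] <- Fm
      labels <- c(labels, ct$operon_pairs)
      pair_index[[length(pair_index) + 1L]] <-
        data.frame(contig_id = ct$contig_id, i = seq_len(n_pairs))
    }
  }
  features <- do.call(rbind, feats)
  colnames(features) <- as.vector(t(outer(seq_len(nl), seq_len(nh),
                                          function(l, h) sprintf("L%dH%d", l, h))))
  list(features = features, labels = labels,
       pair_index = do.call(rbind, pair_index))
}
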