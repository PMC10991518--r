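# Corpus normalization, label construction, masking and batch assembly.

#' Fit a per-feature embedding normalizer
#'
#' Stores the per-feature mean and sample standard deviation over the fitting
#' genes; zero-variance features get their s.d. replaced by 1 so they
#' normalize to exactly 0. Applying the normalizer z-scores each feature and
#' clips the result to `[-clip_bound, clip_bound]`.
#'
#' @param genes list of [gene_record()] (or a `synthetic_corpus` / list of
#'   [subcontig()], which is flattened).
#' @param clip_bound positive clipping bound (default 10).
#' @return an object of class `embedding_normalizer`.
#' @export
fit_normalizer <- function(genes, clip_bound = 10) {
  genes <- flatten_genes(genes)
  if (length(genes) < 2L) stop_param("fit_normalizer: need >= 2 genes")
  X <- do.call(rbind, lapply(genes, function(g) g$embedding))
  if (clip_bound <= 0) stop_param("fit_normalizer: clip_bound must be > 0")
  means <- colMeans(X)
  stds <- apply(X, 2, stats::sd)
  stds[!is.finite(stds) | stds == 0] <- 1
  structure(list(feature_means = means, feature_stds = stds,
                 clip_bound = clip_bound),
            class = "embedding_normalizer")
}

# Accept a gene list, a contig list, or a synthetic_corpus.
flatten_genes <- function(x) {
  if (inherits(x, "synthetic_corpus")) x <- x$contigs
  if (inherits(x, "gene_record")) return(list(x))
  if (length(x) && inherits(x[[1]], "subcontig")) {
    return(unlist(lapply(x, function(ct) ct$genes), recursive = FALSE))
  }
  x
}

#' Apply a fitted normalizer to one gene
#'
#' @param norm an [fit_normalizer()] result.
#' @param gene a [gene_record()].
#' @return the gene with its embedding z-scored and clipped. Note the
#'   transform is not idempotent: reapplying rescales again.
#' @export
apply_normalizer <- function(norm, gene) {
  e <- gene$embedding
  if (length(e) != length(norm$feature_means)) {
    stop_param("apply_normalizer: embedding length mismatch")
  }
  z <- (e - norm$feature_means) / norm$feature_stds
  z <- pmin(pmax(z, -norm$clip_bound), norm$clip_bound)
  gene$embedding <- z
  gene
}

#' Normalize every gene in a corpus
#'
#' @param contigs list of [subcontig()] or a `synthetic_corpus`.
#' @param norm an [fit_normalizer()] result.
#' @return the contig list with normalized embeddings.
#' @export
normalize_corpus <- function(contigs, norm) {
  if (inherits(contigs, "synthetic_corpus")) contigs <- contigs$contigs
  lapply(contigs, function(ct) {
    ct$genes <- lapply(ct$genes, function(g) apply_normalizer(norm, g))
    ct
  })
}

#' Fit the PCA-whitening label projector
#'
#' Fits a PCA on the (already normalized) embeddings and retains `k_pc`
#' components whose scores are divided by their standard deviation, so on the
#' fitting corpus each retained component has exactly unit variance. A gene's
#' training label is the `k_pc` whitened scores concatenated with its
#' orientation flag, giving `label_dim = k_pc + 1` features. Component signs
#' are fixed by forcing the largest-magnitude loading of each component to be
#' positive, so refits on the same data are reproducible.
#'
#' @param genes normalized genes (any container accepted by [fit_normalizer()]).
#' @param k_pc number of principal components; must be < embedding dimension
#'   and < number of genes.
#' @return an object of class `label_projector` with fields `pca_mean`,
#'   `components` (`k_pc` x E, orthonormal rows), `whitening_scales`,
#'   `label_dim`, and `explained_variance` (fraction in \[0,1\]).
#' @export
fit_label_projector <- function(genes, k_pc) {
  genes <- flatten_genes(genes)
  X <- do.call(rbind, lapply(genes, function(g) g$embedding))
  E <- ncol(X)
  if (k_pc >= E) stop_param("fit_label_projector: k_pc must be < embedding dimension")
  if (k_pc >= nrow(X)) stop_param("fit_label_projector: k_pc must be < corpus size")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k_pc)
  rot <- pc$rotation  # E x k_pc
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  sdev <- pc$sdev
  dimnames(rot) <- NULL
  structure(list(pca_mean = unname(pc$center),
                 components = t(rot),
                 whitening_scales = unname(sdev[seq_len(k_pc)]),
                 label_dim = k_pc + 1L,
                 explained_variance = sum(sdev[seq_len(k_pc)]^2) / sum(sdev^2)),
            class = "label_projector")
}

#' Build the training label of a gene
#'
#' @param proj a fitted [fit_label_projector()].
#' @param gene a normalized [gene_record()].
#' @return numeric vector of length `proj$label_dim`: whitened PC scores
#'   followed by the orientation flag.
#' @export
make_label <- function(proj, gene) {
  if (!inherits(proj, "label_projector")) stop_param("make_label: projector not fitted")
  scores <- drop(proj$components %*% (gene$embedding - proj$pca_mean)) /
    proj$whitening_scales
  unname(c(scores, gene$orientation))
}

# L x label_dim matrix of labels for one contig.
label_matrix <- function(proj, contig) {
  t(vapply(contig$genes, function(g) make_label(proj, g),
           numeric(proj$label_dim)))
}

#' Assemble a masked training batch
#'
#' Each gene is masked independently with probability `rate`; a contig whose
#' Bernoulli draw selects no gene is redrawn until at least one gene is
#' masked, so every training example contributes loss (the induced upward
#' rate bias is measurable but small at the lengths used here). Masked token
#' vectors are set to `mask_value` (-1) in every slot, embedding and
#' orientation alike. Labels are recorded from the unmasked records.
#'
#' @param contigs list of normalized [subcontig()].
#' @param rate masking probability in (0, 1).
#' @param proj a fitted [fit_label_projector()], or NULL to skip label
#'   construction (masking-only batches).
#' @param seed integer seed.
#' @return an object of class `masked_batch`: `tokens` (B x L_max x (E+1)),
#'   `attention_mask` (B x L_max logical; FALSE marks padding), `masked_positions`
#'   (n x 2 matrix of batch row and position), `labels` (n x label_dim),
#'   `all_labels` (per-contig L x label_dim matrices used by evaluation),
#'   `lengths`, and `mask_value`.
#' @export
mask_batch <- function(contigs, rate, proj = NULL, seed = NULL) {
  if (rate <= 0 || rate >= 1) stop_param("mask_batch: rate must be in (0,1)")
  masks <- with_seed(seed, lapply(contigs, function(ct) {
    L <- length(ct$genes)
    repeat {
      m <- stats::runif(L) < rate
      if (any(m)) return(m)
    }
  }))
  build_batch(contigs, masks, proj)
}

#' Assemble a batch with masks at chosen positions
#'
#' @param contigs list of normalized [subcontig()].
#' @param positions list (one element per contig) of integer positions to mask.
#' @param proj optional projector for label matrices.
#' @export
mask_positions_batch <- function(contigs, positions, proj = NULL) {
  masks <- Map(function(ct, p) {
    m <- rep(FALSE, length(ct$genes))
    m[p] <- TRUE
    m
  }, contigs, positions)
  build_batch(contigs, masks, proj)
}

#' Assemble an unmasked inference batch
#'
#' @param contigs list of normalized [subcontig()].
#' @param proj optional projector; when given, per-contig label matrices are
#'   attached (needed by the accuracy metrics).
#' @export
as_batch <- function(contigs, proj = NULL) {
  masks <- lapply(contigs, function(ct) rep(FALSE, length(ct$genes)))
  build_batch(contigs, masks, proj)
}

# Shared batch builder; masks is a list of logical vectors.
build_batch <- function(contigs, masks, proj, mask_value = -1) {
  B <- length(contigs)
  lens <- vapply(contigs, function(ct) length(ct$genes), integer(1))
  L_max <- max(lens)
  E1 <- length(contigs[[1]]$genes[[1]]$embedding) + 1L
  tokens <- array(0, dim = c(B, L_max, E1))
  attention_mask <- matrix(FALSE, B, L_max)
  mp <- list()
  labels <- list()
  all_labels <- if (is.null(proj)) NULL else vector("list", B)
  for (b in seq_len(B)) {
    ct <- contigs[[b]]
    L <- lens[b]
    attention_mask[b, seq_len(L)] <- TRUE
    lab <- if (is.null(proj)) NULL else label_matrix(proj, ct)
    if (!is.null(all_labels)) all_labels[[b]] <- lab
    for (i in seq_len(L)) {
      if (masks[[b]][i]) {
        tokens[b, i, ] <- mask_value
        mp[[length(mp) + 1L]] <- c(b, i)
        if (!is.null(lab)) labels[[length(labels) + 1L]] <- lab[i, ]
      } else {
        g <- ct$genes[[i]]
        tokens[b, i, ] <- c(g$embedding, g$orientation)
      }
    }
  }
  masked_positions <- if (length(mp)) do.call(rbind, mp) else
    matrix(integer(0), 0, 2)
  labels <- if (length(labels)) do.call(rbind, labels) else NULL
  structure(list(tokens = tokens, attention_mask = attention_mask,
                 masked_positions = masked_positions, labels = labels,
                 all_labels = all_labels, lengths = lens,
                 contig_ids = vapply(contigs, function(ct) ct$contig_id, character(1)),
                 mask_value = mask_value),
            class = "masked_batch")
}

# ---- on-disk corpus format --------------------------------------------------

#' Write a corpus to disk
#'
#' The on-disk layout is a directory holding `index.jsonl` (one JSON object
#' per contig: contig_id, gene_ids, orientations, optional family ids, operon
#' pair labels and contig class) plus a binary array container
#' `embeddings.bin` (64-bit doubles, row-major per gene in index order) with
#' a JSON sidecar `embeddings.json` recording gene order and dimension.
#'
#' @param contigs list of [subcontig()] or a `synthetic_corpus`.
#' @param path directory to create/overwrite.
#' @export
write_corpus <- function(contigs, path) {
  if (inherits(contigs, "synthetic_corpus")) contigs <- contigs$contigs
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(path, "index.jsonl"), "w")
  on.exit(close(con))
  gene_ids <- character(0)
  embs <- list()
  for (ct in contigs) {
    rec <- list(
      contig_id = ct$contig_id,
      gene_ids = vapply(ct$genes, function(g) g$gene_id, character(1)),
      orientations = contig_orientations(ct)
    )
    fams <- contig_families(ct)
    if (!all(is.na(fams))) rec$family_ids <- fams
    if (!is.null(ct$operon_pairs)) rec$operon_pairs <- ct$operon_pairs
    if (!is.null(ct$contig_class)) rec$contig_class <- ct$contig_class
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    gene_ids <- c(gene_ids, rec$gene_ids)
    embs[[length(embs) + 1L]] <- contig_embedding_matrix(ct)
  }
  X <- do.call(rbind, embs)
  bin <- file(file.path(path, "embeddings.bin"), "wb")
  writeBin(as.vector(t(X)), bin, size = 8)
  close(bin)
  jsonlite::write_json(list(gene_ids = gene_ids, dim = ncol(X)),
                       file.path(path, "embeddings.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a corpus from disk
#'
#' Round-trips [write_corpus()] output exactly (ids, orientations, labels;
#' embeddings to stored 64-bit precision). A malformed index line raises a
#' parse error naming the line; a truncated binary container raises an I/O
#' error rather than a partial load.
#'
#' @param path corpus directory.
#' @return list of [subcontig()].
#' @export
read_corpus <- function(path) {
  idx_file <- file.path(path, "index.jsonl")
  if (!file.exists(idx_file)) stop_param("read_corpus: missing ", idx_file)
  lines <- readLines(idx_file)
  if (!length(lines)) {
    warning("read_corpus: empty corpus index")
    return(list())
  }
  side <- jsonlite::read_json(file.path(path, "embeddings.json"),
                              simplifyVector = TRUE)
  n_genes <- length(side$gene_ids)
  dim <- side$dim
  bin_path <- file.path(path, "embeddings.bin")
  expected <- 8 * n_genes * dim
  if (!file.exists(bin_path) || file.info(bin_path)$size != expected) {
    stop("read_corpus: embeddings.bin missing or truncated (expected ",
         expected, " bytes)", call. = FALSE)
  }
  bin <- file(bin_path, "rb")
  X <- matrix(readBin(bin, "double", n = n_genes * dim, size = 8),
              n_genes, dim, byrow = TRUE)
  close(bin)
  rownames(X) <- side$gene_ids
  contigs <- vector("list", length(lines))
  for (li in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[li], simplifyVector = TRUE),
                    error = function(e) stop("read_corpus: malformed index line ",
                                             li, ": ", conditionMessage(e),
                                             call. = FALSE))
    genes <- lapply(seq_along(rec$gene_ids), function(i) {
      gene_record(rec$gene_ids[i], X[rec$gene_ids[i], ],
                  orientation = rec$orientations[i],
                  family_id = if (!is.null(rec$family_ids)) rec$family_ids[i])
    })
    contigs[[li]] <- subcontig(rec$contig_id, genes,
                               operon_pairs = rec$operon_pairs,
                               contig_class = rec$contig_class)
  }
  contigs
}

#' Read a small corpus from a flat TSV fixture
#'
#' One gene per row with columns `contig_id`, `gene_id`, `orientation`,
#' optional `family_id`, `contig_class`, and embedding columns `e1..eE`.
#' Rows are grouped by `contig_id` in order of first appearance.
#'
#' @param path TSV file.
#' @export
read_corpus_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  emb_cols <- grep("^e[0-9]+$", names(df), value = TRUE)
  if (!length(emb_cols)) stop_param("read_corpus_tsv: no embedding columns e1..eE")
  lapply(split(df, factor(df$contig_id, levels = unique(df$contig_id))),
         function(sub) {
           genes <- lapply(seq_len(nrow(sub)), function(i) {
             gene_record(sub$gene_id[i],
                         as.numeric(sub[i, emb_cols]),
                         orientation = sub$orientation[i],
                         family_id = if ("family_id" %in% names(sub)) sub$family_id[i],
                         class_label = if ("class_label" %in% names(sub)) sub$class_label[i])
           })
           subcontig(sub$contig_id[1], genes,
                     contig_class = if ("contig_class" %in% names(sub)) sub$contig_class[1])
         }) |> unname()
}

#' Write / read operon pair labels as a two-column TSV
#'
#' The export lists each adjacent gene pair marked operonic, one pair per row
#' (`gene_id_a`, `gene_id_b`), matching a regulon-database-style adjacency
#' table. [read_operon_pairs()] applies such a table to a corpus, setting
#' `operon_pairs` on every contig (pairs absent from the table are FALSE).
#'
#' @param contigs list of [subcontig()] with `operon_pairs` set.
#' @param path TSV file.
#' @export
write_operon_pairs <- function(contigs, path) {
  rows <- list()
  for (ct in contigs) {
    if (is.null(ct$operon_pairs)) next
    ids <- vapply(ct$genes, function(g) g$gene_id, character(1))
    w <- which(ct$operon_pairs)
    for (i in w) rows[[length(rows) + 1L]] <- c(ids[i], ids[i + 1L])
  }
  df <- as.data.frame(do.call(rbind, rows) %||% matrix(character(0), 0, 2))
  names(df) <- c("gene_id_a", "gene_id_b")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_operon_pairs
#' @export
read_operon_pairs <- function(contigs, path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  key <- paste(df$gene_id_a, df$gene_id_b)
  lapply(contigs, function(ct) {
    ids <- vapply(ct$genes, function(g) g$gene_id, character(1))
    ct$operon_pairs <- paste(ids[-length(ids)], ids[-1]) %in% key
    ct
  })
}
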