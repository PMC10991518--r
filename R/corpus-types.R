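#' One gene in a contig
#'
#' A gene token: a fixed-length protein embedding plus an orientation flag
#' (+0.5 forward, -0.5 reverse), with optional family / annotation / class
#' metadata carried through to downstream analyses.
#'
#' @param gene_id character identifier, unique within a corpus.
#' @param embedding numeric vector (finite).
#' @param orientation +0.5 or -0.5.
#' @param family_id optional family identifier.
#' @param annotation optional free-text annotation.
#' @param class_label optional per-gene class label (e.g. an enzyme class).
#' @return an object of class `gene_record`.
#' @export
gene_record <- function(gene_id, embedding, orientation,
                        family_id = NULL, annotation = NULL, class_label = NULL) {
  embedding <- as.numeric(embedding)
  if (!all(is.finite(embedding))) stop_param("gene_record: embedding must be finite")
  if (!orientation %in% c(0.5, -0.5)) {
    stop_param("gene_record: orientation must be +0.5 or -0.5")
  }
  structure(
    list(gene_id = as.character(gene_id), embedding = embedding,
         orientation = orientation, family_id = family_id,
         annotation = annotation, class_label = class_label),
    class = "gene_record"
  )
}

#' An ordered window of genes
#'
#' The model's input unit: an ordered list of [gene_record()]s with optional
#' adjacent-pair operon labels (length L-1) and an optional contig class.
#'
#' @param contig_id character identifier.
#' @param genes list of `gene_record`.
#' @param operon_pairs optional logical vector of length `length(genes) - 1`;
#'   `TRUE` means genes i and i+1 belong to the same operon.
#' @param contig_class optional class label (e.g. taxonomy).
#' @return an object of class `subcontig`.
#' @export
subcontig <- function(contig_id, genes, operon_pairs = NULL, contig_class = NULL) {
  if (length(genes) < 2L) stop_param("subcontig: need at least 2 genes")
  if (!all(vapply(genes, inherits, logical(1), "gene_record"))) {
    stop_param("subcontig: genes must be gene_record objects")
  }
  if (!is.null(operon_pairs) && length(operon_pairs) != length(genes) - 1L) {
    stop_param("subcontig: operon_pairs must have length L - 1")
  }
  structure(
    list(contig_id = as.character(contig_id), genes = genes,
         operon_pairs = operon_pairs, contig_class = contig_class),
    class = "subcontig"
  )
}

#' @export
length.subcontig <- function(x) length(x$genes)

#' @export
print.subcontig <- function(x, ...) {
  cat(sprintf("<subcontig %s: %d genes%s>\n", x$contig_id, length(x$genes),
              if (is.null(x$contig_class)) "" else paste0(", class ", x$contig_class)))
  invisible(x)
}

# L x E matrix of raw embeddings for one contig.
contig_embedding_matrix <- function(contig) {
  do.call(rbind, lapply(contig$genes, function(g) g$embedding))
}

#' Per-gene orientation / family accessors
#'
#' @param contig a [subcontig()].
#' @return vector over genes in contig order.
#' @export
contig_orientations <- function(contig) {
  vapply(contig$genes, function(g) g$orientation, numeric(1))
}

#' @rdname contig_orientations
#' @export
contig_families <- function(contig) {
  vapply(contig$genes, function(g) g$family_id %||% NA_character_, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
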