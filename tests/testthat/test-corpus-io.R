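test_that("normalizer stores per-feature statistics and clips", {
  g1 <- gene_record("a", c(0, 0), 0.5)
  g2 <- gene_record("b", c(2, 2), -0.5)
  norm <- fit_normalizer(list(g1, g2), clip_bound = 10)
  expect_equal(norm$feature_means, c(1, 1))
  expect_equal(norm$feature_stds, c(sqrt(2), sqrt(2)))  # sample s.d.
  refit <- fit_normalizer(list(g1, g2), clip_bound = 10)
  expect_identical(norm, refit)

  # constant feature: s.d. substituted by 1, normalized value 0
  h1 <- gene_record("c", c(5, 1), 0.5)
  h2 <- gene_record("d", c(5, 3), 0.5)
  nc <- fit_normalizer(list(h1, h2))
  expect_equal(nc$feature_stds[1], 1)
  expect_equal(apply_normalizer(nc, h1)$embedding[1], 0)

  # extreme outlier clipped to the bound exactly
  o <- gene_record("e", c(1e6, 2), 0.5)
  expect_equal(apply_normalizer(nc, o)$embedding[1], 10)
})

test_that("normalization maps mean to zero and k-sigma to min(k, clip)", {
  set.seed(1)
  genes <- lapply(1:50, function(i) gene_record(i, rnorm(4, sd = 2), 0.5))
  norm <- fit_normalizer(genes)
  at_mean <- gene_record("m", norm$feature_means, 0.5)
  expect_equal(apply_normalizer(norm, at_mean)$embedding, rep(0, 4))
  at3 <- gene_record("s3", norm$feature_means + 3 * norm$feature_stds, 0.5)
  expect_equal(apply_normalizer(norm, at3)$embedding, rep(3, 4))
  at20 <- gene_record("s20", norm$feature_means + 20 * norm$feature_stds, 0.5)
  expect_equal(apply_normalizer(norm, at20)$embedding, rep(10, 4))
  expect_error(apply_normalizer(norm, gene_record("bad", 1:3, 0.5)), "mismatch")
})

test_that("label projector whitens scores and fixes component signs", {
  set.seed(2)
  genes <- lapply(1:500, function(i) gene_record(i, rnorm(8), 0.5))
  proj <- fit_label_projector(genes, k_pc = 3L)
  expect_equal(proj$label_dim, 4L)
  scores <- t(vapply(genes, function(g) make_label(proj, g)[1:3], numeric(3)))
  expect_equal(unname(apply(scores, 2, var)), rep(1, 3), tolerance = 1e-6)
  expect_lt(max(abs(cor(scores)[upper.tri(diag(3))])), 0.05)
  # orthonormal rows
  expect_equal(proj$components %*% t(proj$components), diag(3), tolerance = 1e-8)
  # deterministic refit including signs
  expect_identical(proj, fit_label_projector(genes, k_pc = 3L))

  # rank-1 data: one component explains everything
  line <- lapply(1:40, function(i) gene_record(i, i * c(1, 2, -1), 0.5))
  p1 <- fit_label_projector(line, k_pc = 1L)
  expect_equal(p1$explained_variance, 1, tolerance = 1e-10)

  expect_error(fit_label_projector(genes, k_pc = 8L), "embedding dimension")
  expect_error(fit_label_projector(genes[1:3], k_pc = 4L), "corpus size")
})

test_that("labels are whitened scores plus the orientation flag", {
  set.seed(3)
  genes <- lapply(1:60, function(i) gene_record(i, rnorm(6), 0.5))
  proj <- fit_label_projector(genes, k_pc = 2L)
  at_mean_f <- gene_record("f", proj$pca_mean, 0.5)
  expect_equal(make_label(proj, at_mean_f), c(0, 0, 0.5))
  at_mean_r <- gene_record("r", proj$pca_mean, -0.5)
  lf <- make_label(proj, at_mean_f)
  lr <- make_label(proj, at_mean_r)
  expect_equal(lf[1:2], lr[1:2])
  expect_equal(c(lf[3], lr[3]), c(0.5, -0.5))
  # the last label coordinate always equals the gene's orientation
  for (g in genes[1:10]) {
    expect_identical(make_label(proj, g)[3], g$orientation)
  }
})

test_that("full-scale label construction yields 100 features from 99 PCs", {
  set.seed(4)
  genes <- lapply(1:160, function(i) gene_record(i, rnorm(128), 0.5))
  proj <- fit_label_projector(genes, k_pc = 99L)
  expect_equal(proj$label_dim, 100L)
  expect_length(make_label(proj, genes[[1]]), 100L)
})

test_that("masking floors at one gene per contig and writes -1 tokens", {
  ts <- tiny_setup()
  batch <- mask_batch(ts$contigs, 0.05, ts$proj, seed = 7L)
  per_contig <- table(factor(batch$masked_positions[, 1],
                             levels = seq_along(ts$contigs)))
  expect_true(all(per_contig >= 1L))
  for (r in seq_len(nrow(batch$masked_positions))) {
    mp <- batch$masked_positions[r, ]
    expect_true(all(batch$tokens[mp[1], mp[2], ] == -1))
  }
  # labels come from the unmasked records
  mp1 <- batch$masked_positions[1, ]
  expect_equal(batch$labels[1, ],
               make_label(ts$proj, ts$contigs[[mp1[1]]]$genes[[mp1[2]]]))
  expect_error(mask_batch(ts$contigs, 0, ts$proj), "rate")
  expect_error(mask_batch(ts$contigs, 1, ts$proj), "rate")
})

test_that("corpus round-trips through the on-disk format", {
  ts <- tiny_setup(n_contigs = 3L)
  dir <- file.path(tempdir(), "corpus_rt")
  write_corpus(ts$corp$contigs, dir)
  back <- read_corpus(dir)
  expect_length(back, 3L)
  for (i in 1:3) {
    a <- ts$corp$contigs[[i]]
    b <- back[[i]]
    expect_identical(b$contig_id, a$contig_id)
    expect_identical(contig_families(b), contig_families(a))
    expect_identical(contig_orientations(b), contig_orientations(a))
    expect_identical(b$operon_pairs, a$operon_pairs)
    expect_equal(contiglm:::contig_embedding_matrix(b),
                 contiglm:::contig_embedding_matrix(a),
                 ignore_attr = TRUE)
  }

  # truncated binary container fails loudly, no partial load
  bin <- file.path(dir, "embeddings.bin")
  full <- readBin(bin, "raw", file.info(bin)$size)
  writeBin(full[1:(length(full) - 16)], bin)
  expect_error(read_corpus(dir), "truncated")

  # empty corpus: empty list with a warning
  dir2 <- file.path(tempdir(), "corpus_empty")
  dir.create(dir2, showWarnings = FALSE)
  writeLines(character(0), file.path(dir2, "index.jsonl"))
  jsonlite::write_json(list(gene_ids = character(0), dim = 4),
                       file.path(dir2, "embeddings.json"), auto_unbox = TRUE)
  writeBin(numeric(0), file.path(dir2, "embeddings.bin"))
  expect_warning(out <- read_corpus(dir2), "empty")
  expect_length(out, 0L)
})

test_that("malformed index lines are reported with their line number", {
  ts <- tiny_setup(n_contigs = 2L)
  dir <- file.path(tempdir(), "corpus_bad")
  write_corpus(ts$corp$contigs, dir)
  lines <- readLines(file.path(dir, "index.jsonl"))
  lines[2] <- substr(lines[2], 1, 10)
  writeLines(lines, file.path(dir, "index.jsonl"))
  expect_error(read_corpus(dir), "line 2")
})

test_that("flat TSV fixtures and operon pair tables round-trip", {
  ts <- tiny_setup(n_contigs = 4L)
  tsv <- file.path(tempdir(), "fix.tsv")
  rows <- do.call(rbind, lapply(ts$corp$contigs, function(ct) {
    emb <- contiglm:::contig_embedding_matrix(ct)
    colnames(emb) <- paste0("e", seq_len(ncol(emb)))
    data.frame(contig_id = ct$contig_id,
               gene_id = vapply(ct$genes, function(g) g$gene_id, character(1)),
               orientation = contig_orientations(ct),
               family_id = contig_families(ct), emb)
  }))
  write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_corpus_tsv(tsv)
  expect_length(back, 4L)
  expect_identical(contig_families(back[[2]]), contig_families(ts$corp$contigs[[2]]))

  pairs_tsv <- file.path(tempdir(), "operons.tsv")
  write_operon_pairs(ts$corp$contigs, pairs_tsv)
  relabeled <- read_operon_pairs(back, pairs_tsv)
  for (i in 1:4) {
    expect_identical(relabeled[[i]]$operon_pairs, ts$corp$contigs[[i]]$operon_pairs)
  }
})
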