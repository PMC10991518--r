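# Linear probing of embeddings and paralog matching.

softmax_ce_probe <- function(X1, W, Yh) {
  logits <- X1 %*% W
  P <- softmax_rows(logits)
  list(P = P, loss = -mean(log(pmax(P[Yh], 1e-12))))
}

#' Linear probe of labeled embeddings
#'
#' A single affine layer with softmax output, trained by Adam on
#' cross-entropy with early stopping: a fraction of the training set is held
#' out and training halts when its loss has not improved for `patience`
#' consecutive epochs. With `n_replicates > 1` the probe is refit under
#' different seeds and means plus or minus s.d. are reported.
#'
#' @param train_x,train_y training embeddings and class labels.
#' @param test_x,test_y test embeddings and class labels.
#' @param patience early-stopping patience in epochs (default 10).
#' @param batch_size minibatch size (default: full batch).
#' @param lr Adam learning rate.
#' @param max_epochs training cap.
#' @param val_fraction fraction of training data monitored for stopping.
#' @param n_replicates probe refits for error bars.
#' @param seed integer seed.
#' @return list: `accuracy`, `accuracy_sd`, `mean_ap` (micro-averaged over
#'   one-vs-rest scores), `per_class_f1` (class x replicate matrix),
#'   `epochs_run`.
#' @export
linear_probe <- function(train_x, train_y, test_x, test_y,
                         patience = 10L, batch_size = NULL, lr = 0.05,
                         max_epochs = 500L, val_fraction = 0.2,
                         n_replicates = 1L, seed = 1L) {
  train_y <- as.factor(train_y)
  if (nlevels(train_y) < 2L) stop_param("linear_probe: need >= 2 classes")
  test_y <- factor(test_y, levels = levels(train_y))
  if (any(is.na(test_y))) stop_param("linear_probe: test class absent from training")
  C <- nlevels(train_y)
  d <- ncol(train_x)
  accs <- numeric(n_replicates)
  aps <- numeric(n_replicates)
  f1s <- matrix(NA_real_, C, n_replicates, dimnames = list(levels(train_y), NULL))
  epochs_run <- integer(n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    rs <- derive_seed(seed, rep_i)
    n <- nrow(train_x)
    n_val <- max(1L, floor(val_fraction * n))
    sp <- with_seed(rs, sample.int(n))
    vi <- sp[seq_len(n_val)]
    ti <- sp[-seq_len(n_val)]
    X1 <- cbind(1, train_x[ti, , drop = FALSE])
    Xv <- cbind(1, train_x[vi, , drop = FALSE])
    Yti <- as.integer(train_y[ti])
    Yvi <- as.integer(train_y[vi])
    Yh <- cbind(seq_along(ti), Yti)
    Yhv <- cbind(seq_along(vi), Yvi)
    Yind <- matrix(0, length(ti), C)
    Yind[Yh] <- 1
    W <- matrix(0, d + 1L, C)
    m <- v <- W * 0
    best_val <- Inf
    best_W <- W
    wait <- 0L
    t <- 0L
    bs <- if (is.null(batch_size)) length(ti) else min(batch_size, length(ti))
    n_batches <- ceiling(length(ti) / bs)
    ep <- 0L
    with_seed(derive_seed(rs, 7), {
      for (ep in seq_len(max_epochs)) {
        ord <- if (n_batches > 1L) sample.int(length(ti)) else seq_along(ti)
        for (bi in seq_len(n_batches)) {
          rows <- ord[((bi - 1L) * bs + 1L):min(bi * bs, length(ti))]
          logits <- X1[rows, , drop = FALSE] %*% W
          P <- softmax_rows(logits)
          G <- crossprod(X1[rows, , drop = FALSE],
                         (P - Yind[rows, , drop = FALSE])) / length(rows)
          t <- t + 1L
          m <- 0.9 * m + 0.1 * G
          v <- 0.999 * v + 0.001 * G * G
          W <- W - lr * (m / (1 - 0.9^t)) / (sqrt(v / (1 - 0.999^t)) + 1e-8)
        }
        val <- softmax_ce_probe(Xv, W, Yhv)$loss
        if (val < best_val - 1e-6) {
          best_val <- val
          best_W <- W
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      }
    })
    epochs_run[rep_i] <- ep
    Pt <- softmax_rows(cbind(1, test_x) %*% best_W)
    pred <- max.col(Pt, ties.method = "first")
    truth <- as.integer(test_y)
    accs[rep_i] <- mean(pred == truth)
    onehot <- matrix(0, length(truth), C)
    onehot[cbind(seq_along(truth), truth)] <- 1
    aps[rep_i] <- average_precision(as.vector(Pt), as.vector(onehot) > 0)
    for (c in seq_len(C)) {
      tp <- sum(pred == c & truth == c)
      fp <- sum(pred == c & truth != c)
      fn <- sum(pred != c & truth == c)
      f1s[c, rep_i] <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    }
  }
  list(accuracy = mean(accs), accuracy_sd = stats::sd(accs),
       mean_ap = mean(aps), per_class_f1 = f1s, epochs_run = epochs_run)
}

#' Compare per-class F1 between two probe runs
#'
#' Two-sided t-tests on per-class F1 across replicates with
#' Benjamini-Hochberg correction across classes.
#'
#' @param f1_a,f1_b class x replicate F1 matrices from [linear_probe()].
#' @return data.frame: class, mean_a, mean_b, t_statistic, p_value, p_adjusted.
#' @export
compare_probe_f1 <- function(f1_a, f1_b) {
  stopifnot(nrow(f1_a) == nrow(f1_b))
  cls <- rownames(f1_a) %||% as.character(seq_len(nrow(f1_a)))
  res <- lapply(seq_len(nrow(f1_a)), function(c) {
    a <- f1_a[c, ]
    b <- f1_b[c, ]
    tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
    data.frame(class = cls[c], mean_a = mean(a), mean_b = mean(b),
               t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

# ---- paralog matching -------------------------------------------------------

#' Match an interacting partner from genomic context alone
#'
#' Builds a three-token test contig (mask, query, mask) with the query gene in
#' forward orientation, runs inference, takes the highest-likelihood
#' prediction at each masked flank, and retrieves the nearest candidate by L2
#' distance in label space. The prediction is exactly correct when either
#' flank's nearest candidate is the true partner, and cluster-correct when it
#' shares the partner's sequence cluster.
#'
#' @param model a trained model.
#' @param query a normalized [gene_record()] (orientation is forced forward).
#' @param candidate_labels candidate x label_dim matrix with rownames =
#'   candidate ids.
#' @param true_partner candidate id of the interacting partner.
#' @param clusters optional named vector candidate id -> cluster id.
#' @return object of class `paralog_query_result`.
#' @export
paralog_match <- function(model, query, candidate_labels, true_partner,
                          clusters = NULL) {
  if (!nrow(candidate_labels)) stop_param("paralog_match: empty candidate list")
  E <- length(query$embedding)
  query$orientation <- 0.5
  dummy <- function(id) gene_record(id, numeric(E), 0.5)
  ct <- subcontig("paralog_query",
                  list(dummy("flank_l"), query, dummy("flank_r")))
  batch <- build_batch(list(ct), list(c(TRUE, FALSE, TRUE)), proj = NULL)
  out <- glm_forward(model, batch)
  preds <- out$predictions
  sel <- max.col(preds$likelihoods, ties.method = "first")
  flank <- lapply(1:2, function(i) {
    p <- preds$predictions[i, sel[i], ]
    d <- rowSums((candidate_labels -
                    matrix(p, nrow(candidate_labels), ncol(candidate_labels),
                           byrow = TRUE))^2)
    list(prediction = p, nearest = rownames(candidate_labels)[which.min(d)],
         likelihood = preds$likelihoods[i, sel[i]])
  })
  nearest <- vapply(flank, function(f) f$nearest, character(1))
  correct_exact <- true_partner %in% nearest
  correct_cluster <- if (!is.null(clusters)) {
    any(clusters[nearest] == clusters[true_partner])
  } else NA
  structure(list(query_id = query$gene_id, nearest = nearest,
                 likelihoods = vapply(flank, function(f) f$likelihood, numeric(1)),
                 flank_predictions = lapply(flank, function(f) f$prediction),
                 correct_exact = correct_exact,
                 correct_cluster = correct_cluster),
            class = "paralog_query_result")
}

#' Random-prediction null for paralog matching
#'
#' Replays the matching with standard-normal prediction vectors: per
#' iteration each query gets two random label-space vectors (one per masked
#' flank), the nearest candidate is retrieved for each, and the number of
#' queries whose true partner is found is recorded.
#'
#' @param candidate_labels candidate x label_dim matrix (rownames = ids).
#' @param true_partners character vector, one partner id per query.
#' @param n_iter iterations (default 1000).
#' @param seed integer seed.
#' @return integer vector of per-iteration correct-match counts.
#' @export
paralog_chance_null <- function(candidate_labels, true_partners,
                                n_iter = 1000L, seed = 1L) {
  ld <- ncol(candidate_labels)
  ids <- rownames(candidate_labels)
  n_q <- length(true_partners)
  with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      hits <- 0L
      for (q in seq_len(n_q)) {
        found <- FALSE
        for (f in 1:2) {
          p <- stats::rnorm(ld)
          d <- rowSums((candidate_labels -
                          matrix(p, nrow(candidate_labels), ld, byrow = TRUE))^2)
          if (ids[which.min(d)] == true_partners[q]) found <- TRUE
        }
        hits <- hits + as.integer(found)
      }
      hits
    }, integer(1))
  })
}

#' Evaluate paralog matching on planted pairs
#'
#' For each planted pair (X, Y): queries the model with a clean X occurrence
#' (family center, normalized) in the (mask, X, mask) test contig; candidates
#' are the labels of all pair-member families. Reports the exact-match count
#' and the chance null.
#'
#' @param model a trained model.
#' @param norm the corpus normalizer.
#' @param proj the label projector.
#' @param catalog the family catalog the pairs were drawn from.
#' @param pairs the planted [sample_interacting_pairs()] table.
#' @param n_iter chance-simulation iterations.
#' @param seed integer seed.
#' @return list: `n_correct`, `results`, `null_counts`, `null_q95`.
#' @export
paralog_evaluate <- function(model, norm, proj, catalog, pairs,
                             n_iter = 1000L, seed = 1L) {
  fams <- unique(c(pairs$family_a, pairs$family_b))
  cand_genes <- lapply(fams, function(f) {
    apply_normalizer(norm, gene_record(f, catalog$centers[f, ], 0.5))
  })
  candidate_labels <- do.call(rbind, lapply(cand_genes, function(g) make_label(proj, g)))
  rownames(candidate_labels) <- fams
  results <- lapply(seq_len(nrow(pairs)), function(i) {
    q <- cand_genes[[match(pairs$family_a[i], fams)]]
    q$gene_id <- pairs$family_a[i]
    paralog_match(model, q, candidate_labels, pairs$family_b[i])
  })
  n_correct <- sum(vapply(results, function(r) r$correct_exact, logical(1)))
  null_counts <- paralog_chance_null(candidate_labels, pairs$family_b,
                                     n_iter = n_iter, seed = derive_seed(seed, 3))
  list(n_correct = n_correct, results = results, null_counts = null_counts,
       null_q95 = stats::quantile(null_counts, 0.95, names = FALSE))
}
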