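test_that("configuration arithmetic: heads, head width, validation", {
  full <- glm_config(19L, 1280L, 10L, n_pred = 4L,
                     input_dim = 1281L, label_dim = 100L)
  expect_identical(n_total_heads(full), 190L)

  desk <- tiny_config(n_layers = 4L, hidden = 128L, n_heads = 4L,
                      n_pred = 4L, input_dim = 33L, label_dim = 17L)
  model <- init_model(desk, seed = 1L)
  expect_identical(ncol(model$params$W_head), 4L * 17L + 4L)  # 72 outputs

  expect_error(glm_config(2L, 30L, 4L, input_dim = 5L, label_dim = 3L),
               "divisible")
  expect_error(glm_config(2L, 32L, 4L, n_pred = 0L, input_dim = 5L, label_dim = 3L),
               "n_pred")
})

test_that("initialization is seed-deterministic", {
  cfg <- tiny_config()
  expect_identical(init_model(cfg, seed = 5L)$params,
                   init_model(cfg, seed = 5L)$params)
  expect_false(identical(init_model(cfg, seed = 5L)$params,
                         init_model(cfg, seed = 6L)$params))
})

test_that("forward pass: simplex likelihoods, batch equivariance, padding invariance", {
  ts <- tiny_setup()
  batch <- mask_batch(ts$contigs, 0.2, ts$proj, seed = 3L)
  out <- glm_forward(ts$model, batch, need_attn = TRUE)
  expect_equal(rowSums(out$predictions$likelihoods),
               rep(1, nrow(batch$masked_positions)), tolerance = 1e-6)
  expect_true(all(out$predictions$likelihoods >= 0))

  # attention rows over real keys are stochastic
  A <- out$attns[[1]][[2]][[1]]
  expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)

  # permuting the contigs permutes, but does not change, per-contig outputs
  perm <- rev(seq_along(ts$contigs))
  batch_p <- mask_positions_batch(ts$contigs[perm],
                                  lapply(perm, function(i) 1L), ts$proj)
  batch_o <- mask_positions_batch(ts$contigs,
                                  lapply(seq_along(ts$contigs), function(i) 1L),
                                  ts$proj)
  out_p <- glm_forward(ts$model, batch_p)
  out_o <- glm_forward(ts$model, batch_o)
  for (k in seq_along(perm)) {
    row_p <- which(batch_p$masked_positions[, 1] == k)
    row_o <- which(batch_o$masked_positions[, 1] == perm[k])
    expect_equal(out_p$predictions$predictions[row_p, , ],
                 out_o$predictions$predictions[row_o, , ], tolerance = 1e-12)
  }

  # a short contig batched next to a longer one (hence padded) is unchanged
  short <- ts$contigs[[1]]
  long <- ts$contigs[[which.max(vapply(ts$contigs, length, integer(1)))]]
  alone <- glm_forward(ts$model, mask_positions_batch(list(short), list(2L), ts$proj))
  padded <- glm_forward(ts$model, mask_positions_batch(list(short, long),
                                                       list(2L, 1L), ts$proj))
  expect_equal(alone$predictions$predictions[1, , ],
               padded$predictions$predictions[1, , ], tolerance = 1e-10)

  bad <- mask_positions_batch(list(short), list(2L), ts$proj)
  bad$tokens <- bad$tokens[, , -1, drop = FALSE]
  expect_error(glm_forward(ts$model, bad), "input_dim")
})

test_that("loss closed forms: perfect prediction and uniform likelihoods", {
  label <- c(1, -2, 0.5, 3, 0.5)
  preds <- array(0, dim = c(1, 2, 5))
  preds[1, 1, ] <- label
  preds[1, 2, ] <- label + 10
  ps <- make_prediction_set(preds, matrix(c(50, -50), 1), cbind(1L, 1L))
  lb <- compute_loss(ps, rbind(label), alpha = 1)
  expect_equal(lb$mse_term, 0)
  expect_lt(lb$ce_term, 1e-10)
  expect_lt(lb$total, 1e-10)
  expect_identical(lb$closest_indices, 1L)

  # uniform logits over 4 predictions: cross-entropy is ln 4 exactly
  preds4 <- array(rnorm(2 * 4 * 3), dim = c(2, 4, 3))
  ps4 <- make_prediction_set(preds4, matrix(0, 2, 4), cbind(1:2, 1L))
  lb4 <- compute_loss(ps4, matrix(rnorm(6), 2), alpha = 1)
  expect_equal(lb4$ce_term, log(4), tolerance = 1e-12)
  expect_equal(lb4$total, lb4$mse_term + lb4$alpha * lb4$ce_term)
})

test_that("loss matches a brute-force loop oracle on random batches", {
  brute_force_loss <- function(predictions, logits, labels, alpha) {
    n <- nrow(labels)
    mse_sum <- 0
    ce_sum <- 0
    for (i in seq_len(n)) {
      best_d <- Inf
      best_p <- NA
      for (p in seq_len(dim(predictions)[2])) {
        d <- 0
        for (j in seq_len(ncol(labels))) {
          d <- d + (predictions[i, p, j] - labels[i, j])^2
        }
        if (d < best_d) {
          best_d <- d
          best_p <- p
        }
      }
      for (j in seq_len(ncol(labels))) {
        mse_sum <- mse_sum + (predictions[i, best_p, j] - labels[i, j])^2
      }
      ce_sum <- ce_sum - log(exp(logits[i, best_p]) / sum(exp(logits[i, ])))
    }
    mse_sum / (n * ncol(labels)) + alpha * ce_sum / n
  }
  set.seed(10)
  for (trial in 1:5) {
    n <- sample(2:16, 1)
    np <- sample(2:4, 1)
    ld <- sample(3:6, 1)
    predictions <- array(rnorm(n * np * ld), dim = c(n, np, ld))
    logits <- matrix(rnorm(n * np), n, np)
    labels <- matrix(rnorm(n * ld), n, ld)
    ps <- make_prediction_set(predictions, logits, cbind(seq_len(n), 1L))
    expect_equal(compute_loss(ps, labels, alpha = 1e-4)$total,
                 brute_force_loss(predictions, logits, labels, 1e-4),
                 tolerance = 1e-6)
  }
})

test_that("adding a strictly closer prediction cannot increase the MSE term", {
  set.seed(11)
  labels <- matrix(rnorm(8 * 4), 8, 4)
  predictions <- array(rnorm(8 * 3 * 4), dim = c(8, 3, 4))
  logits <- matrix(rnorm(8 * 3), 8, 3)
  base <- compute_loss(make_prediction_set(predictions, logits,
                                           cbind(1:8, 1L)), labels, 1)
  better <- predictions
  # move prediction 3 of position 1 right onto its label: strictly closer
  better[1, 3, ] <- labels[1, ]
  impr <- compute_loss(make_prediction_set(better, logits, cbind(1:8, 1L)),
                       labels, 1)
  expect_lte(impr$mse_term, base$mse_term)
})

test_that("the likelihood term depends only on logits and closest indices", {
  set.seed(12)
  labels <- matrix(rnorm(6 * 3), 6, 3)
  predictions <- array(rnorm(6 * 4 * 3), dim = c(6, 4, 3))
  logits <- matrix(rnorm(6 * 4), 6, 4)
  a <- compute_loss(make_prediction_set(predictions, logits, cbind(1:6, 1L)),
                    labels, 1)
  moved <- predictions
  for (i in 1:6) {
    for (p in 1:4) {
      if (p != a$closest_indices[i]) {
        # push every non-closest prediction further out: indices unchanged
        moved[i, p, ] <- labels[i, ] + 5 * (moved[i, p, ] - labels[i, ])
      }
    }
  }
  b <- compute_loss(make_prediction_set(moved, logits, cbind(1:6, 1L)),
                    labels, 1)
  expect_identical(b$closest_indices, a$closest_indices)
  expect_identical(b$ce_term, a$ce_term)
})

test_that("backpropagated gradients match central finite differences", {
  cfg <- tiny_config(n_layers = 2L, hidden = 12L, n_heads = 2L, n_pred = 2L,
                     input_dim = 6L, label_dim = 4L, max_rel_distance = 8L)
  model <- init_model(cfg, seed = 21L)
  set.seed(22)
  catalog <- build_family_catalog(4L, 5L, 0.3, seed = 23L)
  corp <- sample_corpus(catalog, n_contigs = 3L, len_range = c(4L, 6L), seed = 24L)
  norm <- fit_normalizer(corp)
  contigs <- normalize_corpus(corp, norm)
  proj <- fit_label_projector(contigs, k_pc = 3L)
  batch <- mask_batch(contigs, 0.3, proj, seed = 25L)
  bt <- contiglm:::batch_tokens(batch)
  loss_at <- function(params) {
    fw <- contiglm:::transformer_forward(params, cfg, bt$X, bt$ranges)
    Hm <- fw$hidden[[cfg$n_layers + 1L]][bt$masked_rows, , drop = FALSE]
    Out <- contiglm:::addb(Hm %*% params$W_head, params$b_head)
    ps <- contiglm:::head_to_predictions(Out, cfg, batch$masked_positions)
    compute_loss(ps, batch$labels, alpha = 0.3)$total
  }
  params <- model$params
  fw <- contiglm:::transformer_forward(params, cfg, bt$X, bt$ranges,
                                       keep_cache = TRUE)
  Hm <- fw$hidden[[cfg$n_layers + 1L]][bt$masked_rows, , drop = FALSE]
  Out <- contiglm:::addb(Hm %*% params$W_head, params$b_head)
  ps <- contiglm:::head_to_predictions(Out, cfg, batch$masked_positions)
  lg <- contiglm:::loss_grad_out(ps, batch$labels, 0.3, cfg)
  grads <- contiglm:::transformer_backward(params, cfg, fw, lg$dOut,
                                           bt$masked_rows)
  flat <- unlist(params)
  gflat <- unlist(grads)
  set.seed(26)
  idx <- sample(length(flat), 40L)
  h <- 1e-5
  for (i in idx) {
    up <- flat
    up[i] <- up[i] + h
    dn <- flat
    dn[i] <- dn[i] - h
    num <- (loss_at(relist(up, params)) - loss_at(relist(dn, params))) / (2 * h)
    if (abs(num) + abs(gflat[i]) < 1e-6) next  # below finite-difference noise
    expect_lt(abs(num - gflat[i]) / (abs(num) + abs(gflat[i])), 1e-3)
  }
})
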