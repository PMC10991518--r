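# Training loop (AdamW with linear warmup) and evaluation metrics:
# pseudo-accuracy, absolute accuracy, confidence analysis.

#' Training configuration
#'
#' Desk-scale defaults; the warmup-to-peak schedule mirrors the published
#' setup (5000 warmup steps to 1e-4 at full scale) with the learning rate
#' held constant after warmup.
#'
#' @param total_steps number of optimizer steps.
#' @param batch_size contigs per step.
#' @param warmup_steps linear warmup length (must be <= total_steps).
#' @param peak_lr learning rate reached at `warmup_steps`.
#' @param weight_decay decoupled weight decay on weight matrices.
#' @param mask_rate masking probability per gene (default 0.15).
#' @param alpha likelihood cross-entropy weight (default 1e-4).
#' @param val_fraction fraction of contigs held out for validation.
#' @param eval_every validation cadence in steps.
#' @param clip_norm global gradient-norm clip (Inf disables).
#' @param lr_decay post-warmup schedule: `"constant"` holds the peak rate,
#'   `"linear"` decays it linearly to zero at `total_steps`.
#' @param seed integer seed driving shuffling and masking.
#' @export
train_config <- function(total_steps = 500L, batch_size = 32L,
                         warmup_steps = 50L, peak_lr = 1e-3,
                         weight_decay = 0.01, mask_rate = 0.15,
                         alpha = 1e-4, val_fraction = 0.1,
                         eval_every = 50L, clip_norm = 1.0,
                         lr_decay = c("constant", "linear"), seed = 1L) {
  lr_decay <- match.arg(lr_decay)
  if (warmup_steps > total_steps) stop_param("train_config: warmup_steps must be <= total_steps")
  if (peak_lr <= 0) stop_param("train_config: peak_lr must be > 0")
  structure(list(total_steps = as.integer(total_steps),
                 batch_size = as.integer(batch_size),
                 warmup_steps = as.integer(warmup_steps), peak_lr = peak_lr,
                 weight_decay = weight_decay, mask_rate = mask_rate,
                 alpha = alpha, val_fraction = val_fraction,
                 eval_every = as.integer(eval_every), clip_norm = clip_norm,
                 lr_decay = lr_decay, seed = seed),
            class = "train_config")
}

#' Learning rate at a given step
#'
#' Linear warmup from 0 to `peak_lr` over `warmup_steps`;
#' `lr_schedule(warmup_steps, cfg) == peak_lr` exactly. After warmup the rate
#' is held constant or decayed linearly to zero at `total_steps`, per
#' `cfg$lr_decay`.
#'
#' @param step optimizer step (1-based).
#' @param cfg a [train_config()].
#' @export
lr_schedule <- function(step, cfg) {
  if (step <= cfg$warmup_steps) return(cfg$peak_lr * step / cfg$warmup_steps)
  if (identical(cfg$lr_decay, "linear")) {
    span <- max(cfg$total_steps - cfg$warmup_steps, 1L)
    return(cfg$peak_lr * (cfg$total_steps - step) / span)
  }
  cfg$peak_lr
}

adamw_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

# Decoupled weight decay applies to 2-d weight matrices only (not biases,
# layer-norm parameters, or other vectors).
adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  upd <- tree_map2(function(m, v) (m / b1t) / (sqrt(v / b2t) + eps), state$m, state$v)
  params <- tree_map2(function(p, u) {
    wd <- if (length(dim(p)) == 2L) weight_decay else 0
    p - lr * (u + wd * p)
  }, params, upd)
  list(params = params, state = state)
}

clip_gradients <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  nrm <- sqrt(tree_sum(function(g) sum(g * g), grads))
  if (nrm > max_norm) grads <- tree_map(function(g) g * (max_norm / nrm), grads)
  grads
}

#' Train a model
#'
#' Splits contigs into disjoint train/validation sets (whole contigs at
#' random), then runs masked-token training: each step masks a fresh batch,
#' runs the forward/backward passes and an AdamW update under the warmup
#' schedule. Validation pseudo-accuracy is computed every `eval_every` steps
#' and the best-scoring parameters are kept as the returned checkpoint.
#'
#' @param model an initialized [init_model()].
#' @param contigs list of normalized [subcontig()].
#' @param proj the fitted [fit_label_projector()].
#' @param cfg a [train_config()].
#' @param quiet suppress progress messages.
#' @return list: `model` (with the best-validation parameters), `history`
#'   (data.frame of step, lr, mse, ce, total), `val_history`,
#'   `train_ids`/`val_ids`, `best_val`.
#' @export
train_glm <- function(model, contigs, proj, cfg = train_config(), quiet = FALSE) {
  if (!length(contigs)) stop_param("train_glm: empty training set")
  cfgm <- model$config
  n <- length(contigs)
  n_val <- floor(cfg$val_fraction * n)
  idx <- with_seed(derive_seed(cfg$seed, 100), sample.int(n))
  val_idx <- if (n_val > 0L) sort(idx[seq_len(n_val)]) else integer(0)
  train_idx <- if (n_val > 0L) sort(idx[-seq_len(n_val)]) else sort(idx)
  if (!length(train_idx)) stop_param("train_glm: empty training split")
  train_set <- contigs[train_idx]
  val_set <- contigs[val_idx]
  val_batch <- if (length(val_set)) {
    mask_batch(val_set, cfg$mask_rate, proj, seed = derive_seed(cfg$seed, 101))
  }
  params <- model$params
  state <- adamw_init(params)
  # contigs are fixed across steps: precompute token and label matrices once
  tok_list <- lapply(train_set, function(ct) {
    cbind(contig_embedding_matrix(ct), contig_orientations(ct))
  })
  lab_list <- lapply(train_set, function(ct) label_matrix(proj, ct))
  lens_all <- vapply(train_set, function(ct) length(ct$genes), integer(1))
  history <- vector("list", cfg$total_steps)
  val_history <- list()
  best_val <- -Inf
  best_params <- params
  order_cache <- integer(0)
  pos <- 0L
  epoch <- 0L
  for (step in seq_len(cfg$total_steps)) {
    if (pos + cfg$batch_size > length(order_cache)) {
      epoch <- epoch + 1L
      order_cache <- with_seed(derive_seed(cfg$seed, 200 + epoch),
                               sample.int(length(train_set)))
      pos <- 0L
    }
    take <- order_cache[pos + seq_len(min(cfg$batch_size, length(order_cache) - pos))]
    pos <- pos + length(take)
    masks <- with_seed(derive_seed(cfg$seed, 1000 + step), {
      lapply(lens_all[take], function(L) {
        repeat {
          m <- stats::runif(L) < cfg$mask_rate
          if (any(m)) return(m)
        }
      })
    })
    X <- do.call(rbind, tok_list[take])
    offsets <- c(0L, cumsum(lens_all[take]))
    ranges <- lapply(seq_along(take), function(b) (offsets[b] + 1L):offsets[b + 1L])
    masked_rows <- unlist(Map(function(b, m) offsets[b] + which(m),
                              seq_along(take), masks))
    X[masked_rows, ] <- cfgm$mask_value
    labels <- do.call(rbind, Map(function(i, m) lab_list[[i]][m, , drop = FALSE],
                                 take, masks))
    positions <- do.call(rbind, Map(function(b, m) cbind(b, which(m)),
                                    seq_along(take), masks))
    fw <- transformer_forward(params, cfgm, X, ranges,
                              keep_cache = TRUE, training = TRUE)
    Hm <- fw$hidden[[cfgm$n_layers + 1L]][masked_rows, , drop = FALSE]
    Out <- addb(Hm %*% params$W_head, params$b_head)
    preds <- head_to_predictions(Out, cfgm, positions)
    lg <- loss_grad_out(preds, labels, cfg$alpha, cfgm)
    if (!is.finite(lg$loss$total)) {
      stop("train_glm: non-finite loss at step ", step,
           " (mse=", lg$loss$mse_term, ", ce=", lg$loss$ce_term, ")",
           call. = FALSE)
    }
    grads <- transformer_backward(params, cfgm, fw, lg$dOut, masked_rows)
    grads <- clip_gradients(grads, cfg$clip_norm)
    lr <- lr_schedule(step, cfg)
    up <- adamw_step(params, grads, state, lr, cfg$weight_decay)
    params <- up$params
    state <- up$state
    history[[step]] <- data.frame(step = step, lr = lr,
                                  mse = lg$loss$mse_term,
                                  ce = lg$loss$ce_term,
                                  total = lg$loss$total)
    if (!is.null(val_batch) &&
        (step %% cfg$eval_every == 0L || step == cfg$total_steps)) {
      vm <- list(config = cfgm, params = params)
      class(vm) <- "glm_model"
      vout <- glm_forward(vm, val_batch)
      vacc <- pseudo_accuracy(vout$predictions, val_batch)
      val_history[[length(val_history) + 1L]] <-
        data.frame(step = step, pseudo_accuracy = vacc)
      if (vacc >= best_val) {
        best_val <- vacc
        best_params <- params
      }
      if (!quiet) {
        message(sprintf("step %d/%d  loss %.4f  val pseudo-accuracy %.3f",
                        step, cfg$total_steps, lg$loss$total, vacc))
      }
    }
  }
  final <- model
  final$params <- if (is.null(val_batch)) params else best_params
  list(model = final,
       history = do.call(rbind, history),
       val_history = if (length(val_history)) do.call(rbind, val_history),
       train_ids = vapply(train_set, function(ct) ct$contig_id, character(1)),
       val_ids = vapply(val_set, function(ct) ct$contig_id, character(1)),
       best_val = best_val)
}

# ---- metrics ----------------------------------------------------------------

# Which prediction represents a masked position: the highest-likelihood one
# (matching the confidence analysis) or the best of the n_pred (diagnostic).
select_predictions <- function(preds, mode = c("top_likelihood", "best_of_n"),
                               batch = NULL) {
  mode <- match.arg(mode)
  n <- nrow(preds$likelihoods)
  ld <- dim(preds$predictions)[3]
  if (mode == "top_likelihood") {
    sel <- max.col(preds$likelihoods, ties.method = "first")
    out <- matrix(0, n, ld)
    for (i in seq_len(n)) out[i, ] <- preds$predictions[i, sel[i], ]
    return(out)
  }
  NULL
}

#' Pseudo-accuracy of masked predictions
#'
#' A masked position is correct when its selected prediction is strictly
#' nearer (L2) to the masked gene's own label than to the label of any other
#' gene in the same subcontig; distance ties count as incorrect. With
#' `mode = "best_of_n"` a position is correct if any of its predictions
#' passes the criterion (secondary diagnostic).
#'
#' @param preds the `prediction_set` from [glm_forward()].
#' @param batch the originating [mask_batch()] (must carry `all_labels`).
#' @param mode prediction selection rule.
#' @return fraction correct, with attribute `correct` (per-position logical).
#' @export
pseudo_accuracy <- function(preds, batch, mode = c("top_likelihood", "best_of_n")) {
  mode <- match.arg(mode)
  if (is.null(batch$all_labels)) stop_param("pseudo_accuracy: batch lacks all_labels (build it with a projector)")
  mp <- preds$positions
  n <- nrow(mp)
  np <- ncol(preds$likelihoods)
  correct <- logical(n)
  sel <- max.col(preds$likelihoods, ties.method = "first")
  for (i in seq_len(n)) {
    lab <- batch$all_labels[[mp[i, 1]]]
    cand <- if (mode == "top_likelihood") {
      matrix(preds$predictions[i, sel[i], ], 1)
    } else {
      matrix(preds$predictions[i, , ], np)
    }
    ok <- FALSE
    for (p in seq_len(nrow(cand))) {
      d <- rowSums((lab - matrix(cand[p, ], nrow(lab), ncol(lab), byrow = TRUE))^2)
      dm <- min(d)
      hits <- which(d == dm)
      if (length(hits) == 1L && hits == mp[i, 2]) ok <- TRUE
      if (length(hits) > 1L && mp[i, 2] %in% hits) {
        warning("pseudo_accuracy: tied nearest labels counted as incorrect")
      }
    }
    correct[i] <- ok
  }
  structure(mean(correct), correct = correct)
}

#' Absolute accuracy over a gene universe
#'
#' Masks each gene of each contig singly, and scores a prediction correct only
#' when the masked gene's label is the unique nearest among the labels of
#' every gene in the whole genome (the union of all contigs). Because that
#' universe contains each subcontig's labels, absolute accuracy can never
#' exceed pseudo-accuracy on the same predictions.
#'
#' @param model a trained model.
#' @param genome list of normalized [subcontig()].
#' @param proj fitted projector.
#' @param chunk number of single-masked contig copies per forward pass.
#' @return fraction correct, attribute `correct`.
#' @export
absolute_accuracy <- function(model, genome, proj, chunk = 64L) {
  if (!length(genome)) stop_param("absolute_accuracy: empty genome")
  universe <- do.call(rbind, lapply(genome, function(ct) label_matrix(proj, ct)))
  jobs <- list()
  for (ci in seq_along(genome)) {
    for (i in seq_len(length(genome[[ci]]$genes))) {
      jobs[[length(jobs) + 1L]] <- c(ci, i)
    }
  }
  offsets <- c(0L, cumsum(vapply(genome, length, integer(1))))
  correct <- logical(length(jobs))
  for (start in seq(1L, length(jobs), by = chunk)) {
    take <- start:min(start + chunk - 1L, length(jobs))
    contigs <- lapply(take, function(j) genome[[jobs[[j]][1]]])
    masks <- lapply(take, function(j) {
      m <- rep(FALSE, length(genome[[jobs[[j]][1]]]$genes))
      m[jobs[[j]][2]] <- TRUE
      m
    })
    batch <- build_batch(contigs, masks, proj)
    out <- glm_forward(model, batch)
    selp <- select_predictions(out$predictions, "top_likelihood")
    for (k in seq_along(take)) {
      j <- jobs[[take[k]]]
      gi <- offsets[j[1]] + j[2]   # row of this gene in the universe
      d <- rowSums((universe - matrix(selp[k, ], nrow(universe),
                                      ncol(universe), byrow = TRUE))^2)
      hits <- which(d == min(d))
      correct[take[k]] <- length(hits) == 1L && hits == gi
    }
  }
  structure(mean(correct), correct = correct)
}

#' Confidence analysis of masked predictions
#'
#' @param preds the `prediction_set`.
#' @param batch the originating batch.
#' @param tau confidence threshold in (0, 1); a position is high confidence
#'   when its top likelihood exceeds `tau`.
#' @return list: `high_conf_fraction`, `high_conf_accuracy` (pseudo-accuracy
#'   restricted to high-confidence positions; NA when there are none).
#' @export
confidence_report <- function(preds, batch, tau = 0.75) {
  if (tau < 0 || tau >= 1) stop_param("confidence_report: tau must be in [0,1)")
  top <- apply(preds$likelihoods, 1, max)
  high <- top > tau
  acc <- pseudo_accuracy(preds, batch)
  correct <- attr(acc, "correct")
  list(high_conf_fraction = mean(high),
       high_conf_accuracy = if (any(high)) mean(correct[high]) else NA_real_,
       overall_accuracy = as.numeric(acc))
}

#' Save / load a model checkpoint
#'
#' Bundles the configuration, parameters, normalizer and projector in one
#' versioned RDS file.
#'
#' @param model a `glm_model`.
#' @param norm the [fit_normalizer()] used for its corpus.
#' @param proj the [fit_label_projector()].
#' @param path file path.
#' @export
save_checkpoint <- function(model, norm, proj, path) {
  saveRDS(list(version = 1L, config = model$config, params = model$params,
               normalizer = norm, projector = proj), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$version)) stop_param("load_checkpoint: not a checkpoint file")
  model <- structure(list(config = ck$config, params = ck$params),
                     class = "glm_model")
  list(model = model, normalizer = ck$normalizer, projector = ck$projector)
}
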