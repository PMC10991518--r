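# User-facing forward pass, prediction set, and the training loss.

# Extract real (unpadded) tokens from a masked_batch into a dense N x (E+1)
# matrix plus per-contig row ranges and global row indices of masked positions.
batch_tokens <- function(batch) {
  B <- dim(batch$tokens)[1]
  lens <- batch$lengths
  offsets <- c(0L, cumsum(lens))
  X <- matrix(0, sum(lens), dim(batch$tokens)[3])
  ranges <- vector("list", B)
  for (b in seq_len(B)) {
    r <- (offsets[b] + 1L):offsets[b + 1L]
    ranges[[b]] <- r
    X[r, ] <- batch$tokens[b, seq_len(lens[b]), ]
  }
  mp <- batch$masked_positions
  masked_rows <- if (nrow(mp)) offsets[mp[, 1]] + mp[, 2] else integer(0)
  list(X = X, ranges = ranges, masked_rows = masked_rows, offsets = offsets)
}

# Split the flat head output into predictions and likelihood logits.
head_to_predictions <- function(Out, cfg, positions) {
  n <- nrow(Out)
  np <- cfg$n_pred
  ld <- cfg$label_dim
  predictions <- array(Out[, seq_len(np * ld), drop = FALSE], dim = c(n, ld, np))
  predictions <- aperm(predictions, c(1, 3, 2))  # n x n_pred x label_dim
  logits <- Out[, np * ld + seq_len(np), drop = FALSE]
  structure(list(predictions = predictions,
                 likelihood_logits = logits,
                 likelihoods = softmax_rows(logits),
                 positions = positions),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set: %d masked positions, %d predictions each>\n",
              nrow(x$likelihoods), ncol(x$likelihoods)))
  invisible(x)
}

#' Run the model on a batch
#'
#' Computes predictions (and likelihood simplexes) for every masked position.
#' Padding positions are never part of the computation, so attention mass on
#' padded keys is exactly zero and outputs are invariant to padding.
#'
#' @param model a [init_model()] or [train_glm()] result.
#' @param batch a [mask_batch()] or [as_batch()] result.
#' @param need_hidden keep all per-layer hidden states.
#' @param need_attn keep all per-layer/head attention matrices.
#' @return object of class `glm_output`: `predictions` (a `prediction_set`,
#'   or NULL when nothing is masked), `hidden` (list over layers 0..n_layers
#'   of N x hidden matrices, layer 0 being the projected inputs), `attns`
#'   (`attns[[layer]][[contig]][[head]]`, row-stochastic L x L), `ranges`.
#' @export
glm_forward <- function(model, batch, need_hidden = FALSE, need_attn = FALSE) {
  cfg <- model$config
  bt <- batch_tokens(batch)
  if (ncol(bt$X) != cfg$input_dim) {
    stop_param("glm_forward: batch token width ", ncol(bt$X),
               " != configured input_dim ", cfg$input_dim)
  }
  fw <- transformer_forward(model$params, cfg, bt$X, bt$ranges,
                            need_attn = need_attn, keep_cache = FALSE)
  preds <- NULL
  if (length(bt$masked_rows)) {
    Hm <- fw$hidden[[cfg$n_layers + 1L]][bt$masked_rows, , drop = FALSE]
    Out <- addb(Hm %*% model$params$W_head, model$params$b_head)
    preds <- head_to_predictions(Out, cfg, batch$masked_positions)
  }
  structure(list(predictions = preds,
                 hidden = if (need_hidden) fw$hidden,
                 attns = if (need_attn) fw$attns,
                 ranges = bt$ranges, lengths = batch$lengths,
                 contig_ids = batch$contig_ids),
            class = "glm_output")
}

#' Training loss of a prediction set
#'
#' Per masked position the closest of the `n_pred` predictions to the label
#' (L2 distance, ties to the lowest index) carries the squared error, averaged
#' over positions and label dimensions; the likelihood logits are scored by
#' cross-entropy against the closest-prediction index, averaged over
#' positions. `total = mse_term + alpha * ce_term`.
#'
#' @param preds a `prediction_set`.
#' @param labels n x label_dim matrix, one row per masked position.
#' @param alpha cross-entropy weight.
#' @return object of class `loss_breakdown` with `mse_term`, `ce_term`,
#'   `total`, `alpha`, `closest_indices`.
#' @export
compute_loss <- function(preds, labels, alpha = 1e-4) {
  np <- ncol(preds$likelihoods)
  if (np < 1L) stop_param("compute_loss: n_pred must be >= 1")
  labels <- rbind(labels)
  n <- nrow(labels)
  ld <- ncol(labels)
  if (!all(is.finite(preds$predictions))) stop("compute_loss: non-finite predictions")
  dists <- matrix(0, n, np)
  for (p in seq_len(np)) {
    Pm <- matrix(preds$predictions[, p, ], nrow = n)
    dists[, p] <- rowSums((Pm - labels)^2)
  }
  closest <- max.col(-dists, ties.method = "first")
  mse <- sum(dists[cbind(seq_len(n), closest)]) / (n * ld)
  logits <- preds$likelihood_logits
  lse <- log(rowSums(exp(logits - row_max(logits)))) + row_max(logits)
  ce <- mean(lse - logits[cbind(seq_len(n), closest)])
  structure(list(mse_term = mse, ce_term = ce, total = mse + alpha * ce,
                 alpha = alpha, closest_indices = closest),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss: total %.6g = mse %.6g + %.2g * ce %.6g>\n",
              x$total, x$mse_term, x$alpha, x$ce_term))
  invisible(x)
}

# Gradient of compute_loss w.r.t. the flat head output (n x out_dim).
loss_grad_out <- function(preds, labels, alpha, cfg) {
  labels <- rbind(labels)
  n <- nrow(labels)
  ld <- ncol(labels)
  np <- cfg$n_pred
  lb <- compute_loss(preds, labels, alpha)
  dOut <- matrix(0, n, np * ld + np)
  chosen <- matrix(0, n, ld)
  for (i in seq_len(n)) chosen[i, ] <- preds$predictions[i, lb$closest_indices[i], ]
  dchosen <- 2 * (chosen - labels) / (n * ld)
  for (i in seq_len(n)) {
    p <- lb$closest_indices[i]
    dOut[i, (p - 1L) * ld + seq_len(ld)] <- dchosen[i, ]
  }
  probs <- preds$likelihoods
  onehot <- matrix(0, n, np)
  onehot[cbind(seq_len(n), lb$closest_indices)] <- 1
  dOut[, np * ld + seq_len(np)] <- alpha * (probs - onehot) / n
  list(dOut = dOut, loss = lb)
}
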