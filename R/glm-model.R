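# Transformer encoder over gene tokens with a multi-prediction + likelihood
# head. Forward and backward passes are written directly in matrix code:
# post-layer-norm encoder blocks, multi-head self-attention with learned
# relative key-query position terms, GELU feed-forward, and a joint affine
# head projecting the final hidden state of each masked position into
# n_pred label-space vectors and n_pred likelihood logits.

#' Model configuration
#'
#' @param n_layers encoder layers (full scale: 19).
#' @param hidden hidden width (full scale: 1280); must be divisible by `n_heads`.
#' @param n_heads attention heads per layer (full scale: 10).
#' @param n_pred number of predictions per masked position (default 4).
#' @param input_dim token width: embedding dimension + 1 orientation slot.
#' @param label_dim label width: retained PCs + 1 orientation slot.
#' @param max_rel_distance relative-position clip; defaults to 30 (the
#'   maximum contig length) so every pairwise offset gets its own embedding.
#' @param ffn_mult feed-forward expansion factor.
#' @param mask_value the mask token value (-1).
#' @param alpha weight of the likelihood cross-entropy term (default 1e-4).
#' @param dropout dropout probability on sublayer outputs during training.
#' @return object of class `glm_config`.
#' @export
glm_config <- function(n_layers, hidden, n_heads, n_pred = 4L,
                       input_dim, label_dim, max_rel_distance = 30L,
                       ffn_mult = 2L, mask_value = -1, alpha = 1e-4,
                       dropout = 0) {
  if (hidden %% n_heads != 0) stop_param("glm_config: hidden must be divisible by n_heads")
  if (n_pred < 1L) stop_param("glm_config: n_pred must be >= 1")
  if (alpha < 0) stop_param("glm_config: alpha must be >= 0")
  if (n_layers < 1L || hidden < 1L || input_dim < 1L || label_dim < 1L) {
    stop_param("glm_config: dimensions must be positive")
  }
  structure(list(n_layers = as.integer(n_layers), hidden = as.integer(hidden),
                 n_heads = as.integer(n_heads), n_pred = as.integer(n_pred),
                 input_dim = as.integer(input_dim), label_dim = as.integer(label_dim),
                 max_rel_distance = as.integer(max_rel_distance),
                 ffn_mult = as.integer(ffn_mult), mask_value = mask_value,
                 alpha = alpha, dropout = dropout),
            class = "glm_config")
}

#' Total number of attention heads of a configuration
#'
#' @param config a [glm_config()].
#' @export
n_total_heads <- function(config) config$n_layers * config$n_heads

#' Initialize a model
#'
#' Weights are drawn N(0, 0.02^2), biases start at zero, layer-norm gains at
#' one; the same seed reproduces the initialization exactly.
#'
#' @param config a [glm_config()].
#' @param seed integer seed.
#' @return object of class `glm_model`: `list(config, params)`.
#' @export
init_model <- function(config, seed = 1L) {
  H <- config$hidden
  dh <- H %/% config$n_heads
  M <- 2L * config$max_rel_distance + 1L
  ffn <- H * config$ffn_mult
  out_dim <- config$n_pred * config$label_dim + config$n_pred
  wmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  params <- with_seed(seed, {
    layers <- lapply(seq_len(config$n_layers), function(l) {
      list(Wq = wmat(H, H), bq = numeric(H),
           Wk = wmat(H, H), bk = numeric(H),
           Wv = wmat(H, H), bv = numeric(H),
           Wo = wmat(H, H), bo = numeric(H),
           R = wmat(M, dh),
           g1 = rep(1, H), be1 = numeric(H),
           W1 = wmat(H, ffn), b1 = numeric(ffn),
           W2 = wmat(ffn, H), b2 = numeric(H),
           g2 = rep(1, H), be2 = numeric(H))
    })
    list(W_in = wmat(config$input_dim, H), b_in = numeric(H),
         layers = layers,
         W_head = wmat(H, out_dim), b_head = numeric(out_dim))
  })
  structure(list(config = config, params = params), class = "glm_model")
}

#' @export
print.glm_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<glm_model: %d layers, hidden %d, %d heads (%d total), n_pred %d, %d parameters>\n",
              cfg$n_layers, cfg$hidden, cfg$n_heads, n_total_heads(cfg),
              cfg$n_pred, tree_sum(length, x$params)))
  invisible(x)
}

# ---- low-level pieces -------------------------------------------------------

addb <- function(M, b) M + rep(b, each = nrow(M))

gelu <- function(x) x * stats::pnorm(x)

ln_eps <- 1e-5

ln_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + ln_eps)
  xhat <- xc * inv
  list(y = addb(xhat * rep(g, each = nrow(x)), b) , xhat = xhat, inv = inv)
}

ln_backward <- function(dy, xhat, inv, g) {
  n <- nrow(dy)
  dxhat <- dy * rep(g, each = n)
  rm1 <- rowMeans(dxhat)
  rm2 <- rowMeans(dxhat * xhat)
  list(dx = (dxhat - rm1 - xhat * rm2) * inv,
       dg = colSums(dy * xhat),
       db = colSums(dy))
}

# Cached gather/scatter indices for the relative-position terms.
# For query row i and key column j the (clipped) signed offset j - i selects
# table row D[i, j]; qr/kr are L x L linear indices into an L x M score
# contribution matrix, used both to gather (forward) and as scatter groups
# (backward, via rowsum).
.rel_idx_cache <- new.env(parent = emptyenv())

rel_idx <- function(L, maxd) {
  key <- paste0(L, "_", maxd)
  got <- .rel_idx_cache[[key]]
  if (!is.null(got)) return(got)
  D <- matrix(0L, L, L)
  for (j in seq_len(L)) D[, j] <- pmin(pmax(j - seq_len(L), -maxd), maxd) + maxd + 1L
  I <- matrix(seq_len(L), L, L)
  J <- matrix(seq_len(L), L, L, byrow = TRUE)
  out <- list(qr = I + (D - 1L) * L, kr = J + (D - 1L) * L,
              # without clipping each (query, key) cell hits a distinct table
              # cell, so the backward scatter is a plain indexed assignment
              injective = maxd >= L - 1L)
  .rel_idx_cache[[key]] <- out
  out
}

rel_scatter <- function(draw, group, L, M, injective = FALSE) {
  out <- numeric(L * M)
  if (injective) {
    out[as.vector(group)] <- as.vector(draw)
  } else {
    rs <- rowsum(as.vector(draw), as.vector(group))
    out[as.integer(rownames(rs))] <- rs
  }
  dim(out) <- c(L, M)
  out
}

row_max <- function(S) S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]

softmax_rows <- function(S) {
  P <- exp(S - row_max(S))
  P / rowSums(P)
}

# ---- forward ----------------------------------------------------------------

# X: N x input_dim real tokens (no padding rows); ranges: list of row-index
# vectors, one per contig. Returns hidden states, optional attentions, and a
# cache sufficient for the backward pass.
transformer_forward <- function(params, cfg, X, ranges,
                                need_attn = FALSE, keep_cache = FALSE,
                                training = FALSE) {
  N <- nrow(X)
  H <- cfg$hidden
  nh <- cfg$n_heads
  dh <- H %/% nh
  maxd <- cfg$max_rel_distance
  sq <- sqrt(dh)
  drop_p <- if (training) cfg$dropout else 0
  Hs <- addb(X %*% params$W_in, params$b_in)
  hidden <- vector("list", cfg$n_layers + 1L)
  hidden[[1]] <- Hs
  attns <- if (need_attn || keep_cache) vector("list", cfg$n_layers) else NULL
  caches <- if (keep_cache) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    lp <- params$layers[[l]]
    tR <- t(lp$R)
    H_in <- Hs
    Q <- addb(H_in %*% lp$Wq, lp$bq)
    K <- addb(H_in %*% lp$Wk, lp$bk)
    V <- addb(H_in %*% lp$Wv, lp$bv)
    Ctx <- matrix(0, N, H)
    Pl <- if (!is.null(attns)) vector("list", length(ranges)) else NULL
    for (ci in seq_along(ranges)) {
      r <- ranges[[ci]]
      L <- length(r)
      g <- rel_idx(L, maxd)
      Pc <- if (!is.null(Pl)) vector("list", nh) else NULL
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        Qh <- Q[r, cols, drop = FALSE]
        Kh <- K[r, cols, drop = FALSE]
        QR <- Qh %*% tR
        KR <- Kh %*% tR
        S <- (tcrossprod(Qh, Kh) + QR[g$qr] + KR[g$kr]) / sq
        P <- softmax_rows(S)
        Ctx[r, cols] <- P %*% V[r, cols, drop = FALSE]
        if (!is.null(Pc)) Pc[[h]] <- P
      }
      if (!is.null(Pl)) Pl[[ci]] <- Pc
    }
    A <- addb(Ctx %*% lp$Wo, lp$bo)
    dm1 <- NULL
    if (drop_p > 0) {
      dm1 <- matrix(stats::rbinom(N * H, 1, 1 - drop_p), N, H) / (1 - drop_p)
      A <- A * dm1
    }
    ln1 <- ln_forward(H_in + A, lp$g1, lp$be1)
    H1 <- ln1$y
    U <- addb(H1 %*% lp$W1, lp$b1)
    pn <- stats::pnorm(U)
    G <- U * pn
    Fo <- addb(G %*% lp$W2, lp$b2)
    dm2 <- NULL
    if (drop_p > 0) {
      dm2 <- matrix(stats::rbinom(N * H, 1, 1 - drop_p), N, H) / (1 - drop_p)
      Fo <- Fo * dm2
    }
    ln2 <- ln_forward(H1 + Fo, lp$g2, lp$be2)
    Hs <- ln2$y
    hidden[[l + 1L]] <- Hs
    if (!is.null(attns)) attns[[l]] <- Pl
    if (keep_cache) {
      caches[[l]] <- list(H_in = H_in, Q = Q, K = K, V = V, Ctx = Ctx,
                          P = Pl, ln1 = ln1, ln2 = ln2, H1 = H1, U = U,
                          pn = pn, G = G, dm1 = dm1, dm2 = dm2)
    }
  }
  list(hidden = hidden, attns = if (need_attn || keep_cache) attns,
       caches = caches, X = X, ranges = ranges)
}

# Backward pass: dOut is the loss gradient w.r.t. the head output rows
# (n_masked x out_dim), masked_rows are global row indices into the token
# matrix. Returns a gradient tree with the same shape as params.
transformer_backward <- function(params, cfg, fw, dOut, masked_rows) {
  N <- nrow(fw$X)
  H <- cfg$hidden
  nh <- cfg$n_heads
  dh <- H %/% nh
  maxd <- cfg$max_rel_distance
  sq <- sqrt(dh)
  Hm <- fw$hidden[[cfg$n_layers + 1L]][masked_rows, , drop = FALSE]
  gW_head <- crossprod(Hm, dOut)
  gb_head <- colSums(dOut)
  dH <- matrix(0, N, H)
  dH[masked_rows, ] <- dOut %*% t(params$W_head)
  glayers <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- params$layers[[l]]
    cc <- fw$caches[[l]]
    ln2b <- ln_backward(dH, cc$ln2$xhat, cc$ln2$inv, lp$g2)
    dres2 <- ln2b$dx
    dF <- if (is.null(cc$dm2)) dres2 else dres2 * cc$dm2
    dH1 <- dres2
    dG <- dF %*% t(lp$W2)
    gW2 <- crossprod(cc$G, dF)
    gb2 <- colSums(dF)
    dU <- dG * (cc$pn + cc$U * stats::dnorm(cc$U))
    dH1 <- dH1 + dU %*% t(lp$W1)
    gW1 <- crossprod(cc$H1, dU)
    gb1 <- colSums(dU)
    ln1b <- ln_backward(dH1, cc$ln1$xhat, cc$ln1$inv, lp$g1)
    dres1 <- ln1b$dx
    dA <- if (is.null(cc$dm1)) dres1 else dres1 * cc$dm1
    dH_prev <- dres1
    dCtx <- dA %*% t(lp$Wo)
    gWo <- crossprod(cc$Ctx, dA)
    gbo <- colSums(dA)
    M <- 2L * maxd + 1L
    dQ <- matrix(0, N, H)
    dK <- matrix(0, N, H)
    dV <- matrix(0, N, H)
    gR <- matrix(0, M, dh)
    for (ci in seq_along(fw$ranges)) {
      r <- fw$ranges[[ci]]
      L <- length(r)
      g <- rel_idx(L, maxd)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        P <- cc$P[[ci]][[h]]
        Qh <- cc$Q[r, cols, drop = FALSE]
        Kh <- cc$K[r, cols, drop = FALSE]
        Vh <- cc$V[r, cols, drop = FALSE]
        dCtx_h <- dCtx[r, cols, drop = FALSE]
        dP <- tcrossprod(dCtx_h, Vh)
        dV[r, cols] <- crossprod(P, dCtx_h)
        draw <- (P * (dP - rowSums(dP * P))) / sq
        dQh <- draw %*% Kh
        dKh <- crossprod(draw, Qh)
        dQR <- rel_scatter(draw, g$qr, L, M, g$injective)
        dKR <- rel_scatter(draw, g$kr, L, M, g$injective)
        dQh <- dQh + dQR %*% lp$R
        dKh <- dKh + dKR %*% lp$R
        gR <- gR + crossprod(dQR, Qh) + crossprod(dKR, Kh)
        dQ[r, cols] <- dQh
        dK[r, cols] <- dKh
      }
    }
    dH_prev <- dH_prev + dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
    glayers[[l]] <- list(Wq = crossprod(cc$H_in, dQ), bq = colSums(dQ),
                         Wk = crossprod(cc$H_in, dK), bk = colSums(dK),
                         Wv = crossprod(cc$H_in, dV), bv = colSums(dV),
                         Wo = gWo, bo = gbo, R = gR,
                         g1 = ln1b$dg, be1 = ln1b$db,
                         W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                         g2 = ln2b$dg, be2 = ln2b$db)
    dH <- dH_prev
  }
  list(W_in = crossprod(fw$X, dH), b_in = colSums(dH),
       layers = glayers, W_head = gW_head, b_head = gb_head)
}
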