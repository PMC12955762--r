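#' Aggregator network configuration
#'
#' The aggregator maps a variable-length sequence of residue embeddings to a
#' fixed-length structure embedding: a linear input projection, a stack of
#' transformer encoder layers *without positional encoding*, summation
#' pooling over the residue axis, and a stack of fully connected residual
#' blocks. Because no positional information enters the attention layers and
#' pooling is a sum, the output is invariant to any permutation of the input
#' rows — the property that makes assembly embeddings independent of chain
#' order.
#'
#' The default preset mirrors the production-scale architecture (6 encoder
#' layers, model width 1536, feedforward width 3072, ReLU, 12 residual
#' blocks, ~170M trainable parameters — audit it with [count_parameters()],
#' never by instantiating). [mini_aggregator_config()] is the desk-scale
#' preset used throughout the tests: it trains on one CPU in minutes.
#'
#' @param n_encoder_layers Number of transformer encoder layers.
#' @param d_model Model width (also the output embedding dimension).
#' @param d_ff Feedforward width inside each encoder layer.
#' @param n_residual_blocks Number of residual blocks after pooling (each:
#'   two affine `d_model` layers with ReLU and an identity skip).
#' @param d_in Residue-embedding input dimension.
#' @param n_heads Attention heads; default `d_model / 32`.
#' @return An object of class `aggregator_config`.
#' @export
aggregator_config <- function(n_encoder_layers = 6L, d_model = 1536L,
                              d_ff = 3072L, n_residual_blocks = 12L,
                              d_in = d_model,
                              n_heads = max(1L, d_model %/% 32L)) {
  if (any(c(n_encoder_layers, d_model, d_ff, n_residual_blocks, d_in,
            n_heads) < 1L)) {
    abort("all aggregator dimensions must be positive.")
  }
  if (d_model %% n_heads != 0L) abort("`d_model` must be divisible by `n_heads`.")
  structure(
    list(n_encoder_layers = as.integer(n_encoder_layers),
         d_model = as.integer(d_model), d_ff = as.integer(d_ff),
         n_residual_blocks = as.integer(n_residual_blocks),
         d_in = as.integer(d_in), n_heads = as.integer(n_heads)),
    class = "aggregator_config"
  )
}

#' @rdname aggregator_config
#' @export
mini_aggregator_config <- function() {
  aggregator_config(n_encoder_layers = 2L, d_model = 64L, d_ff = 128L,
                    n_residual_blocks = 3L, d_in = 32L, n_heads = 2L)
}

#' Trainable parameter count of an aggregator configuration
#'
#' Computed analytically from the dimensions: input projection
#' `d_in*d + d`; per encoder layer `4*(d^2 + d)` (Q/K/V/output projections)
#' plus `2*d*ff + ff + d` (feedforward) plus `4*d` (two layer norms); per
#' residual block `2*(d^2 + d)`.
#'
#' @param cfg An [aggregator_config()].
#' @return Integer-valued double: number of trainable parameters.
#' @export
count_parameters <- function(cfg) {
  d <- as.numeric(cfg$d_model); ff <- as.numeric(cfg$d_ff)
  din <- as.numeric(cfg$d_in)
  proj <- din * d + d
  per_layer <- 4 * (d^2 + d) + (d * ff + ff) + (ff * d + d) + 4 * d
  per_block <- 2 * (d^2 + d)
  proj + cfg$n_encoder_layers * per_layer + cfg$n_residual_blocks * per_block
}

#' Initialise aggregator weights
#'
#' Gaussian fan-average (Glorot) initialisation for weight matrices, zero
#' biases, unit layer-norm gains.
#'
#' @param cfg An [aggregator_config()].
#' @param seed Integer seed.
#' @return Nested list of weight matrices/vectors (class `aggregator_weights`).
#' @export
init_aggregator_weights <- function(cfg, seed = 1L) {
  gl <- function(n_in, n_out) {
    matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
  }
  d <- cfg$d_model; ff <- cfg$d_ff
  withr::with_seed(seed, {
    w <- list(
      W_in = gl(cfg$d_in, d), b_in = numeric(d),
      layers = lapply(seq_len(cfg$n_encoder_layers), function(i) list(
        Wq = gl(d, d), bq = numeric(d),
        Wk = gl(d, d), bk = numeric(d),
        Wv = gl(d, d), bv = numeric(d),
        Wo = gl(d, d), bo = numeric(d),
        g1 = rep(1, d), beta1 = numeric(d),
        W1 = gl(d, ff), b1 = numeric(ff),
        W2 = gl(ff, d), b2 = numeric(d),
        g2 = rep(1, d), beta2 = numeric(d)
      )),
      blocks = lapply(seq_len(cfg$n_residual_blocks), function(i) list(
        A1 = gl(d, d), a1 = numeric(d),
        A2 = gl(d, d), a2 = numeric(d)
      ))
    )
    class(w) <- "aggregator_weights"
    w
  })
}

layernorm_fwd <- function(U, g, b, eps = 1e-5) {
  mu <- rowMeans(U)
  Uc <- U - mu
  sig <- sqrt(rowMeans(Uc^2) + eps)
  xhat <- Uc / sig
  list(Y = sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+"), xhat = xhat, sig = sig)
}

layernorm_bwd <- function(dY, g, xhat, sig) {
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  list(dU = (dxhat - m1 - xhat * m2) / sig, dg = dg, db = db)
}

#' Run the aggregator forward pass on a raw embedding matrix
#'
#' Lower-level entry point behind [aggregate()]: maps an L x `d_in` matrix of
#' residue embeddings to the pooled output vector. `keep_cache = TRUE`
#' additionally returns the intermediate activations needed by the analytic
#' backward pass during training.
#'
#' @param X Numeric L x `d_in` matrix.
#' @param w Weights from [init_aggregator_weights()].
#' @param cfg The matching [aggregator_config()].
#' @param keep_cache Retain intermediate activations.
#' @return List with `out` (length `d_model` vector) and `cache`.
#' @export
aggregator_forward <- function(X, w, cfg, keep_cache = FALSE) {
  L <- nrow(X)
  dh <- cfg$d_model %/% cfg$n_heads
  H <- sweep(X %*% w$W_in, 2L, w$b_in, "+")
  caches <- if (keep_cache) vector("list", cfg$n_encoder_layers)
  for (li in seq_len(cfg$n_encoder_layers)) {
    lw <- w$layers[[li]]
    Hin <- H
    Q <- sweep(Hin %*% lw$Wq, 2L, lw$bq, "+")
    K <- sweep(Hin %*% lw$Wk, 2L, lw$bk, "+")
    V <- sweep(Hin %*% lw$Wv, 2L, lw$bv, "+")
    Ocat <- matrix(0, L, cfg$d_model)
    A_list <- vector("list", cfg$n_heads)
    for (h in seq_len(cfg$n_heads)) {
      idx <- seq.int((h - 1L) * dh + 1L, h * dh)
      S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
      S <- S - apply(S, 1L, max)
      E <- exp(S)
      A <- E / rowSums(E)
      Ocat[, idx] <- A %*% V[, idx, drop = FALSE]
      if (keep_cache) A_list[[h]] <- A
    }
    O <- sweep(Ocat %*% lw$Wo, 2L, lw$bo, "+")
    U1 <- Hin + O
    ln1 <- layernorm_fwd(U1, lw$g1, lw$beta1)
    H1 <- ln1$Y
    Z <- sweep(H1 %*% lw$W1, 2L, lw$b1, "+")
    Rl <- pmax(Z, 0)
    Ff <- sweep(Rl %*% lw$W2, 2L, lw$b2, "+")
    U2 <- H1 + Ff
    ln2 <- layernorm_fwd(U2, lw$g2, lw$beta2)
    H <- ln2$Y
    if (keep_cache) {
      caches[[li]] <- list(Hin = Hin, Q = Q, K = K, V = V, A = A_list,
                           Ocat = Ocat, ln1 = ln1, H1 = H1, Z = Z, Rl = Rl,
                           ln2 = ln2)
    }
  }
  s <- colSums(H)
  block_cache <- if (keep_cache) vector("list", cfg$n_residual_blocks)
  for (bi in seq_len(cfg$n_residual_blocks)) {
    bw <- w$blocks[[bi]]
    z1 <- drop(s %*% bw$A1) + bw$a1
    r <- pmax(z1, 0)
    if (keep_cache) block_cache[[bi]] <- list(s_in = s, z1 = z1, r = r)
    s <- s + drop(r %*% bw$A2) + bw$a2
  }
  list(out = s,
       cache = if (keep_cache) list(X = X, layers = caches,
                                    blocks = block_cache, L = L))
}

# analytic backward pass through the aggregator; `ds` is the gradient of the
# loss with respect to the pooled output vector
aggregator_backward <- function(ds, w, cfg, cache) {
  dh <- cfg$d_model %/% cfg$n_heads
  L <- cache$L
  g <- zero_like(w)
  s_grad <- ds
  for (bi in rev(seq_len(cfg$n_residual_blocks))) {
    bw <- w$blocks[[bi]]
    bc <- cache$blocks[[bi]]
    g$blocks[[bi]]$A2 <- outer(bc$r, s_grad)
    g$blocks[[bi]]$a2 <- s_grad
    dr <- drop(s_grad %*% t(bw$A2))
    dz1 <- dr * (bc$z1 > 0)
    g$blocks[[bi]]$A1 <- outer(bc$s_in, dz1)
    g$blocks[[bi]]$a1 <- dz1
    s_grad <- s_grad + drop(dz1 %*% t(bw$A1))
  }
  dH <- matrix(s_grad, L, cfg$d_model, byrow = TRUE)
  for (li in rev(seq_len(cfg$n_encoder_layers))) {
    lw <- w$layers[[li]]
    lc <- cache$layers[[li]]
    b2b <- layernorm_bwd(dH, lw$g2, lc$ln2$xhat, lc$ln2$sig)
    g$layers[[li]]$g2 <- b2b$dg
    g$layers[[li]]$beta2 <- b2b$db
    dU2 <- b2b$dU
    dH1 <- dU2
    g$layers[[li]]$W2 <- crossprod(lc$Rl, dU2)
    g$layers[[li]]$b2 <- colSums(dU2)
    dZ <- (dU2 %*% t(lw$W2)) * (lc$Z > 0)
    g$layers[[li]]$W1 <- crossprod(lc$H1, dZ)
    g$layers[[li]]$b1 <- colSums(dZ)
    dH1 <- dH1 + dZ %*% t(lw$W1)
    b1b <- layernorm_bwd(dH1, lw$g1, lc$ln1$xhat, lc$ln1$sig)
    g$layers[[li]]$g1 <- b1b$dg
    g$layers[[li]]$beta1 <- b1b$db
    dU1 <- b1b$dU
    dHin <- dU1
    dO <- dU1
    g$layers[[li]]$Wo <- crossprod(lc$Ocat, dO)
    g$layers[[li]]$bo <- colSums(dO)
    dOcat <- dO %*% t(lw$Wo)
    dQ <- matrix(0, L, cfg$d_model)
    dK <- matrix(0, L, cfg$d_model)
    dV <- matrix(0, L, cfg$d_model)
    for (h in seq_len(cfg$n_heads)) {
      idx <- seq.int((h - 1L) * dh + 1L, h * dh)
      A <- lc$A[[h]]
      dOh <- dOcat[, idx, drop = FALSE]
      dA <- dOh %*% t(lc$V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, idx] <- dS %*% lc$K[, idx, drop = FALSE] / sqrt(dh)
      dK[, idx] <- crossprod(dS, lc$Q[, idx, drop = FALSE]) / sqrt(dh)
    }
    g$layers[[li]]$Wq <- crossprod(lc$Hin, dQ)
    g$layers[[li]]$bq <- colSums(dQ)
    g$layers[[li]]$Wk <- crossprod(lc$Hin, dK)
    g$layers[[li]]$bk <- colSums(dK)
    g$layers[[li]]$Wv <- crossprod(lc$Hin, dV)
    g$layers[[li]]$bv <- colSums(dV)
    dHin <- dHin + dQ %*% t(lw$Wq) + dK %*% t(lw$Wk) + dV %*% t(lw$Wv)
    dH <- dHin
  }
  g$W_in <- crossprod(cache$X, dH)
  g$b_in <- colSums(dH)
  g
}

# structural helpers over nested weight lists -------------------------------

zero_like <- function(p) {
  if (is.numeric(p)) return(p * 0)
  out <- lapply(p, zero_like)
  attributes(out) <- attributes(p)
  out
}

params_add <- function(p, q) {
  if (is.numeric(p)) return(p + q)
  out <- mapply(params_add, p, q, SIMPLIFY = FALSE)
  attributes(out) <- attributes(p)
  out
}

params_scale <- function(p, a) {
  if (is.numeric(p)) return(p * a)
  out <- lapply(p, params_scale, a = a)
  attributes(out) <- attributes(p)
  out
}
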