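# Independent oracles, written straight-line against the definitions and kept
# free of the package's computational paths.

# Exhaustive TM-score maximization: every contiguous window (length >= 3,
# stride 1) is superposed with an inline base-R SVD fit and refined by the
# keep-close/re-superpose sweep; the maximum over all visited superpositions
# is reported. Tractable for short chains only.
oracle_tm_exhaustive <- function(q, t) {
  P <- q$ca_coords; Q <- t$ca_coords
  n <- min(nrow(P), nrow(Q))
  P <- P[seq_len(n), , drop = FALSE]; Q <- Q[seq_len(n), , drop = FALSE]
  Lq <- nrow(q$ca_coords); Lt <- nrow(t$ca_coords)
  d0_of <- function(L) max(0.5, 1.24 * sign(L - 15) * abs(L - 15)^(1 / 3) - 1.8)
  d0q <- d0_of(Lq); d0t <- d0_of(Lt); d0s <- d0_of(min(Lq, Lt))
  fit <- function(ii) {
    X <- P[ii, , drop = FALSE]; Y <- Q[ii, , drop = FALSE]
    cx <- colMeans(X); cy <- colMeans(Y)
    H <- t(sweep(X, 2, cx)) %*% sweep(Y, 2, cy)
    s <- svd(H)
    d <- sign(det(s$u) * det(s$v)); if (d == 0) d <- 1
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    list(R = R, tr = cy - drop(cx %*% R))
  }
  best_q <- -Inf; best_t <- -Inf
  consider <- function(f) {
    d2 <- rowSums((sweep(P %*% f$R, 2, f$tr, "+") - Q)^2)
    best_q <<- max(best_q, sum(1 / (1 + d2 / d0q^2)) / Lq)
    best_t <<- max(best_t, sum(1 / (1 + d2 / d0t^2)) / Lt)
    d2
  }
  for (len in 3:n) {
    for (s0 in 1:(n - len + 1)) {
      ii <- s0:(s0 + len - 1)
      f <- fit(ii)
      d2 <- consider(f)
      for (dc0 in d0s + c(0.5, 1.5, 2.5, 3.5)) {
        sel <- ii; dc <- dc0; d2c <- d2
        for (it in 1:30) {
          keep <- which(d2c < dc^2)
          while (length(keep) < 3) {
            dc <- dc + 0.5
            keep <- which(d2c < dc^2)
          }
          if (length(keep) == length(sel) && all(keep == sel)) break
          sel <- keep
          f <- fit(sel)
          d2c <- consider(f)
        }
      }
    }
  }
  list(tm_query = best_q, tm_target = best_t, tm_max = max(best_q, best_t))
}

# Straight-line re-implementation of the aggregator forward pass: explicit
# per-position/per-head loops, no shared code with aggregator_forward().
oracle_forward <- function(X, w, cfg) {
  L <- nrow(X); d <- cfg$d_model; dh <- d %/% cfg$n_heads
  ln <- function(x, g, b) {
    mu <- mean(x); v <- mean((x - mu)^2)
    ((x - mu) / sqrt(v + 1e-5)) * g + b
  }
  H <- matrix(0, L, d)
  for (i in seq_len(L)) H[i, ] <- drop(X[i, ] %*% w$W_in) + w$b_in
  for (lw in w$layers) {
    Q <- matrix(0, L, d); K <- matrix(0, L, d); V <- matrix(0, L, d)
    for (i in seq_len(L)) {
      Q[i, ] <- drop(H[i, ] %*% lw$Wq) + lw$bq
      K[i, ] <- drop(H[i, ] %*% lw$Wk) + lw$bk
      V[i, ] <- drop(H[i, ] %*% lw$Wv) + lw$bv
    }
    Ocat <- matrix(0, L, d)
    for (h in seq_len(cfg$n_heads)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      for (i in seq_len(L)) {
        logits <- numeric(L)
        for (j in seq_len(L)) {
          logits[j] <- sum(Q[i, idx] * K[j, idx]) / sqrt(dh)
        }
        a <- exp(logits - max(logits))
        a <- a / sum(a)
        for (j in seq_len(L)) {
          Ocat[i, idx] <- Ocat[i, idx] + a[j] * V[j, idx]
        }
      }
    }
    H1 <- matrix(0, L, d)
    for (i in seq_len(L)) {
      u1 <- H[i, ] + drop(Ocat[i, ] %*% lw$Wo) + lw$bo
      H1[i, ] <- ln(u1, lw$g1, lw$beta1)
    }
    for (i in seq_len(L)) {
      z <- pmax(drop(H1[i, ] %*% lw$W1) + lw$b1, 0)
      u2 <- H1[i, ] + drop(z %*% lw$W2) + lw$b2
      H[i, ] <- ln(u2, lw$g2, lw$beta2)
    }
  }
  s <- numeric(d)
  for (i in seq_len(L)) s <- s + H[i, ]
  for (bw in w$blocks) {
    r <- pmax(drop(s %*% bw$A1) + bw$a1, 0)
    s <- s + drop(r %*% bw$A2) + bw$a2
  }
  s
}

# brute-force cosine k-NN over raw (unnormalized) vectors
oracle_knn <- function(emb, v, k) {
  sims <- apply(emb, 1, function(r) {
    sum(r * v) / (sqrt(sum(r^2)) * sqrt(sum(v^2)))
  })
  ids <- rownames(emb)
  ord <- order(-sims, ids)
  ids[ord[seq_len(min(k, length(ids)))]]
}

# step-rule PR reference: walks distinct thresholds and recomputes counts
# from scratch at each one
oracle_pr_auprc <- function(scores, labels) {
  P <- sum(labels == "TP")
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  auc <- 0
  for (s in thr) {
    sel <- scores >= s
    tp <- sum(sel & labels == "TP")
    fp <- sum(sel & labels == "FP")
    precision <- tp / (tp + fp)
    recall <- tp / P
    auc <- auc + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  auc
}
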