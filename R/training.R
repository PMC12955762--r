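#' Round a TM-score to its training bin
#'
#' TM-scores are rounded to the first decimal (round-half-up), giving the 11
#' regression targets `{0.0, 0.1, ..., 1.0}`.
#'
#' @param tm Numeric in \[0, 1\].
#' @return Binned value(s) in `{0.0, ..., 1.0}`.
#' @export
bin_tm <- function(tm) {
  if (any(tm < 0 | tm > 1)) abort("`tm` must lie in [0, 1].")
  # the 1e-9 guard keeps decimal halves (0.05, 0.15, ...) rounding up even
  # when their binary representation falls a hair below the half
  floor(tm * 10 + 0.5 + 1e-9) / 10
}

#' Sample a TM-bin-uniform batch of pairs
#'
#' Counters the heavy skew of TM-scores toward low values: pairs are drawn
#' with replacement so every bin present in the pool contributes equally.
#' `"quota"` mode assigns each non-empty bin an exact share of the batch
#' (remainders spread over randomly chosen bins); `"multinomial"` draws each
#' element's bin independently and uniformly.
#'
#' @param pool Data frame of pairs with a `bin` column (from [bin_tm()]).
#' @param batch_size Number of pairs to draw, >= 1.
#' @param mode `"quota"` or `"multinomial"`.
#' @return Tibble of `batch_size` sampled rows.
#' @export
sample_uniform_batch <- function(pool, batch_size,
                                 mode = c("quota", "multinomial")) {
  mode <- match.arg(mode)
  if (!nrow(pool)) abort("`pool` is empty.")
  if (batch_size < 1L) abort("`batch_size` must be >= 1.")
  pool <- tibble::as_tibble(pool)
  if (!"bin" %in% names(pool)) abort("`pool` needs a `bin` column.")
  by_bin <- split(seq_len(nrow(pool)), pool$bin)
  bins <- names(by_bin)
  nb <- length(bins)
  counts <- if (mode == "quota") {
    base <- batch_size %/% nb
    extra <- batch_size - base * nb
    cnt <- rep(base, nb)
    if (extra > 0L) {
      lucky <- sample.int(nb, extra)
      cnt[lucky] <- cnt[lucky] + 1L
    }
    cnt
  } else {
    drawn <- sample.int(nb, batch_size, replace = TRUE)
    tabulate(drawn, nbins = nb)
  }
  idx <- unlist(lapply(seq_len(nb), function(i) {
    if (counts[i] == 0L) return(integer(0))
    members <- by_bin[[i]]
    members[sample.int(length(members), counts[i], replace = TRUE)]
  }), use.names = FALSE)
  pool[idx[sample.int(length(idx))], , drop = FALSE]
}

#' Squared-error pair loss
#'
#' `(cosine - tm_bin)^2`; the training objective of the twin network (batch
#' loss is the mean over pairs).
#'
#' @param cosine Cosine similarity in \[-1, 1\].
#' @param tm_bin Binned TM-score target.
#' @return Loss value(s).
#' @export
pair_loss <- function(cosine, tm_bin) {
  if (any(cosine < -1 - 1e-12 | cosine > 1 + 1e-12)) {
    abort("`cosine` must lie in [-1, 1].")
  }
  (cosine - tm_bin)^2
}

#' Learning rate schedule: linear warmup then cosine decay
#'
#' Ramps linearly from 0 to the peak over the warmup steps, then decays along
#' a cosine from peak to the minimum rate at the final step.
#'
#' @param step Current step, `0 <= step <= total_steps`.
#' @param total_steps Total optimisation steps.
#' @param cfg A [training_config()] (uses `peak_lr`, `min_lr`,
#'   `warmup_epochs`, `epochs`).
#' @return Learning rate.
#' @export
lr_at <- function(step, total_steps, cfg) {
  if (any(step < 0 | step > total_steps)) {
    abort("`step` must lie in [0, total_steps].")
  }
  warmup <- total_steps * cfg$warmup_epochs / cfg$epochs
  ifelse(step <= warmup,
         cfg$peak_lr * step / max(warmup, 1),
         cfg$min_lr + 0.5 * (cfg$peak_lr - cfg$min_lr) *
           (1 + cos(pi * (step - warmup) / max(total_steps - warmup, 1))))
}

#' Training configuration
#'
#' @param batch_size Pairs per optimisation step.
#' @param pairs_per_epoch Pairs sampled per epoch (desk-scale default; the
#'   production-scale analogue is 320,000).
#' @param epochs Total epochs; `warmup_epochs` must be smaller.
#' @param peak_lr,min_lr Learning-rate schedule bounds (`min_lr` defaults to
#'   `peak_lr / 100`).
#' @param warmup_epochs Linear warmup length (default 2).
#' @param adam_beta1,adam_beta2,adam_eps Adam moments/epsilon.
#' @param validation_fraction Fraction of pairs held out, stratified by TM
#'   bin, in (0, 0.5).
#' @param regress_binned Regress the binned TM (`TRUE`, default) or the raw
#'   `tm_max` (ablation).
#' @param seed Master seed: sampling, split and initialisation all derive
#'   from it, so retraining reproduces the history exactly.
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 32L, pairs_per_epoch = 512L,
                            epochs = 15L, peak_lr = 2e-3,
                            min_lr = peak_lr / 100, warmup_epochs = 2L,
                            adam_beta1 = 0.9, adam_beta2 = 0.999,
                            adam_eps = 1e-8, validation_fraction = 0.1,
                            regress_binned = TRUE, seed = 42L) {
  if (warmup_epochs >= epochs) abort("`warmup_epochs` must be < `epochs`.")
  if (validation_fraction <= 0 || validation_fraction >= 0.5) {
    abort("`validation_fraction` must be in (0, 0.5).")
  }
  structure(
    list(batch_size = as.integer(batch_size),
         pairs_per_epoch = as.integer(pairs_per_epoch),
         epochs = as.integer(epochs), peak_lr = peak_lr, min_lr = min_lr,
         warmup_epochs = as.integer(warmup_epochs),
         adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
         adam_eps = adam_eps, validation_fraction = validation_fraction,
         regress_binned = isTRUE(regress_binned), seed = as.integer(seed)),
    class = "training_config"
  )
}

# gradient of the pair loss with respect to both embedding vectors
cosine_loss_grad <- function(u, v, target) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  cosv <- sum(u * v) / (nu * nv)
  err <- cosv - target
  dcos <- 2 * err
  list(loss = err^2,
       du = dcos * (v / (nu * nv) - cosv * u / nu^2),
       dv = dcos * (u / (nu * nv) - cosv * v / nv^2),
       cosine = cosv)
}

#' Train the twin embedding network
#'
#' Both structures of a pair pass through the same aggregator weights (twin
#' network); the mean squared error between the embeddings' cosine
#' similarity and the (binned) maximum TM-score is minimised with Adam under
#' a warmup + cosine-decay schedule, drawing TM-bin-uniform batches. The
#' residue encoder is frozen; residue embeddings are precomputed once. After
#' every epoch the validation AUPRC (positives: `tm_max >= 0.5`, score:
#' cosine) is computed and the best-epoch weights are retained.
#'
#' @param structures Named list of [chain_structure()] covering all pair ids.
#' @param pairs Data frame `id1`, `id2`, `tm_max` (e.g. from
#'   [benchmark_pairs()]).
#' @param encoder_cfg An [encoder_config()].
#' @param aggregator_cfg An [aggregator_config()]; its `d_in` must match the
#'   encoder.
#' @param training_cfg A [training_config()].
#' @param checkpoint_dir Optional directory; if given, a checkpoint file is
#'   written per epoch plus `history.tsv`.
#' @return An object of class `foldvec_model`: list with `weights` (best
#'   epoch), `final_weights`, `history` tibble (epoch, loss, val_auprc, lr),
#'   `best_epoch`, configs and the validation pair table.
#' @export
train_model <- function(structures, pairs, encoder_cfg = encoder_config(),
                        aggregator_cfg = mini_aggregator_config(),
                        training_cfg = training_config(),
                        checkpoint_dir = NULL) {
  cfg <- training_cfg
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("id1", "id2", "tm_max") %in% names(pairs))) {
    abort("`pairs` needs columns id1, id2, tm_max.")
  }
  pairs$bin <- bin_tm(pairs$tm_max)
  pairs$target <- if (cfg$regress_binned) pairs$bin else pairs$tm_max

  withr::with_seed(cfg$seed, {
    # residue encoder is frozen: encode every structure once
    enc <- lapply(structures, function(ch) {
      encode_residues(ch, encoder_cfg)$embeddings
    })

    # validation split by pair, stratified by bin
    val_idx <- unlist(lapply(split(seq_len(nrow(pairs)), pairs$bin),
                             function(ii) {
      n_val <- max(1L, round(length(ii) * cfg$validation_fraction))
      if (length(ii) == 1L) return(integer(0))
      sample(ii, min(n_val, length(ii) - 1L))
    }), use.names = FALSE)
    val_pairs <- pairs[val_idx, , drop = FALSE]
    train_pairs <- pairs[setdiff(seq_len(nrow(pairs)), val_idx), , drop = FALSE]
    val_pos <- val_pairs$tm_max >= 0.5
    if (!any(val_pos) || all(val_pos)) {
      abort("validation split needs both positive (tm_max >= 0.5) and negative pairs.")
    }

    w <- init_aggregator_weights(aggregator_cfg, seed = sample.int(10^6, 1L))
    m_state <- zero_like(w); v_state <- zero_like(w)
    steps_per_epoch <- max(1L, ceiling(cfg$pairs_per_epoch / cfg$batch_size))
    total_steps <- cfg$epochs * steps_per_epoch
    b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2; eps <- cfg$adam_eps
    t_step <- 0L
    history <- vector("list", cfg$epochs)
    best <- list(epoch = 0L, auprc = -Inf, weights = NULL)
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    }

    adam_update <- function(p, g, m, v, lr, t) {
      if (is.numeric(p)) {
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        mh <- m / (1 - b1^t)
        vh <- v / (1 - b2^t)
        return(list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v))
      }
      outs <- mapply(adam_update, p, g, m, v,
                     MoreArgs = list(lr = lr, t = t), SIMPLIFY = FALSE)
      res <- list(p = lapply(outs, `[[`, "p"),
                  m = lapply(outs, `[[`, "m"),
                  v = lapply(outs, `[[`, "v"))
      attributes(res$p) <- attributes(p)
      res
    }

    for (epoch in seq_len(cfg$epochs)) {
      epoch_losses <- numeric(steps_per_epoch)
      lr_now <- NA_real_
      for (st in seq_len(steps_per_epoch)) {
        t_step <- t_step + 1L
        lr_now <- lr_at(t_step, total_steps, cfg)
        batch <- sample_uniform_batch(train_pairs, cfg$batch_size)
        grad <- zero_like(w)
        loss_sum <- 0
        for (bi in seq_len(nrow(batch))) {
          f1 <- aggregator_forward(enc[[batch$id1[bi]]], w, aggregator_cfg,
                                   keep_cache = TRUE)
          f2 <- aggregator_forward(enc[[batch$id2[bi]]], w, aggregator_cfg,
                                   keep_cache = TRUE)
          cl <- cosine_loss_grad(f1$out, f2$out, batch$target[bi])
          loss_sum <- loss_sum + cl$loss
          grad <- params_add(grad, aggregator_backward(cl$du, w, aggregator_cfg,
                                                       f1$cache))
          grad <- params_add(grad, aggregator_backward(cl$dv, w, aggregator_cfg,
                                                       f2$cache))
        }
        grad <- params_scale(grad, 1 / nrow(batch))
        upd <- adam_update(w, grad, m_state, v_state, lr_now, t_step)
        w <- upd$p; m_state <- upd$m; v_state <- upd$v
        class(w) <- "aggregator_weights"
        epoch_losses[st] <- loss_sum / nrow(batch)
      }

      val_cos <- vapply(seq_len(nrow(val_pairs)), function(i) {
        cosine_similarity(
          aggregator_forward(enc[[val_pairs$id1[i]]], w, aggregator_cfg)$out,
          aggregator_forward(enc[[val_pairs$id2[i]]], w, aggregator_cfg)$out)
      }, numeric(1))
      auprc <- pr_curve(val_cos, ifelse(val_pos, "TP", "FP"))$auprc

      history[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = mean(epoch_losses), val_auprc = auprc,
        lr = lr_now)
      if (auprc > best$auprc) {
        best <- list(epoch = epoch, auprc = auprc, weights = w)
      }
      if (!is.null(checkpoint_dir)) {
        save_checkpoint(w, encoder_cfg, aggregator_cfg,
                        file.path(checkpoint_dir,
                                  sprintf("epoch_%03d.rds", epoch)),
                        extra = list(epoch = epoch, val_auprc = auprc))
      }
    }

    history <- dplyr::bind_rows(history)
    if (!is.null(checkpoint_dir)) {
      readr::write_tsv(history, file.path(checkpoint_dir, "history.tsv"))
    }
    structure(
      list(weights = best$weights, final_weights = w, history = history,
           best_epoch = best$epoch, encoder_cfg = encoder_cfg,
           aggregator_cfg = aggregator_cfg, training_cfg = cfg,
           val_pairs = val_pairs, train_pairs = train_pairs),
      class = "foldvec_model")
  })
}

#' @export
print.foldvec_model <- function(x, ...) {
  cat(sprintf(
    "<foldvec_model> %d epochs; best epoch %d (val AUPRC %.3f); d_out = %d\n",
    nrow(x$history), x$best_epoch,
    x$history$val_auprc[x$best_epoch], x$aggregator_cfg$d_model))
  invisible(x)
}

#' @rdname train_model
#' @param x A `foldvec_model`.
#' @param ... Unused.
#' @export
tidy.foldvec_model <- function(x, ...) x$history

#' @rdname train_model
#' @export
glance.foldvec_model <- function(x, ...) {
  tibble::tibble(
    best_epoch = x$best_epoch,
    best_val_auprc = x$history$val_auprc[x$best_epoch],
    first_epoch_loss = x$history$loss[1L],
    final_epoch_loss = x$history$loss[nrow(x$history)],
    n_train_pairs = nrow(x$train_pairs),
    n_val_pairs = nrow(x$val_pairs),
    parameters = count_parameters(x$aggregator_cfg))
}

#' @rdname train_model
#' @param object A `foldvec_model`.
#' @export
autoplot.foldvec_model <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("loss", "val_auprc"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}
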