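test_that("TM bins round half up to one decimal", {
  expect_equal(bin_tm(0.84), 0.8)
  expect_equal(bin_tm(0.05), 0.1)
  expect_equal(bin_tm(1.0), 1.0)
  expect_equal(bin_tm(0.0), 0.0)
  expect_equal(bin_tm(c(0.14999, 0.15, 0.951)), c(0.1, 0.2, 1.0))
  expect_error(bin_tm(1.2), "\\[0, 1\\]")
})

test_that("quota sampling fills bins exactly and redistributes absences", {
  pool <- tibble::tibble(id1 = "a", id2 = "b",
                         bin = rep(seq(0, 1, 0.1), each = 3))
  withr::local_seed(71)
  batch <- sample_uniform_batch(pool, 110)
  expect_equal(as.integer(table(batch$bin)), rep(10L, 11L))
  pool2 <- tibble::tibble(id1 = "a", id2 = "b", bin = rep(c(0.2, 0.8), 5))
  batch2 <- sample_uniform_batch(pool2, 100)
  expect_equal(as.integer(table(batch2$bin)), c(50L, 50L))
  expect_error(sample_uniform_batch(pool2[0, ], 10), "empty")
})

test_that("multinomial sampling is uniform over available bins", {
  pool <- tibble::tibble(id1 = "a", id2 = "b",
                         bin = rep(seq(0, 1, 0.1), times = c(1:11)))
  withr::local_seed(72)
  batch <- sample_uniform_batch(pool, 10000, mode = "multinomial")
  counts <- table(factor(batch$bin, levels = seq(0, 1, 0.1)))
  chisq <- sum((counts - 10000 / 11)^2 / (10000 / 11))
  p <- stats::pchisq(chisq, df = 10, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("pair loss and its cosine gradient are exact", {
  expect_equal(pair_loss(0.8, 0.8), 0)
  expect_equal(pair_loss(0.0, 1.0), 1)
  expect_equal(pair_loss(-1.0, 0.1), 1.21)
  expect_error(pair_loss(1.5, 0.5), "\\[-1, 1\\]")
  # analytic d(loss)/d(cosine) = 2 (cos - y) vs finite differences
  for (cosv in c(-0.9, -0.2, 0.3, 0.7)) {
    y <- 0.4
    eps <- 1e-6
    num <- (pair_loss(cosv + eps, y) - pair_loss(cosv - eps, y)) / (2 * eps)
    expect_lt(abs(num - 2 * (cosv - y)), 1e-5)
  }
})

test_that("twin gradients through the embeddings match finite differences", {
  withr::local_seed(73)
  u <- rnorm(8); v <- rnorm(8); y <- 0.6
  g <- foldvec:::cosine_loss_grad(u, v, y)
  f <- function(u, v) (sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2))) - y)^2
  eps <- 1e-6
  for (j in 1:8) {
    up <- u; up[j] <- up[j] + eps
    um <- u; um[j] <- um[j] - eps
    expect_lt(abs((f(up, v) - f(um, v)) / (2 * eps) - g$du[j]), 1e-6)
    vp <- v; vp[j] <- vp[j] + eps
    vm <- v; vm[j] <- vm[j] - eps
    expect_lt(abs((f(u, vp) - f(u, vm)) / (2 * eps) - g$dv[j]), 1e-6)
  }
})

test_that("aggregator backprop matches finite differences", {
  cfg <- aggregator_config(n_encoder_layers = 1L, d_model = 16L, d_ff = 24L,
                           n_residual_blocks = 2L, d_in = 8L, n_heads = 2L)
  w <- init_aggregator_weights(cfg, seed = 4)
  withr::local_seed(74)
  X <- matrix(rnorm(5 * 8), 5, 8)
  v <- rnorm(16)
  fwd <- aggregator_forward(X, w, cfg, keep_cache = TRUE)
  g <- foldvec:::aggregator_backward(v, w, cfg, fwd$cache)
  objective <- function(w) sum(v * aggregator_forward(X, w, cfg)$out)
  eps <- 1e-6
  probe <- list(
    list(get = function(w) w$W_in, set = function(w, p) { w$W_in <- p; w }, i = 5L),
    list(get = function(w) w$layers[[1]]$Wq,
         set = function(w, p) { w$layers[[1]]$Wq <- p; w }, i = 17L),
    list(get = function(w) w$layers[[1]]$Wo,
         set = function(w, p) { w$layers[[1]]$Wo <- p; w }, i = 100L),
    list(get = function(w) w$layers[[1]]$W1,
         set = function(w, p) { w$layers[[1]]$W1 <- p; w }, i = 200L),
    list(get = function(w) w$layers[[1]]$g2,
         set = function(w, p) { w$layers[[1]]$g2 <- p; w }, i = 3L),
    list(get = function(w) w$blocks[[2]]$A2,
         set = function(w, p) { w$blocks[[2]]$A2 <- p; w }, i = 33L))
  for (pr in probe) {
    p <- pr$get(w)
    p1 <- p; p1[pr$i] <- p[pr$i] + eps
    p2 <- p; p2[pr$i] <- p[pr$i] - eps
    num <- (objective(pr$set(w, p1)) - objective(pr$set(w, p2))) / (2 * eps)
    expect_lt(abs(num - pr$get(g)[pr$i]), 1e-5)
  }
})

test_that("the twin loss is symmetric in its branches", {
  withr::local_seed(75)
  for (i in 1:10) {
    u <- rnorm(12); v <- rnorm(12); y <- runif(1)
    a <- foldvec:::cosine_loss_grad(u, v, y)
    b <- foldvec:::cosine_loss_grad(v, u, y)
    expect_lt(abs(a$loss - b$loss), 1e-6)
    expect_lt(max(abs(a$du - b$dv)), 1e-10)
  }
})

test_that("the learning-rate schedule warms up then cosine decays", {
  cfg <- training_config(epochs = 10L, warmup_epochs = 2L, peak_lr = 1e-3)
  total <- 100
  expect_equal(lr_at(0, total, cfg), 0)
  expect_equal(lr_at(20, total, cfg), cfg$peak_lr)
  expect_equal(lr_at(total, total, cfg), cfg$min_lr)
  expect_equal(lr_at(10, total, cfg), cfg$peak_lr / 2)
  mid <- lr_at(60, total, cfg)
  expect_equal(mid, cfg$min_lr + 0.5 * (cfg$peak_lr - cfg$min_lr) *
                 (1 + cos(pi * 0.5)))
  expect_error(lr_at(101, total, cfg))
  expect_error(training_config(epochs = 2L, warmup_epochs = 2L), "warmup")
})

test_that("training improves the loss and recovers TM structure", {
  model <- shared_model()
  h <- model$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_equal(model$best_epoch, which.max(h$val_auprc))
  # held-out cosine tracks the oracle tm_max
  emb <- embed_structures(shared_benchmark()$structures, model$encoder_cfg,
                          model$aggregator_cfg, model$weights)
  vp <- score_pairs_cosine(model$val_pairs, emb)
  expect_gte(cor(vp$score, vp$tm_max, method = "spearman"), 0.6)
})

test_that("training is deterministic under its master seed", {
  bench <- shared_benchmark()
  ids <- names(bench$structures)[1:12]
  pr <- shared_pairs()
  pr <- pr[pr$id1 %in% ids & pr$id2 %in% ids, ]
  cfg <- training_config(batch_size = 8L, pairs_per_epoch = 24L, epochs = 3L,
                         warmup_epochs = 1L, validation_fraction = 0.2,
                         seed = 99L)
  acfg <- aggregator_config(n_encoder_layers = 1L, d_model = 32L, d_ff = 48L,
                            n_residual_blocks = 2L, d_in = 32L, n_heads = 1L)
  m1 <- train_model(bench$structures[ids], pr, aggregator_cfg = acfg,
                    training_cfg = cfg)
  m2 <- train_model(bench$structures[ids], pr, aggregator_cfg = acfg,
                    training_cfg = cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
})

test_that("training refuses a one-sided validation split", {
  bench <- shared_benchmark()
  pr <- shared_pairs()
  low <- pr[pr$tm_max < 0.4, ][1:40, ]
  expect_error(
    train_model(bench$structures, low,
                training_cfg = training_config(epochs = 3L, warmup_epochs = 1L,
                                               pairs_per_epoch = 16L,
                                               batch_size = 8L)),
    "positive")
})

test_that("model accessors expose the history", {
  model <- shared_model()
  expect_identical(tidy(model), model$history)
  g <- glance(model)
  expect_equal(g$best_epoch, model$best_epoch)
  expect_equal(g$n_val_pairs, nrow(model$val_pairs))
  expect_s3_class(autoplot(model), "ggplot")
})
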