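test_that("the geometric encoder is rigid-motion invariant but order sensitive", {
  ch <- demo_fold()
  cfg <- encoder_config()
  e <- encode_residues(ch, cfg)
  withr::local_seed(61)
  moved <- rigid_move(ch, random_proper_rotation(), rnorm(3, 0, 30))
  e2 <- encode_residues(moved, cfg)
  expect_lt(max(abs(e$embeddings - e2$embeddings)), 1e-5)

  # an asymmetric trace read backwards encodes differently
  asym <- chain_structure("A", rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.4, 1, 0),
                                     c(10, 3, 1), c(12, 6, 3)),
                          sequence = "ACDEF")
  rev_ch <- chain_structure("A", asym$ca_coords[5:1, ],
                            sequence = "FEDCA")
  er <- encode_residues(rev_ch, cfg)$embeddings[5:1, ]
  expect_gt(max(abs(encode_residues(asym, cfg)$embeddings - er)), 1e-4)

  one <- chain_structure("A", matrix(c(0, 0, 0), 1, 3), "G")
  eo <- encode_residues(one, cfg)
  expect_equal(dim(eo$embeddings), c(1L, cfg$d_in))
  expect_true(all(is.finite(eo$embeddings)))
})

test_that("aggregation is permutation invariant and length sensitive", {
  cfg <- mini_aggregator_config()
  w <- init_aggregator_weights(cfg, seed = 7)
  withr::local_seed(62)
  for (i in 1:50) {
    X <- matrix(rnorm(30 * cfg$d_in), 30, cfg$d_in)
    res <- residue_embedding_sequence(X, 30L, "x")
    out <- aggregate(res, cfg, w)$vector
    perm <- sample(30)
    out_p <- aggregate(residue_embedding_sequence(X[perm, ], 30L, "x"),
                       cfg, w)$vector
    expect_lt(max(abs(out - out_p)), 1e-4)
  }
  # duplicated rows change the sum-pooled embedding (sum, not mean)
  X <- matrix(rnorm(10 * cfg$d_in), 10, cfg$d_in)
  a <- aggregate(residue_embedding_sequence(X, 10L, "x"), cfg, w)$vector
  b <- aggregate(residue_embedding_sequence(X[rep(1:10, each = 2), ], 20L, "x"),
                 cfg, w)$vector
  expect_gt(max(abs(a - b)), 1e-3)
  expect_error(aggregate(residue_embedding_sequence(X[, 1:10], 10L, "x"),
                         cfg, w), "does not match")
})

test_that("the forward pass matches an independent re-implementation", {
  withr::local_seed(63)
  for (i in 1:20) {
    cfg <- aggregator_config(
      n_encoder_layers = sample(1:2, 1), d_model = 32L, d_ff = 48L,
      n_residual_blocks = sample(1:3, 1), d_in = 16L, n_heads = 2L)
    w <- init_aggregator_weights(cfg, seed = 100 + i)
    L <- sample(1:12, 1)
    X <- matrix(rnorm(L * cfg$d_in), L, cfg$d_in)
    got <- aggregator_forward(X, w, cfg)$out
    want <- oracle_forward(X, w, cfg)
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("single-row inputs reduce to the residual head on the encoded row", {
  cfg <- mini_aggregator_config()
  w <- init_aggregator_weights(cfg, seed = 8)
  X <- matrix(rnorm(cfg$d_in), 1, cfg$d_in)
  got <- aggregate(residue_embedding_sequence(X, 1L, "x"), cfg, w)$vector
  expect_equal(got, oracle_forward(X, w, cfg), tolerance = 1e-10)
})

test_that("chain embeddings are rigid-motion invariant", {
  ch <- demo_fold()
  ecfg <- encoder_config()
  acfg <- mini_aggregator_config()
  w <- init_aggregator_weights(acfg, seed = 9)
  e1 <- embed_chain(ch, ecfg, acfg, w)
  expect_equal(cosine_similarity(e1, embed_chain(ch, ecfg, acfg, w)), 1.0)
  withr::local_seed(64)
  moved <- rigid_move(ch, random_proper_rotation(), rnorm(3, 0, 25))
  e2 <- embed_chain(moved, ecfg, acfg, w)
  expect_gte(cosine_similarity(e1, e2), 1 - 1e-6)
})

test_that("assembly embeddings are chain-order invariant and degenerate in arrangement", {
  ch <- demo_fold()
  ecfg <- encoder_config()
  acfg <- mini_aggregator_config()
  w <- init_aggregator_weights(acfg, seed = 10)
  asm <- generate_assembly(ch, 4, "cyclic", radius = 30)
  base <- embed_assembly(asm, ecfg, acfg, w)$vector
  perms <- list(c(2, 1, 3, 4), c(4, 3, 2, 1), c(3, 1, 4, 2), c(2, 3, 4, 1))
  for (p in perms) {
    reord <- assembly_structure("r", unname(asm$chains[p]))
    expect_lt(max(abs(embed_assembly(reord, ecfg, acfg, w)$vector - base)),
              1e-4)
  }
  # identical subunits, different quaternary arrangement: same embedding
  a20 <- generate_assembly(ch, 3, "cyclic", radius = 20)
  a45 <- generate_assembly(ch, 3, "cyclic", radius = 45)
  expect_lt(assembly_tm(a20, a45)$tm_max, 0.5)
  d <- max(abs(embed_assembly(a20, ecfg, acfg, w)$vector -
                 embed_assembly(a45, ecfg, acfg, w)$vector))
  expect_lt(d, 1e-8)
  # single-chain assembly equals the chain embedding
  solo <- assembly_structure("s", list(ch))
  expect_equal(embed_assembly(solo, ecfg, acfg, w)$vector,
               embed_chain(ch, ecfg, acfg, w)$vector)
})

test_that("similarity is clamped cosine", {
  a <- structure_embedding(c(1, 0), id = "a")
  expect_equal(similarity(a, a), 1.0)
  expect_equal(similarity(a, structure_embedding(c(0, 1))), 0.0)
  anti <- structure_embedding(c(-1, 0))
  expect_equal(cosine_similarity(a, anti), -1.0)
  expect_equal(similarity(a, anti), 0.0)
  expect_error(cosine_similarity(a$vector, c(0, 0)), "zero-norm")
  expect_error(cosine_similarity(a, structure_embedding(c(1, 0, 0))),
               "equal dimension")
})

test_that("the mean-pooling baseline is a parameter-free row mean", {
  v <- rnorm(16)
  X <- matrix(rep(v, each = 12), 12, 16)
  res <- residue_embedding_sequence(X, 12L, "x")
  expect_equal(baseline_mean_embed(res)$vector, v)
  Y <- matrix(rnorm(12 * 16), 12, 16)
  res_y <- residue_embedding_sequence(Y, 12L, "x")
  expect_equal(baseline_mean_embed(res_y)$vector,
               baseline_mean_embed(
                 residue_embedding_sequence(Y[sample(12), ], 12L, "x"))$vector)
})

test_that("the production preset stays near its 170M parameter budget", {
  n <- count_parameters(aggregator_config())
  expect_lt(abs(n - 170e6) / 170e6, 0.10)
  # analytic count agrees with an instantiated mini network
  cfg <- mini_aggregator_config()
  w <- init_aggregator_weights(cfg, seed = 1)
  n_inst <- sum(rapply(unclass(w), length, how = "unlist"))
  expect_equal(count_parameters(cfg), n_inst)
})

test_that("residue embedding files round trip", {
  ch <- demo_fold()
  res <- encode_residues(ch, encoder_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_residue_embeddings(res, path)
  back <- read_residue_embeddings(path)
  expect_equal(unname(back$embeddings), unname(res$embeddings),
               tolerance = 1e-12)
  expect_equal(back$boundaries, res$boundaries)
})

test_that("checkpoints embed configs and detect corruption", {
  cfg <- mini_aggregator_config()
  w <- init_aggregator_weights(cfg, seed = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(w, encoder_config(), cfg, path)
  back <- load_checkpoint(path)
  expect_equal(back$weights, w)
  expect_equal(back$aggregator_cfg, cfg)
  bad <- readRDS(path)
  bad$weights$b_in[1] <- bad$weights$b_in[1] + 1
  saveRDS(bad, path)
  expect_error(load_checkpoint(path), "hash")
})
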