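test_that("kabsch handles identity, exact recovery and mirrors", {
  withr::local_seed(1)
  X <- matrix(rnorm(30), 10, 3)
  sp <- kabsch(X, X)
  expect_lt(sp$rmsd, 1e-12)
  expect_lt(max(abs(sp$rotation - diag(3))), 1e-8)

  R0 <- random_proper_rotation()
  Y <- sweep(X %*% R0, 2, c(3, -1, 2), "+")
  sp <- kabsch(X, Y)
  expect_lt(max(abs(sp$rotation - R0)), 1e-6)
  expect_lt(sp$rmsd, 1e-6)

  # chiral 4-point set vs its mirror image: fit imperfect, rotation proper
  Xc <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  Ym <- Xc %*% diag(c(1, 1, -1))
  spm <- kabsch(Xc, Ym)
  expect_gt(spm$rmsd, 0.1)
  expect_equal(det(spm$rotation), 1, tolerance = 1e-8)
  # brute force over many proper rotations cannot beat the Kabsch fit
  rmsd_at <- function(R) {
    Xr <- sweep(Xc, 2, colMeans(Xc)) %*% R
    Yc <- sweep(Ym, 2, colMeans(Ym))
    sqrt(mean(rowSums((Xr - Yc)^2)))
  }
  grid_best <- min(vapply(1:5000, function(i) rmsd_at(random_proper_rotation()),
                          numeric(1)))
  expect_lte(spm$rmsd, grid_best + 1e-9)
  expect_lte(grid_best - spm$rmsd, 0.05)
  expect_error(kabsch(X[1:2, ], X[1:2, ]), "3 points")
})

test_that("d0 follows the clamped length formula", {
  expect_equal(tm_d0(15), 0.5)
  expect_equal(tm_d0(5), 0.5)
  expect_equal(tm_d0(100), 1.24 * 85^(1 / 3) - 1.8, tolerance = 1e-12)
  L <- 1:1000
  expect_true(all(diff(tm_d0(L)) >= 0))
  expect_true(all(tm_d0(L) > 0))
})

test_that("score_at_superposition matches its closed forms", {
  ch <- rand_walk_chain(30, seed = 21)
  idcorr <- identity_correspondence(ch, ch)
  ident <- structure(list(rotation = diag(3), translation = c(0, 0, 0),
                          rmsd = 0), class = "superposition")
  expect_equal(score_at_superposition(ch, ch, idcorr, ident), 1.0)

  # every displacement exactly d0 -> every term 1/2
  d0 <- tm_d0(30)
  shifted <- structure(list(rotation = diag(3), translation = c(d0, 0, 0),
                            rmsd = d0), class = "superposition")
  expect_equal(score_at_superposition(ch, ch, idcorr, shifted), 0.5)

  # half coverage at zero distance -> coverage factor 1/2
  half <- cbind(1:15, 1:15)
  expect_equal(score_at_superposition(ch, ch, half, ident), 0.5)
  expect_error(score_at_superposition(ch, ch, idcorr[0, ], ident),
               "non-empty")
})

test_that("tm_score on identical chains is exactly 1", {
  ch <- demo_fold()
  r <- tm_score(ch, ch)
  expect_identical(r$tm_query, 1)
  expect_identical(r$tm_target, 1)
  expect_identical(r$tm_max, 1)
  expect_equal(r$n_corresponding, chain_length(ch))
})

test_that("heuristic search equals the exhaustive oracle on small chains", {
  withr::local_seed(33)
  for (rep in 1:50) {
    L <- sample(4:10, 1)
    a <- rand_walk_chain(L, seed = 7000 + rep)
    b <- rand_walk_chain(L, seed = 9000 + rep)
    got <- tm_score(a, b)
    want <- oracle_tm_exhaustive(a, b)
    expect_lt(abs(got$tm_max - want$tm_max), 1e-9)
    expect_lt(abs(got$tm_query - want$tm_query), 1e-9)
    expect_lt(abs(got$tm_target - want$tm_target), 1e-9)
  }
})

test_that("normalization lengths are handled asymmetrically", {
  # target = query plus 50 extra residues far away: the common 50 superpose
  # exactly, so tm_query = 1 and tm_target = 50/100
  a <- rand_walk_chain(50, seed = 41)
  extra <- rand_walk_chain(51, seed = 42)$ca_coords[-1, , drop = FALSE]
  extra <- sweep(extra, 2, c(500, 500, 500), "+")
  b <- chain_structure("B", rbind(a$ca_coords, extra))
  r <- tm_score(a, b)
  expect_equal(r$tm_query, 1.0)
  expect_equal(r$tm_target, 0.5)
  expect_equal(r$tm_max, 1.0)
})

test_that("tm_score is rigid-motion invariant and symmetric", {
  ch <- demo_fold()
  withr::local_seed(52)
  for (i in 1:50) {
    moved <- rigid_move(ch, random_proper_rotation(), rnorm(3, 0, 20))
    expect_lt(abs(tm_score(ch, moved)$tm_max - 1), 1e-9)
  }
  for (i in 1:20) {
    a <- rand_walk_chain(sample(20:60, 1), seed = 300 + i)
    b <- rand_walk_chain(sample(20:60, 1), seed = 600 + i)
    expect_lt(abs(tm_score(a, b)$tm_max - tm_score(b, a)$tm_max), 1e-9)
  }
})

test_that("growing noise gives non-increasing median TM", {
  base <- demo_fold()
  med <- vapply(c(0.2, 0.5, 1, 2, 4), function(sd) {
    tms <- vapply(1:20, function(i) {
      tm_score(perturb_structure(base, sd, 0L, 0, rng_seed = 100 * sd + i),
               base)$tm_max
    }, numeric(1))
    median(tms)
  }, numeric(1))
  expect_true(all(diff(med) <= 0))
})

test_that("assembly TM handles symmetry, permutations and errors", {
  ch <- demo_fold()
  asm <- generate_assembly(ch, 2, "cyclic", radius = 25)
  expect_equal(assembly_tm(asm, asm)$tm_max, 1.0)

  swapped <- assembly_structure("sw", {
    chs <- rev(unname(asm$chains))
    chs[[1]]$chain_id <- "A"; chs[[2]]$chain_id <- "B"
    chs
  })
  expect_lt(assembly_tm(asm, swapped, "best_permutation")$tm_max - 1, 1e-9)
  expect_equal(assembly_tm(asm, swapped, "best_permutation")$tm_max, 1.0)

  trimer <- generate_assembly(ch, 3, "cyclic", radius = 25)
  expect_error(assembly_tm(asm, trimer), "equal chain counts")
  short <- chain_structure("A", ch$ca_coords[1:10, ])
  mixed <- assembly_structure("mx", list(
    short, chain_structure("B", ch$ca_coords)))
  expect_error(assembly_tm(mixed, asm, "identity"), "lengths differ")
})

test_that("batch pair scoring matches single calls", {
  bench <- shared_benchmark()
  ids <- names(bench$structures)[1:4]
  pr <- all_pairs(ids)
  out <- tm_pairs(pr, bench$structures)
  expect_equal(nrow(out), 6L)
  one <- tm_score(bench$structures[[out$id1[1]]],
                  bench$structures[[out$id2[1]]])
  expect_equal(out$tm_max[1], one$tm_max)
  expect_error(tm_pairs(tibble::tibble(id1 = "zz", id2 = ids[1]),
                        bench$structures), "missing")
})
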