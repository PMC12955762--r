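toy_metadata <- function() {
  tibble::tibble(
    id = c("a1", "a2", "b1", "c1", "d1"),
    family = c("f1.1.1", "f1.1.1", "f1.1.2", "f1.2.1", "f2.1.1"),
    superfamily = c("f1.1", "f1.1", "f1.1", "f1.2", "f2.1"),
    fold = c("f1", "f1", "f1", "f1", "f2"),
    topologies = c("T1", "T1", "T1", "T1,T2", "T2"),
    architectures = c("A1", "A1", "A1", "A1,A2", "A2"))
}

test_that("classification labeling follows the hierarchy definitions", {
  md <- toy_metadata()
  fam <- label_pairs(md, labeling_scheme("classification", "family"))
  key <- paste(fam$id1, fam$id2)
  expect_equal(fam$label[key == "a1 a2"], "TP")     # same family
  expect_equal(fam$label[key == "a1 b1"], "ignore") # same sf, diff family
  expect_equal(fam$label[key == "a1 d1"], "FP")     # different fold

  sf <- label_pairs(md, labeling_scheme("classification", "superfamily"))
  key <- paste(sf$id1, sf$id2)
  expect_equal(sf$label[key == "a1 b1"], "TP")
  expect_equal(sf$label[key == "a1 a2"], "ignore")
  expect_equal(sf$label[key == "a1 c1"], "ignore")  # same fold, diff sf

  fd <- label_pairs(md, labeling_scheme("classification", "fold"))
  key <- paste(fd$id1, fd$id2)
  expect_equal(fd$label[key == "a1 c1"], "TP")
  expect_equal(fd$label[key == "a1 b1"], "ignore")
  expect_equal(fd$label[key == "c1 d1"], "FP")

  expect_error(label_pairs(md[, c("id", "family")],
                           labeling_scheme("classification", "family")))
  md_na <- md; md_na$fold[2] <- NA
  expect_error(label_pairs(md_na, labeling_scheme("classification", "family")),
               "a2")
})

test_that("tm-threshold labeling brackets the FP cutoff", {
  sch <- labeling_scheme("tm_threshold", tp_threshold = 0.6)
  pairs <- tibble::tibble(id1 = c("x", "x", "x"), id2 = c("y", "z", "w"),
                          tm_max = c(0.62, 0.55, 0.31))
  out <- label_pairs(tibble::tibble(id = c("x", "y", "z", "w")), sch, pairs)
  expect_equal(out$label, c("TP", "ignore", "FP"))
  expect_error(labeling_scheme("tm_threshold", tp_threshold = 0.4), "exceed")
})

test_that("topology-combination labeling compares multisets and architectures", {
  md <- toy_metadata()
  out <- label_pairs(md, labeling_scheme("topology_combination"))
  key <- paste(out$id1, out$id2)
  expect_equal(out$label[key == "a1 a2"], "TP")     # identical topo multiset
  expect_equal(out$label[key == "a1 c1"], "ignore") # shared architecture A1
  expect_equal(out$label[key == "a1 d1"], "FP")     # disjoint architectures
})

test_that("every non-self pair gets exactly one label", {
  md <- shared_benchmark()$labels
  for (lvl in c("family", "superfamily", "fold")) {
    lp <- label_pairs(md, labeling_scheme("classification", lvl))
    expect_equal(nrow(lp), choose(nrow(md), 2))
    expect_true(all(lp$label %in% c("TP", "FP", "ignore")))
    expect_true(all(lp$id1 != lp$id2))
  }
})

test_that("sensitivity to the first FP counts leading true positives", {
  expect_equal(sensitivity_to_first_fp(c("TP", "TP", "FP", "TP")),
               list(count = 2L, fraction = 2 / 3))
  expect_equal(sensitivity_to_first_fp(c("TP", "TP", "TP"))$fraction, 1.0)
  expect_equal(sensitivity_to_first_fp(c("FP", "TP"))$fraction, 0.0)
  # ignores neither count nor block
  expect_equal(sensitivity_to_first_fp(c("ignore", "TP", "ignore", "FP", "TP")),
               list(count = 1L, fraction = 0.5))
  expect_true(is.na(sensitivity_to_first_fp(c("FP", "ignore"))$fraction))
})

test_that("the PR curve matches hand-enumerated and closed-form cases", {
  hand <- pr_curve(c(0.9, 0.8, 0.7, 0.6), c("TP", "TP", "FP", "TP"))
  expect_equal(hand$auprc, 11 / 12)
  perfect <- pr_curve(c(0.9, 0.8, 0.2, 0.1), c("TP", "TP", "FP", "FP"))
  expect_equal(perfect$auprc, 1.0)
  expect_error(pr_curve(c(1, 2), c("TP", "TP")), "at least one")
  # ties share a threshold
  tied <- pr_curve(c(0.5, 0.5, 0.5), c("TP", "FP", "TP"))
  expect_equal(nrow(tied$curve), 1L)
  expect_equal(tied$auprc, 2 / 3)
})

test_that("the step-rule area matches an independent reference", {
  withr::local_seed(81)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    scores <- round(runif(n), 2)  # force ties
    labels <- ifelse(runif(n) < 0.4, "TP", "FP")
    if (!any(labels == "TP") || !any(labels == "FP")) next
    expect_equal(pr_curve(scores, labels)$auprc,
                 oracle_pr_auprc(scores, labels), tolerance = 1e-12)
  }
})

test_that("random scores give AUPRC near the prevalence", {
  withr::local_seed(82)
  labels <- c(rep("TP", 300), rep("FP", 700))
  aucs <- vapply(1:1000, function(i) {
    pr_curve(runif(1000), labels)$auprc
  }, numeric(1))
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.3), max(3 * se, 0.01))
})

test_that("sensitivity distributions sort and report the perfect share", {
  d <- sensitivity_distribution(c(1.0, 1.0, 0.5, 0.0))
  expect_equal(d$perfect_fraction, 0.5)
  expect_true(all(diff(d$curve$sensitivity) <= 0))
  expect_equal(sensitivity_distribution(c(0, 0))$perfect_fraction, 0.0)
  expect_equal(sensitivity_distribution(c(0.4, NA, 1))$perfect_fraction, 0.5)
})

test_that("family CV splits partition families evenly and reproducibly", {
  md <- shared_benchmark()$labels
  splits <- build_family_cv_splits(md, k = 4, seed = 9)
  expect_equal(nrow(splits), 4L)
  expect_true(all(vapply(splits$test_families, length, integer(1)) == 4L))
  all_test <- unname(unlist(splits$test_ids))
  expect_setequal(all_test, md$id)
  expect_equal(anyDuplicated(all_test), 0L)
  for (i in 1:4) {
    fams_test <- unique(md$family[md$id %in% splits$test_ids[[i]]])
    fams_train <- unique(md$family[md$id %in% splits$train_ids[[i]]])
    expect_length(intersect(fams_test, fams_train), 0L)
  }
  expect_identical(splits, build_family_cv_splits(md, k = 4, seed = 9))
  expect_error(build_family_cv_splits(md, k = 40, seed = 1), "exceeds")
})

test_that("superfamily holdout withholds the ceiling fraction cleanly", {
  md <- tibble::tibble(id = sprintf("s%02d", 1:80),
                       superfamily = rep(sprintf("sf%02d", 1:40), each = 2))
  h <- holdout_superfamilies(md, fraction = 0.05, seed = 3)
  expect_length(h$held_superfamilies, 2L)
  expect_length(intersect(h$train_ids, h$test_ids), 0L)
  sf_test <- unique(md$superfamily[md$id %in% h$test_ids])
  sf_train <- unique(md$superfamily[md$id %in% h$train_ids])
  expect_length(intersect(sf_test, sf_train), 0L)
  expect_identical(h, holdout_superfamilies(md, fraction = 0.05, seed = 3))
})

test_that("scoring by the oracle TM itself is a perfect benchmark", {
  pairs <- shared_pairs()
  md <- shared_benchmark()$labels
  lp <- label_pairs(md, labeling_scheme("tm_threshold", tp_threshold = 0.8),
                    pairs = pairs)
  lp$score <- lp$tm_max
  rep <- run_benchmark(lp, method = "oracle")
  expect_equal(rep$auprc, 1.0)
  expect_equal(rep$perfect_fraction, 1.0)
  expect_true(all(rep$per_query$fraction[!is.na(rep$per_query$fraction)] == 1))
})

test_that("a constant scorer degrades to prevalence under the tie rule", {
  pairs <- shared_pairs()
  md <- shared_benchmark()$labels
  lp <- label_pairs(md, labeling_scheme("classification", "family"))
  lp$score <- 0.5
  rep <- run_benchmark(lp, method = "constant")
  lab <- lp$label[lp$label != "ignore"]
  expect_equal(rep$auprc, mean(lab == "TP"))
})

test_that("benchmark reports expose tidy accessors and plots", {
  pairs <- shared_pairs()
  md <- shared_benchmark()$labels
  lp <- label_pairs(md, labeling_scheme("classification", "family"))
  lp <- score_pairs_cosine(lp, embed_structures(
    shared_benchmark()$structures, encoder_config(), method = "mean"))
  rep <- run_benchmark(lp, method = "baseline")
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(glance(rep)$method, "baseline")
  expect_s3_class(autoplot(rep, "sensitivity"), "ggplot")
  expect_s3_class(autoplot(rep, "pr"), "ggplot")
})
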