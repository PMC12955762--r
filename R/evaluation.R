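#' Pair labeling schemes
#'
#' Three ways of declaring a structure pair a true positive (TP), false
#' positive (FP) or neither (ignored) for benchmarking:
#'
#' * `"classification"` at a hierarchy `level`: at the family level TP =
#'   same family; at the superfamily level TP = same superfamily but
#'   different family; at the fold level TP = same fold but different
#'   superfamily. In all three, FP = different fold; everything else is
#'   ignored.
#' * `"tm_threshold"`: TP = `tm_max >= tp_threshold` (conventionally 0.6,
#'   0.7 or 0.8), FP = `tm_max < 0.5` (distinct folds), in-between ignored.
#' * `"topology_combination"`: TP = identical multisets of domain
#'   topologies; FP = the two architecture sets are disjoint; else ignored.
#'
#' @param kind One of `"classification"`, `"tm_threshold"`,
#'   `"topology_combination"`.
#' @param level Hierarchy level for `"classification"`.
#' @param tp_threshold TM threshold for TPs (must exceed `fp_threshold`).
#' @param fp_threshold TM threshold below which pairs are FPs (default 0.5).
#' @return An object of class `labeling_scheme`.
#' @export
labeling_scheme <- function(kind = c("classification", "tm_threshold",
                                     "topology_combination"),
                            level = c("family", "superfamily", "fold"),
                            tp_threshold = 0.8, fp_threshold = 0.5) {
  kind <- match.arg(kind)
  level <- match.arg(level)
  if (tp_threshold <= fp_threshold) {
    abort("`tp_threshold` must exceed `fp_threshold`.")
  }
  structure(list(kind = kind, level = level, tp_threshold = tp_threshold,
                 fp_threshold = fp_threshold),
            class = "labeling_scheme")
}

#' Label structure pairs under a scheme
#'
#' Every non-self pair receives exactly one of `TP`, `FP`, `ignore`.
#'
#' @param metadata Tibble with `id` plus the columns the scheme needs
#'   (`family`/`superfamily`/`fold`, or `topologies`/`architectures` as
#'   comma-separated strings) — see [structure_metadata()].
#' @param scheme A [labeling_scheme()].
#' @param pairs Pair table `id1`, `id2` (plus `tm_max` for the
#'   `tm_threshold` scheme); default all unordered pairs of `metadata$id`.
#' @return Tibble `id1`, `id2`, `label` (plus any input columns).
#' @export
label_pairs <- function(metadata, scheme, pairs = NULL) {
  metadata <- tibble::as_tibble(metadata)
  if (is.null(pairs)) pairs <- all_pairs(metadata$id)
  pairs <- tibble::as_tibble(pairs)
  pairs <- pairs[pairs$id1 != pairs$id2, , drop = FALSE]

  need <- switch(scheme$kind,
                 classification = c("family", "superfamily", "fold"),
                 tm_threshold = character(0),
                 topology_combination = c("topologies", "architectures"))
  ids_used <- unique(c(pairs$id1, pairs$id2))
  missing_ids <- setdiff(ids_used, metadata$id)
  if (length(need)) {
    covered <- metadata[metadata$id %in% ids_used, , drop = FALSE]
    bad <- covered$id[!stats::complete.cases(covered[, need, drop = FALSE])]
    missing_ids <- union(missing_ids, bad)
  }
  if (scheme$kind != "tm_threshold" && length(missing_ids)) {
    abort(paste("metadata missing or incomplete for ids:",
                paste(head(sort(missing_ids), 5L), collapse = ", ")))
  }

  if (scheme$kind == "tm_threshold") {
    if (!"tm_max" %in% names(pairs)) {
      abort("tm_threshold labeling needs a `tm_max` column in `pairs`.")
    }
    pairs$label <- dplyr::case_when(
      pairs$tm_max >= scheme$tp_threshold ~ "TP",
      pairs$tm_max < scheme$fp_threshold ~ "FP",
      TRUE ~ "ignore")
    return(pairs)
  }

  if (scheme$kind == "classification") {
    lut <- metadata[, c("id", "family", "superfamily", "fold")]
    p <- dplyr::left_join(pairs, lut, by = c(id1 = "id")) |>
      dplyr::left_join(lut, by = c(id2 = "id"), suffix = c("_1", "_2"))
    same_fam <- p$family_1 == p$family_2
    same_sf <- p$superfamily_1 == p$superfamily_2
    same_fold <- p$fold_1 == p$fold_2
    tp <- switch(scheme$level,
                 family = same_fam,
                 superfamily = same_sf & !same_fam,
                 fold = same_fold & !same_sf)
    pairs$label <- dplyr::case_when(tp ~ "TP", !same_fold ~ "FP",
                                    TRUE ~ "ignore")
    return(pairs)
  }

  # topology_combination
  lut <- setNames(
    lapply(seq_len(nrow(metadata)), function(i) list(
      topo = sort(strsplit(metadata$topologies[i], ",")[[1]]),
      arch = unique(strsplit(metadata$architectures[i], ",")[[1]]))),
    metadata$id)
  pairs$label <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- lut[[pairs$id1[i]]]; b <- lut[[pairs$id2[i]]]
    if (identical(a$topo, b$topo)) "TP"
    else if (!length(intersect(a$arch, b$arch))) "FP"
    else "ignore"
  }, character(1))
  pairs
}

#' Per-query sensitivity to the first false positive
#'
#' Given a query's targets in rank order, counts the true positives retrieved
#' before the first false positive. Ignored pairs neither count nor block.
#' The fraction normalizes by the query's total TPs (1 when the list has no
#' FP; `NA` when the query has no TPs, in which case the query is skipped by
#' [run_benchmark()]).
#'
#' @param labels Character vector (`"TP"`, `"FP"`, `"ignore"`) in descending
#'   score order.
#' @return List with `count` (TPs before the first FP) and `fraction`.
#' @export
sensitivity_to_first_fp <- function(labels) {
  labels <- labels[labels != "ignore"]
  total_tp <- sum(labels == "TP")
  if (total_tp == 0L) return(list(count = 0L, fraction = NA_real_))
  first_fp <- match("FP", labels)
  count <- if (is.na(first_fp)) total_tp else sum(labels[seq_len(first_fp - 1L)] == "TP")
  list(count = count, fraction = count / total_tp)
}

#' Precision-recall curve and AUPRC
#'
#' Pooled over all labeled pairs, ranked by descending score. Tied scores
#' share a threshold. The area is the step-wise (rectangular) sum
#' `sum((R_i - R_{i-1}) * P_i)` over distinct thresholds.
#'
#' @param scores Numeric scores (higher = more similar).
#' @param labels `"TP"`/`"FP"` per score (ignored pairs must be excluded by
#'   the caller), or logical.
#' @return List with `curve` (tibble `threshold`, `precision`, `recall`) and
#'   `auprc`.
#' @export
pr_curve <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "TP", "FP")
  keep <- labels %in% c("TP", "FP")
  scores <- scores[keep]; labels <- labels[keep]
  P <- sum(labels == "TP"); N <- sum(labels == "FP")
  if (P == 0L || N == 0L) {
    abort("PR curve needs at least one TP and one FP.")
  }
  ord <- order(-scores)
  scores <- scores[ord]; labels <- labels[ord]
  is_tp <- cumsum(labels == "TP")
  is_fp <- cumsum(labels == "FP")
  last_of_tie <- c(scores[-1L] != scores[-length(scores)], TRUE)
  tp <- is_tp[last_of_tie]; fp <- is_fp[last_of_tie]
  precision <- tp / (tp + fp)
  recall <- tp / P
  auprc <- sum(diff(c(0, recall)) * precision)
  list(curve = tibble::tibble(threshold = scores[last_of_tie],
                              precision = precision, recall = recall),
       auprc = auprc)
}

#' Sorted per-query sensitivity distribution
#'
#' Sensitivities sorted from best to worst against the fraction of queries,
#' plus the share of queries at perfect sensitivity (fraction exactly 1).
#'
#' @param fractions Per-query sensitivity fractions (NAs dropped).
#' @return List with `curve` (tibble `query_fraction`, `sensitivity`,
#'   non-increasing) and `perfect_fraction`.
#' @export
sensitivity_distribution <- function(fractions) {
  fractions <- fractions[!is.na(fractions)]
  if (!length(fractions)) abort("need at least one query with TPs.")
  s <- sort(fractions, decreasing = TRUE)
  list(curve = tibble::tibble(query_fraction = seq_along(s) / length(s),
                              sensitivity = s),
       perfect_fraction = mean(fractions == 1))
}

#' Family-grouped cross-validation splits
#'
#' Partitions *families* (not structures) into `k` groups; test split `i`
#' contains all structures of group-`i` families, so no family straddles
#' train and test.
#'
#' @param metadata Tibble with `id` and `family`.
#' @param k Number of splits (<= number of families).
#' @param seed Integer seed.
#' @return Tibble with columns `split`, `test_families`, `train_ids`,
#'   `test_ids` (list-columns).
#' @export
build_family_cv_splits <- function(metadata, k = 10L, seed = 1L) {
  fams <- unique(metadata$family)
  if (k > length(fams)) abort("`k` exceeds the number of families.")
  withr::with_seed(seed, {
    shuffled <- fams[sample.int(length(fams))]
    groups <- split(shuffled, rep_len(seq_len(k), length(shuffled)))
    tibble::tibble(
      split = seq_len(k),
      test_families = unname(groups),
      train_ids = lapply(groups, function(g) {
        metadata$id[!metadata$family %in% g]
      }),
      test_ids = lapply(groups, function(g) {
        metadata$id[metadata$family %in% g]
      }))
  })
}

#' Superfamily holdout split
#'
#' Withholds `ceiling(fraction * S)` superfamilies at random; all their
#' structures form the test set and are excluded from training.
#'
#' @param metadata Tibble with `id` and `superfamily`.
#' @param fraction Fraction of superfamilies to hold out (default 0.05).
#' @param seed Integer seed.
#' @return List with `train_ids`, `test_ids`, `held_superfamilies`.
#' @export
holdout_superfamilies <- function(metadata, fraction = 0.05, seed = 1L) {
  sfs <- unique(metadata$superfamily)
  n_hold <- ceiling(fraction * length(sfs))
  withr::with_seed(seed, {
    held <- sfs[sample.int(length(sfs), n_hold)]
    list(train_ids = metadata$id[!metadata$superfamily %in% held],
         test_ids = metadata$id[metadata$superfamily %in% held],
         held_superfamilies = held)
  })
}

#' Run the retrieval benchmark
#'
#' All-versus-all evaluation: per query, targets are ranked by descending
#' score (ties broken by target id for determinism) and the sensitivity to
#' the first FP is computed; pooled over unordered pairs, the
#' precision-recall curve and AUPRC are computed. Any scorer can be plugged
#' in by supplying its scores — the trained model's cosines, the mean-pooling
#' baseline's, or the oracle `tm_max` itself.
#'
#' @param scored_pairs Tibble `id1`, `id2`, `score`, `label` — labeled pairs
#'   (see [label_pairs()]) joined with a score per pair.
#' @param method Tag naming the scorer (stored in the report).
#' @param scheme Optional [labeling_scheme()] stored in the report.
#' @return An object of class `benchmark_report`.
#' @export
run_benchmark <- function(scored_pairs, method = "model", scheme = NULL) {
  sp <- tibble::as_tibble(scored_pairs)
  if (!all(c("id1", "id2", "score", "label") %in% names(sp))) {
    abort("`scored_pairs` needs columns id1, id2, score, label.")
  }
  if (any(!is.finite(sp$score))) abort("scores must be finite for all pairs.")
  directed <- dplyr::bind_rows(
    tibble::tibble(query = sp$id1, target = sp$id2, score = sp$score,
                   label = sp$label),
    tibble::tibble(query = sp$id2, target = sp$id1, score = sp$score,
                   label = sp$label))
  per_query <- directed |>
    dplyr::arrange(.data$query, dplyr::desc(.data$score), .data$target) |>
    dplyr::group_by(.data$query) |>
    dplyr::summarise(
      n_tp = sum(.data$label == "TP"),
      count = sensitivity_to_first_fp(.data$label)$count,
      fraction = sensitivity_to_first_fp(.data$label)$fraction,
      .groups = "drop")
  dist <- sensitivity_distribution(per_query$fraction)
  pr <- pr_curve(sp$score[sp$label != "ignore"],
                 sp$label[sp$label != "ignore"])
  structure(
    list(per_query = per_query, sensitivity_curve = dist$curve,
         perfect_fraction = dist$perfect_fraction,
         pr_curve = pr$curve, auprc = pr$auprc,
         method = method, scheme = scheme,
         n_tp_pairs = sum(sp$label == "TP"),
         n_fp_pairs = sum(sp$label == "FP")),
    class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf(
    "<benchmark_report> %s: AUPRC %.4f; perfect sensitivity for %.1f%% of %d queries\n",
    x$method, x$auprc, 100 * x$perfect_fraction,
    sum(!is.na(x$per_query$fraction))))
  invisible(x)
}

#' @rdname run_benchmark
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @export
tidy.benchmark_report <- function(x, ...) x$per_query

#' @rdname run_benchmark
#' @export
glance.benchmark_report <- function(x, ...) {
  tibble::tibble(method = x$method, auprc = x$auprc,
                 perfect_fraction = x$perfect_fraction,
                 n_queries = sum(!is.na(x$per_query$fraction)),
                 n_tp_pairs = x$n_tp_pairs, n_fp_pairs = x$n_fp_pairs)
}

#' @rdname run_benchmark
#' @param object A `benchmark_report`.
#' @param type `"sensitivity"` or `"pr"`.
#' @export
autoplot.benchmark_report <- function(object, type = c("sensitivity", "pr"),
                                      ...) {
  type <- match.arg(type)
  if (type == "sensitivity") {
    ggplot2::ggplot(object$sensitivity_curve,
                    ggplot2::aes(x = .data$query_fraction,
                                 y = .data$sensitivity)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "fraction of queries (sorted best to worst)",
                    y = "sensitivity to first FP", title = object$method) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$pr_curve,
                    ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(x = "recall", y = "precision",
                    title = sprintf("%s (AUPRC %.3f)", object$method,
                                    object$auprc)) +
      ggplot2::theme_minimal()
  }
}

#' Score pairs with an embedding matrix
#'
#' Helper joining a pair table with cosine similarities computed from an
#' embedding matrix (rownames = structure ids).
#'
#' @param pairs Tibble with `id1`, `id2`.
#' @param emb Numeric matrix with rownames covering all pair ids.
#' @return `pairs` with a `score` column (raw cosine).
#' @export
score_pairs_cosine <- function(pairs, emb) {
  pairs <- tibble::as_tibble(pairs)
  norms <- sqrt(rowSums(emb^2))
  en <- emb / norms
  i1 <- match(pairs$id1, rownames(emb))
  i2 <- match(pairs$id2, rownames(emb))
  if (anyNA(i1) || anyNA(i2)) abort("embedding matrix missing some pair ids.")
  pairs$score <- rowSums(en[i1, , drop = FALSE] * en[i2, , drop = FALSE])
  pairs
}
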