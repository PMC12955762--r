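#' Build an embedding store
#'
#' Stores structure embeddings L2-normalized (cosine similarity is then a dot
#' product) alongside the raw norms, with a manifest of dimension, count and
#' granularity. The exact k-NN search over the store ([query_exact()]) is the
#' reference against which the approximate index is judged.
#'
#' @param emb Numeric matrix of embeddings with unique rownames (ids), or a
#'   list of [structure_embedding()] objects.
#' @param granularity `"chain"` or `"assembly"`.
#' @param metadata Optional named list stored in the manifest.
#' @return An object of class `embedding_store`.
#' @export
build_store <- function(emb, granularity = "chain", metadata = list()) {
  if (is.list(emb) && !is.matrix(emb)) {
    ids <- vapply(emb, function(e) e$id, character(1))
    emb <- do.call(rbind, lapply(emb, function(e) e$vector))
    rownames(emb) <- ids
  }
  emb <- as.matrix(emb)
  if (is.null(rownames(emb))) {
    if (nrow(emb)) abort("embeddings need rownames (ids).")
    rownames(emb) <- character(0)
  }
  dup <- rownames(emb)[duplicated(rownames(emb))]
  if (length(dup)) {
    abort(paste("duplicate embedding id(s):", paste(unique(dup), collapse = ", ")))
  }
  norms <- unname(sqrt(rowSums(emb^2)))
  if (nrow(emb) && any(norms == 0)) abort("zero-norm embeddings cannot be stored.")
  structure(
    list(ids = rownames(emb),
         matrix = if (nrow(emb)) emb / norms else emb,
         norms = norms, dim = ncol(emb), granularity = granularity,
         metadata = metadata),
    class = "embedding_store"
  )
}

#' @export
print.embedding_store <- function(x, ...) {
  cat(sprintf("<embedding_store> %d vector(s) x %d dims (%s)\n",
              length(x$ids), x$dim, x$granularity))
  invisible(x)
}

#' Save / load an embedding store
#'
#' Single text container: a JSON manifest line (dim, count, granularity,
#' metadata) followed by tab-separated full-precision rows (`id`, raw norm,
#' normalized coordinates). The round trip is bit-exact.
#'
#' @param store An `embedding_store`.
#' @param path File path.
#' @return `save_store()`: `path` invisibly; `load_store()`: the store.
#' @export
save_store <- function(store, path) {
  manifest <- jsonlite::toJSON(
    list(dim = store$dim, count = length(store$ids),
         granularity = store$granularity, metadata = store$metadata),
    auto_unbox = TRUE)
  rows <- vapply(seq_along(store$ids), function(i) {
    paste(c(store$ids[i], sprintf("%.17g", store$norms[i]),
            sprintf("%.17g", store$matrix[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(as.character(manifest), rows), path)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  lines <- readLines(path)
  manifest <- jsonlite::fromJSON(lines[1L])
  rows <- lines[-1L]
  if (length(rows)) {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    ids <- vapply(parts, `[[`, character(1), 1L)
    norms <- as.numeric(vapply(parts, `[[`, character(1), 2L))
    mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-(1:2)])))
    rownames(mat) <- ids
  } else {
    ids <- character(0)
    norms <- numeric(0)
    mat <- matrix(numeric(0), 0L, manifest$dim)
    rownames(mat) <- character(0)
  }
  # reconstruct directly: the stored rows are already normalized, and
  # renormalizing would perturb the last ulp
  structure(
    list(ids = ids, matrix = mat, norms = norms, dim = manifest$dim,
         granularity = manifest$granularity,
         metadata = as.list(manifest$metadata)),
    class = "embedding_store"
  )
}

#' Exact cosine k-nearest-neighbour search
#'
#' Full scan over the store; ties broken by id, `k` clamped to the store
#' size. This is the deterministic reference search.
#'
#' @param store An `embedding_store`.
#' @param vector Query vector (dimension must match) or a
#'   [structure_embedding()].
#' @param k Number of hits, >= 1.
#' @return A tibble `rank`, `id`, `similarity` (non-increasing), class
#'   `query_result`.
#' @export
query_exact <- function(store, vector, k = 10L) {
  if (!length(store$ids)) abort("store is empty.")
  if (k < 1L) abort("`k` must be >= 1.")
  v <- if (inherits(vector, "structure_embedding")) vector$vector else as.numeric(vector)
  if (length(v) != store$dim) abort("query dimension mismatch.")
  nv <- sqrt(sum(v^2))
  if (nv == 0) abort("zero-norm query.")
  sims <- unname(drop(store$matrix %*% (v / nv)))
  ord <- order(-sims, store$ids)
  take <- seq_len(min(k, length(ord)))
  out <- tibble::tibble(rank = take, id = store$ids[ord[take]],
                        similarity = sims[ord[take]])
  class(out) <- c("query_result", class(out))
  out
}

#' Build an HNSW approximate-nearest-neighbour index
#'
#' Indexes the store's normalized vectors with a Hierarchical Navigable
#' Small World graph (cosine metric). The graph is returned as plain R data
#' (adjacency lists per layer), so the index serializes with `saveRDS()`.
#'
#' @param store A non-empty `embedding_store`.
#' @param backend Only `"hnsw"` is supported.
#' @param M Maximum neighbours per node on upper layers (2M on layer 0).
#' @param ef_construction Beam width during construction.
#' @param seed Integer seed for the level assignment.
#' @return An object of class `ann_index`.
#' @export
build_ann_index <- function(store, backend = "hnsw", M = 16L,
                            ef_construction = 200L, seed = 1L) {
  if (!identical(backend, "hnsw")) {
    abort(paste0("unsupported ANN backend: ", backend))
  }
  if (!length(store$ids)) abort("store is empty.")
  graph <- withr::with_seed(seed, {
    .hnsw_build(store$matrix, as.integer(M), as.integer(ef_construction))
  })
  structure(
    list(graph = graph, ids = store$ids, matrix = store$matrix,
         dim = store$dim,
         params = list(backend = "hnsw", M = M,
                       ef_construction = ef_construction, seed = seed)),
    class = "ann_index"
  )
}

#' @export
print.ann_index <- function(x, ...) {
  cat(sprintf("<ann_index> hnsw over %d vector(s) x %d dims (M=%d, efC=%d)\n",
              length(x$ids), x$dim, x$params$M, x$params$ef_construction))
  invisible(x)
}

#' Approximate k-nearest-neighbour query
#'
#' Beam search over the HNSW graph. Similarities reported for returned ids
#' are exact cosines; only the candidate set is approximate. `k` is clamped
#' to the store size.
#'
#' @param index An `ann_index`.
#' @param vector Query vector or [structure_embedding()].
#' @param k Number of hits.
#' @param ef_search Beam width (recall grows with it; floor is `k`).
#' @return A tibble `rank`, `id`, `similarity`.
#' @export
query_ann <- function(index, vector, k = 10L, ef_search = 128L) {
  if (!length(index$ids)) abort("index is empty.")
  v <- if (inherits(vector, "structure_embedding")) vector$vector else as.numeric(vector)
  if (length(v) != index$dim) abort("query dimension mismatch.")
  nv <- sqrt(sum(v^2))
  if (nv == 0) abort("zero-norm query.")
  res <- .hnsw_query(index$matrix, index$graph$adjacency, index$graph$levels,
                     index$graph$entry, index$graph$max_level, v / nv,
                     as.integer(min(k, length(index$ids))),
                     as.integer(ef_search))
  out <- tibble::tibble(rank = seq_along(res$idx), id = index$ids[res$idx],
                        similarity = res$similarity)
  class(out) <- c("query_result", class(out))
  out
}

#' Recall of the approximate index against the exact reference
#'
#' Fraction of the exact top-k ids retrieved by the ANN search, averaged over
#' queries.
#'
#' @param index An `ann_index`.
#' @param store The `embedding_store` the index was built from.
#' @param queries Matrix of query vectors (rows).
#' @param k Neighbours per query.
#' @param ef_search Beam width.
#' @return Mean recall at k over the queries.
#' @export
ann_recall <- function(index, store, queries, k = 10L, ef_search = 128L) {
  queries <- as.matrix(queries)
  rec <- vapply(seq_len(nrow(queries)), function(i) {
    exact <- query_exact(store, queries[i, ], k)$id
    approx <- query_ann(index, queries[i, ], k, ef_search)$id
    length(intersect(exact, approx)) / length(exact)
  }, numeric(1))
  mean(rec)
}
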