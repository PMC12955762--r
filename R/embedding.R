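#' Fixed-length structure embedding
#'
#' @param vector Numeric embedding vector (finite, non-zero norm).
#' @param granularity `"chain"` or `"assembly"`.
#' @param id Identifier string.
#' @return An object of class `structure_embedding`.
#' @export
structure_embedding <- function(vector, granularity = c("chain", "assembly"),
                                id = "") {
  granularity <- match.arg(granularity)
  vector <- as.numeric(vector)
  if (!all(is.finite(vector))) abort("embedding must be finite.")
  if (sqrt(sum(vector^2)) == 0) abort("embedding must have non-zero norm.")
  structure(list(vector = vector, granularity = granularity,
                 id = as.character(id)),
            class = "structure_embedding")
}

#' @export
print.structure_embedding <- function(x, ...) {
  cat(sprintf("<structure_embedding> %s (%s), %d dims, norm %.3f\n",
              x$id, x$granularity, length(x$vector), sqrt(sum(x$vector^2))))
  invisible(x)
}

#' Aggregate residue embeddings into a structure embedding
#'
#' Runs the transformer aggregator (see [aggregator_config()]) over a residue
#' embedding sequence: encoder stack without positional encoding, summation
#' pooling, residual head. The output is invariant to permutations of the
#' input rows.
#'
#' @param res A `residue_embedding_sequence`.
#' @param cfg An [aggregator_config()] with `d_in` matching the embeddings.
#' @param weights Weights from [init_aggregator_weights()] or a trained model.
#' @return A [structure_embedding()] (granularity `"assembly"` when the
#'   sequence spans multiple chains).
#' @export
aggregate <- function(res, cfg, weights) {
  if (!inherits(res, "residue_embedding_sequence")) {
    abort("`res` must be a residue_embedding_sequence.")
  }
  if (ncol(res$embeddings) != cfg$d_in) {
    abort(sprintf("embedding dim %d does not match cfg$d_in = %d.",
                  ncol(res$embeddings), cfg$d_in))
  }
  out <- aggregator_forward(res$embeddings, weights, cfg)$out
  structure_embedding(
    out,
    granularity = if (length(res$boundaries) > 1L) "assembly" else "chain",
    id = paste(res$ids, collapse = "|"))
}

#' Embed a chain or assembly
#'
#' `embed_chain()` composes [encode_residues()] and [aggregate()].
#' `embed_assembly()` encodes each chain independently, concatenates the
#' residue-embedding matrices row-wise and aggregates once; because the
#' aggregator carries no positional encoding and pools by summation, the
#' result is invariant to chain order — and, by the same token, identical
#' subunits arranged differently in space yield identical assembly
#' embeddings (a documented degeneracy of this representation).
#'
#' @param chain A [chain_structure()].
#' @param encoder_cfg An [encoder_config()].
#' @param aggregator_cfg An [aggregator_config()].
#' @param weights Aggregator weights.
#' @return A [structure_embedding()].
#' @export
embed_chain <- function(chain, encoder_cfg, aggregator_cfg, weights) {
  emb <- aggregate(encode_residues(chain, encoder_cfg), aggregator_cfg, weights)
  emb$id <- chain$chain_id
  emb
}

#' @rdname embed_chain
#' @param assembly An [assembly_structure()].
#' @export
embed_assembly <- function(assembly, encoder_cfg, aggregator_cfg, weights) {
  if (!length(assembly$chains)) abort("assembly has no chains.")
  per_chain <- lapply(assembly$chains, encode_residues, cfg = encoder_cfg)
  res <- residue_embedding_sequence(
    do.call(rbind, lapply(per_chain, function(r) r$embeddings)),
    boundaries = vapply(per_chain, function(r) nrow(r$embeddings), integer(1)),
    ids = names(assembly$chains))
  emb <- aggregate(res, aggregator_cfg, weights)
  emb$granularity <- "assembly"
  emb$id <- assembly$assembly_id
  emb
}

#' Cosine similarity / predicted TM-score between embeddings
#'
#' The cosine of two structure embeddings is the model's predicted TM-score.
#' `similarity()` clamps the cosine to \[0, 1\] for reporting on the TM scale;
#' `cosine_similarity()` returns the raw cosine (used for ranking, where the
#' clamp could only merge ties at 0).
#'
#' @param a,b [structure_embedding()] objects (or bare numeric vectors) of
#'   equal dimension.
#' @return A single number.
#' @export
similarity <- function(a, b) {
  min(1, max(0, cosine_similarity(a, b)))
}

#' @rdname similarity
#' @export
cosine_similarity <- function(a, b) {
  va <- if (inherits(a, "structure_embedding")) a$vector else as.numeric(a)
  vb <- if (inherits(b, "structure_embedding")) b$vector else as.numeric(b)
  if (length(va) != length(vb)) abort("embeddings must have equal dimension.")
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) abort("cosine undefined for zero-norm vectors.")
  sum(va * vb) / (na * nb)
}

#' Mean-pooling baseline embedding
#'
#' The naive alternative to the trained aggregator: the row-wise mean of the
#' residue embeddings, with no learned parameters. Kept as the comparison
#' baseline for benchmark runs.
#'
#' @param res A `residue_embedding_sequence`.
#' @return A [structure_embedding()].
#' @export
baseline_mean_embed <- function(res) {
  if (!nrow(res$embeddings)) abort("empty residue embedding sequence.")
  structure_embedding(
    colMeans(res$embeddings),
    granularity = if (length(res$boundaries) > 1L) "assembly" else "chain",
    id = paste(res$ids, collapse = "|"))
}

#' Embed a set of chains as a matrix
#'
#' Convenience wrapper used by training, evaluation and indexing: embeds
#' every chain and stacks the vectors.
#'
#' @param structures Named list of [chain_structure()] objects.
#' @param encoder_cfg,aggregator_cfg,weights As in [embed_chain()].
#' @param method `"aggregator"` (trained model) or `"mean"` (the
#'   [baseline_mean_embed()] baseline, which ignores `aggregator_cfg` and
#'   `weights`).
#' @return Numeric matrix, one row per structure, rownames = ids.
#' @export
embed_structures <- function(structures, encoder_cfg, aggregator_cfg = NULL,
                             weights = NULL,
                             method = c("aggregator", "mean")) {
  method <- match.arg(method)
  rows <- lapply(structures, function(ch) {
    res <- encode_residues(ch, encoder_cfg)
    if (method == "aggregator") {
      aggregator_forward(res$embeddings, weights, aggregator_cfg)$out
    } else {
      colMeans(res$embeddings)
    }
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(structures)
  m
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint embedding the aggregator and encoder configs, the
#' weights and a content hash for integrity checking on load.
#'
#' @param weights Aggregator weights.
#' @param encoder_cfg,aggregator_cfg Configs to embed.
#' @param path Destination file.
#' @param extra Optional list stored verbatim (e.g. training history).
#' @return `path` invisibly; `load_checkpoint()` returns the checkpoint list.
#' @export
save_checkpoint <- function(weights, encoder_cfg, aggregator_cfg, path,
                            extra = NULL) {
  payload <- list(weights = weights, encoder_cfg = encoder_cfg,
                  aggregator_cfg = aggregator_cfg, extra = extra)
  payload$hash <- rlang::hash(payload[c("weights", "encoder_cfg",
                                        "aggregator_cfg")])
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  expect <- rlang::hash(payload[c("weights", "encoder_cfg", "aggregator_cfg")])
  if (!identical(expect, payload$hash)) abort("checkpoint hash mismatch.")
  payload
}
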