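#' Residue encoder configuration
#'
#' The residue encoder turns a chain into a sequence of per-residue feature
#' vectors. The built-in `"geometric"` encoder is self-contained and
#' rigid-motion invariant: per residue it collects windowed CA-CA distances,
#' the pseudo-bond angle and pseudo-dihedral along the trace, and a seeded
#' residue-type embedding, then projects them linearly to `d_in` dimensions
#' with fixed (untrained) weights. It plays the role a frozen protein
#' language model plays in production pipelines; any external per-residue
#' embedding can be substituted through [read_residue_embeddings()], which
#' fulfils the external-adapter contract.
#'
#' @param kind `"geometric"` (built-in) or `"external"` (embeddings supplied
#'   by file; [encode_residues()] then refuses to run and the adapter must be
#'   used).
#' @param window_radius Residue window half-width for distance features, >= 1.
#' @param d_in Output dimension, >= 8.
#' @param aa_dim Width of the residue-type embedding.
#' @param seed Seed fixing the (frozen) projection and residue-type weights.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(kind = c("geometric", "external"),
                           window_radius = 16L, d_in = 32L, aa_dim = 8L,
                           seed = 101L) {
  kind <- match.arg(kind)
  if (d_in < 8L) abort("`d_in` must be >= 8.")
  if (window_radius < 1L) abort("`window_radius` must be >= 1.")
  structure(
    list(kind = kind, window_radius = as.integer(window_radius),
         d_in = as.integer(d_in), aa_dim = as.integer(aa_dim),
         seed = as.integer(seed)),
    class = "encoder_config"
  )
}

encoder_weights <- function(cfg) {
  n_feat <- 2L * cfg$window_radius + 4L + cfg$aa_dim
  withr::with_seed(cfg$seed, list(
    W = matrix(stats::rnorm(n_feat * cfg$d_in, sd = 1 / sqrt(n_feat)),
               n_feat, cfg$d_in),
    aa = matrix(stats::rnorm(21L * cfg$aa_dim, sd = 1), 21L, cfg$aa_dim)
  ))
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# L x (2w + 4) matrix of trace-internal geometry: distances to +/-1..w
# neighbours (0-padded at the ends, scaled by 1/10), cos/sin of the
# pseudo-bond angle at i, cos/sin of the pseudo-dihedral (i-1, i, i+1, i+2)
geometric_features <- function(coords, w) {
  L <- nrow(coords)
  feats <- matrix(0, L, 2L * w + 4L)
  for (k in seq_len(w)) {
    if (L > k) {
      d <- sqrt(rowSums((coords[seq.int(1L + k, L), , drop = FALSE] -
                           coords[seq.int(1L, L - k), , drop = FALSE])^2)) / 10
      feats[seq.int(1L, L - k), k] <- d            # distance to i + k
      feats[seq.int(1L + k, L), w + k] <- d        # distance to i - k
    }
  }
  if (L >= 3L) {
    for (i in seq.int(2L, L - 1L)) {
      v1 <- coords[i - 1L, ] - coords[i, ]
      v2 <- coords[i + 1L, ] - coords[i, ]
      ca <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      ca <- max(-1, min(1, ca))
      feats[i, 2L * w + 1L] <- ca
      feats[i, 2L * w + 2L] <- sqrt(1 - ca^2)
    }
  }
  if (L >= 4L) {
    for (i in seq.int(2L, L - 2L)) {
      b1 <- coords[i, ] - coords[i - 1L, ]
      b2 <- coords[i + 1L, ] - coords[i, ]
      b3 <- coords[i + 2L, ] - coords[i + 1L, ]
      n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
      m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
      x <- sum(n1 * n2); y <- sum(m1 * n2)
      ang <- atan2(y, x)
      feats[i, 2L * w + 3L] <- cos(ang)
      feats[i, 2L * w + 4L] <- sin(ang)
    }
  }
  feats
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Per-residue embeddings for a chain
#'
#' Runs the geometric residue encoder (see [encoder_config()]). The output is
#' deterministic given the config and invariant to global rigid motion of the
#' chain, because every feature is an internal distance or angle.
#'
#' @param chain A [chain_structure()].
#' @param cfg An [encoder_config()] of kind `"geometric"`.
#' @return An object of class `residue_embedding_sequence`: list with
#'   `embeddings` (L x `d_in`), `boundaries` (segment lengths; one segment
#'   for a chain), `ids`.
#' @export
encode_residues <- function(chain, cfg = encoder_config()) {
  if (cfg$kind != "geometric") {
    abort("encode_residues computes geometric embeddings; external embeddings come from read_residue_embeddings().")
  }
  L <- chain_length(chain)
  if (L < 1L) abort("chain must have at least one residue.")
  ew <- encoder_weights(cfg)
  aa_idx <- match(strsplit(chain$sequence, "")[[1]], AA_ALPHABET)
  aa_idx[is.na(aa_idx)] <- 21L
  feats <- cbind(geometric_features(chain$ca_coords, cfg$window_radius),
                 ew$aa[aa_idx, , drop = FALSE])
  residue_embedding_sequence(feats %*% ew$W, boundaries = L,
                             ids = chain$chain_id)
}

#' @rdname encode_residues
#' @param embeddings L x D matrix of per-residue embeddings.
#' @param boundaries Integer segment lengths summing to L (one per chain).
#' @param ids Character ids, one per segment.
#' @export
residue_embedding_sequence <- function(embeddings, boundaries, ids) {
  embeddings <- as.matrix(embeddings)
  if (!all(is.finite(embeddings))) abort("embeddings must be finite.")
  if (sum(boundaries) != nrow(embeddings)) {
    abort("`boundaries` must sum to the number of rows.")
  }
  structure(
    list(embeddings = embeddings, boundaries = as.integer(boundaries),
         ids = as.character(ids)),
    class = "residue_embedding_sequence"
  )
}

#' @export
print.residue_embedding_sequence <- function(x, ...) {
  cat(sprintf("<residue_embedding_sequence> %d residues x %d dims, %d segment(s)\n",
              nrow(x$embeddings), ncol(x$embeddings), length(x$boundaries)))
  invisible(x)
}

#' Residue-embedding interchange files (external adapter contract)
#'
#' Headered TSV holding one residue per row: columns `chain_id`, `pos`, then
#' `e1 ... eD`. Any external per-residue embedding source (for example a
#' protein language model run elsewhere) can hand its output to the
#' aggregator through this format.
#'
#' @param path File path.
#' @return `read_residue_embeddings()`: a `residue_embedding_sequence`;
#'   `write_residue_embeddings()`: `path`, invisibly.
#' @export
read_residue_embeddings <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    chain_id = readr::col_character(), .default = readr::col_double()))
  segs <- rle(tbl$chain_id)
  residue_embedding_sequence(
    as.matrix(tbl[, setdiff(names(tbl), c("chain_id", "pos"))]),
    boundaries = segs$lengths, ids = segs$values)
}

#' @rdname read_residue_embeddings
#' @param res A `residue_embedding_sequence`.
#' @export
write_residue_embeddings <- function(res, path) {
  d <- ncol(res$embeddings)
  tbl <- tibble::as_tibble(res$embeddings, .name_repair = ~ paste0("e", seq_len(d)))
  tbl <- dplyr::bind_cols(
    tibble::tibble(chain_id = rep(res$ids, res$boundaries),
                   pos = unlist(lapply(res$boundaries, seq_len))),
    tbl)
  readr::write_tsv(tbl, path)
  invisible(path)
}
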