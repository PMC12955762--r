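#' Single-chain CA trace
#'
#' A `chain_structure` is the package's unit of 3D structure: one polypeptide
#' chain reduced to its ordered C-alpha trace, together with its one-letter
#' sequence and optional classification labels (fold / superfamily / family /
#' topologies). All downstream machinery — TM-score computation, the geometric
#' residue encoder, the synthetic benchmark generator — consumes this type.
#'
#' @param chain_id Single string chain identifier.
#' @param ca_coords Numeric L x 3 matrix of CA coordinates in Angstrom.
#' @param sequence One-letter residue string of length L, or `NULL` to fill
#'   with `"X"`.
#' @param labels Optional named list with any of `fold`, `superfamily`,
#'   `family`, `topologies` (character vector).
#' @param source Optional provenance string (file path or entry id).
#'
#' @return An object of class `chain_structure`: a list with fields
#'   `chain_id`, `sequence`, `ca_coords`, `labels`, `source`.
#' @export
chain_structure <- function(chain_id, ca_coords, sequence = NULL,
                            labels = NULL, source = NULL) {
  ca_coords <- as.matrix(ca_coords)
  storage.mode(ca_coords) <- "double"
  if (ncol(ca_coords) != 3L || nrow(ca_coords) < 1L) {
    abort("`ca_coords` must be an L x 3 matrix with L >= 1.")
  }
  if (!all(is.finite(ca_coords))) {
    abort("`ca_coords` must be finite.")
  }
  L <- nrow(ca_coords)
  if (is.null(sequence)) sequence <- strrep("X", L)
  if (!is.character(sequence) || length(sequence) != 1L ||
      nchar(sequence) != L) {
    abort("`sequence` must be a single string of length L.")
  }
  if (L > 1L) {
    steps <- sqrt(rowSums((ca_coords[-1L, , drop = FALSE] -
                             ca_coords[-L, , drop = FALSE])^2))
    if (any(steps <= 0)) {
      abort("consecutive CA positions must be distinct.")
    }
  }
  structure(
    list(chain_id = as.character(chain_id), sequence = sequence,
         ca_coords = ca_coords, labels = labels, source = source),
    class = "chain_structure"
  )
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> %s: %d residues\n", x$chain_id,
              chain_length(x)))
  if (!is.null(x$labels)) {
    lab <- x$labels[!vapply(x$labels, is.null, logical(1))]
    if (length(lab)) {
      cat("  labels:",
          paste(names(lab),
                vapply(lab, function(v) paste(v, collapse = ","),
                       character(1)),
                sep = "=", collapse = " "), "\n")
    }
  }
  invisible(x)
}

#' Number of residues in a chain
#' @param chain A `chain_structure`.
#' @return Integer residue count.
#' @export
chain_length <- function(chain) nrow(chain$ca_coords)

#' Multimeric assembly of chains
#'
#' Ordered collection of [chain_structure()] objects with unique chain ids.
#'
#' @param assembly_id Single string identifier.
#' @param chains List of `chain_structure` objects (at least one).
#' @return An object of class `assembly_structure`.
#' @export
assembly_structure <- function(assembly_id, chains) {
  if (!length(chains)) abort("an assembly needs at least one chain.")
  ok <- vapply(chains, inherits, logical(1), "chain_structure")
  if (!all(ok)) abort("all `chains` must be chain_structure objects.")
  ids <- vapply(chains, function(ch) ch$chain_id, character(1))
  if (anyDuplicated(ids)) abort("chain ids must be unique within an assembly.")
  structure(
    list(assembly_id = as.character(assembly_id),
         chains = setNames(chains, ids)),
    class = "assembly_structure"
  )
}

#' @export
print.assembly_structure <- function(x, ...) {
  cat(sprintf("<assembly_structure> %s: %d chain(s), %d residues\n",
              x$assembly_id, length(x$chains),
              sum(vapply(x$chains, chain_length, integer(1)))))
  invisible(x)
}

#' Summarise a set of chains as a tibble
#'
#' One row per chain with id, length and any classification labels, the
#' tabular form consumed by the evaluation module.
#'
#' @param structures Named list of `chain_structure` objects.
#' @return A tibble with columns `id`, `length`, `fold`, `superfamily`,
#'   `family`, `topologies` (comma-separated string; `NA` when unlabeled).
#' @export
structure_metadata <- function(structures) {
  grab <- function(ch, what) {
    v <- ch$labels[[what]]
    if (is.null(v)) NA_character_ else paste(v, collapse = ",")
  }
  tibble::tibble(
    id = vapply(structures, function(ch) ch$chain_id, character(1)),
    length = vapply(structures, chain_length, integer(1)),
    fold = vapply(structures, grab, character(1), "fold"),
    superfamily = vapply(structures, grab, character(1), "superfamily"),
    family = vapply(structures, grab, character(1), "family"),
    topologies = vapply(structures, grab, character(1), "topologies")
  )
}
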