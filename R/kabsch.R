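#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares proper rotation and translation superposing `X` onto `Y`.
#' Reflections are excluded by the determinant correction in the SVD
#' construction, so the returned rotation always has determinant +1 — for a
#' chiral point set and its mirror image the fit is imperfect (rmsd > 0)
#' rather than improper.
#'
#' Points are rows; the fitted transform maps `X` to
#' `X %*% rotation + translation` (see [apply_superposition()]).
#'
#' @param X,Y Numeric N x 3 matrices of corresponding points, N >= 3.
#' @return An object of class `superposition`: list with `rotation` (3 x 3,
#'   proper orthonormal), `translation` (length-3), `rmsd` (Angstrom over the
#'   fitted points).
#' @export
kabsch <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y) || ncol(X) != 3L || ncol(Y) != 3L) {
    abort("`X` and `Y` must be N x 3 matrices with equal N.")
  }
  if (nrow(X) < 3L) abort("Kabsch superposition needs at least 3 points.")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  H <- crossprod(Xc, Yc)
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tr <- cy - drop(cx %*% R)
  dev <- Xc %*% R - Yc
  structure(
    list(rotation = R, translation = tr,
         rmsd = sqrt(mean(rowSums(dev^2)))),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param X Numeric N x 3 matrix (points as rows).
#' @param sp A `superposition` from [kabsch()].
#' @return Transformed N x 3 matrix.
#' @export
apply_superposition <- function(X, sp) {
  sweep(as.matrix(X) %*% sp$rotation, 2L, sp$translation, "+")
}

#' TM-score distance scale d0
#'
#' Length-dependent normalization distance `1.24 * (L - 15)^(1/3) - 1.8`,
#' clamped below at 0.5 Angstrom (the raw formula is negative for L <= 15).
#'
#' @param L Integer chain length(s), L >= 1.
#' @return d0 in Angstrom, vectorised over `L`.
#' @export
tm_d0 <- function(L) {
  if (any(L < 1)) abort("`L` must be >= 1.")
  x <- L - 15
  raw <- 1.24 * sign(x) * abs(x)^(1 / 3) - 1.8
  pmax(raw, 0.5)
}

#' TM-score of a fixed superposition
#'
#' Evaluates the TM-score functional
#' \deqn{TM = \frac{1}{L_{norm}} \sum_i \frac{1}{1 + (d_i / d_0(L_{norm}))^2}}
#' over the corresponding residue pairs after applying `sp` to the query
#' coordinates. No optimisation is performed; see [tm_score()] for the
#' maximised score.
#'
#' @param query,target `chain_structure` objects.
#' @param correspondence Integer matrix with two columns (query index, target
#'   index), 1-based.
#' @param sp A `superposition` applied to the query.
#' @param normalize_by `"query"` or `"target"`: whose length L_norm
#'   normalizes the score.
#' @return TM-score in (0, 1].
#' @export
score_at_superposition <- function(query, target, correspondence, sp,
                                   normalize_by = c("query", "target")) {
  normalize_by <- match.arg(normalize_by)
  correspondence <- as_correspondence(correspondence)
  if (nrow(correspondence) == 0L) abort("`correspondence` must be non-empty.")
  P <- apply_superposition(query$ca_coords[correspondence[, 1L], , drop = FALSE], sp)
  Q <- target$ca_coords[correspondence[, 2L], , drop = FALSE]
  d2 <- rowSums((P - Q)^2)
  L_norm <- if (normalize_by == "query") chain_length(query) else chain_length(target)
  d0 <- tm_d0(L_norm)
  sum(1 / (1 + d2 / d0^2)) / L_norm
}

as_correspondence <- function(correspondence) {
  m <- as.matrix(correspondence)
  if (ncol(m) != 2L) abort("`correspondence` must have two columns.")
  storage.mode(m) <- "integer"
  m
}

#' Identity residue correspondence
#'
#' Index correspondence `i <-> i` over the first `min(L1, L2)` residues, the
#' default pairing for equal-length homologs and for all synthetic benchmark
#' structures (which are built with positional correspondence).
#'
#' @param query,target `chain_structure` objects.
#' @return Integer matrix with columns `query`, `target`.
#' @export
identity_correspondence <- function(query, target) {
  n <- min(chain_length(query), chain_length(target))
  cbind(query = seq_len(n), target = seq_len(n))
}
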