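#' Specification of a toy fold
#'
#' An ordered list of secondary-structure elements plus packing information.
#' Structured elements (helix, strand) are built on textbook CA geometry and
#' rigidly placed at the given offsets with orientations drawn from
#' `packing_seed`; coil elements act as linkers between their flanking
#' structured elements.
#'
#' @param elements Data frame with columns `kind` (`"helix"`, `"strand"`,
#'   `"coil"`) and `length` (residues, >= 3); total length >= 10.
#' @param packing_seed Integer seed controlling element orientations.
#' @param offsets Numeric matrix (one row per structured element, 3 columns,
#'   Angstrom), or `NULL` to auto-place elements ~13 A apart along a seeded
#'   random walk.
#' @return An object of class `fold_spec`.
#' @export
fold_spec <- function(elements, packing_seed = 1L, offsets = NULL) {
  elements <- tibble::as_tibble(elements)
  if (!all(c("kind", "length") %in% names(elements))) {
    abort("`elements` needs columns `kind` and `length`.")
  }
  if (!all(elements$kind %in% c("helix", "strand", "coil"))) {
    abort("element kinds must be helix, strand or coil.")
  }
  if (any(elements$length < 3L)) abort("element lengths must be >= 3.")
  if (sum(elements$length) < 10L) abort("total fold length must be >= 10.")
  n_struct <- sum(elements$kind != "coil")
  if (!is.null(offsets)) {
    offsets <- as.matrix(offsets)
    if (nrow(offsets) != n_struct || ncol(offsets) != 3L) {
      abort("`offsets` must have one row per structured element and 3 columns.")
    }
  } else if (n_struct > 0L) {
    offsets <- withr::with_seed(packing_seed, {
      pos <- matrix(0, n_struct, 3L)
      for (k in seq_len(n_struct)[-1L]) {
        repeat {
          step <- random_unit_vector() * stats::runif(1, 12, 15)
          cand <- pos[k - 1L, ] + step
          d <- sqrt(rowSums(sweep(pos[seq_len(k - 1L), , drop = FALSE], 2L,
                                  cand)^2))
          if (all(d > 10)) break
        }
        pos[k, ] <- cand
      }
      pos
    })
  }
  structure(
    list(elements = elements, packing_seed = as.integer(packing_seed),
         offsets = offsets),
    class = "fold_spec"
  )
}

# canonical CA helix: rise 1.5 A/residue, 100 deg/residue, radius 2.3 A
helix_trace <- function(len) {
  t <- seq_len(len) - 1L
  theta <- t * 100 * pi / 180
  cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * t)
}

# near-linear zig-zag strand, 3.3 A rise, +/- 0.9 A lateral alternation
strand_trace <- function(len) {
  t <- seq_len(len) - 1L
  cbind(0.9 * (-1)^t, rep(0, len), 3.3 * t)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# uniform random proper rotation from a quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3L, 3L, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Interior points of a bent linker between p0 and p1. The linker is a
# circular arc through both endpoints, sampled at equal angle, so every
# consecutive chord has exactly the same length c. The per-step angle phi
# solves sin(m*phi/2) = (gap/c) * sin(phi/2) with m = n_pts + 1 segments,
# which has a solution whenever gap < m*c; when the gap needs (nearly)
# straight steps the straight-line interpolation is used instead.
coil_linker <- function(p0, p1, n_pts, step = 3.8) {
  if (n_pts < 1L) return(NULL)
  gap <- sqrt(sum((p1 - p0)^2))
  m <- n_pts + 1L
  if (gap >= step * m * 0.999) {
    # straight interpolation; chords gap/m are within a hair of `step`
    t <- seq_len(n_pts) / m
    return(outer(1 - t, p0) + outer(t, p1))
  }
  axis <- (p1 - p0) / max(gap, 1e-9)
  u <- random_unit_vector()
  u <- u - sum(u * axis) * axis
  while (sqrt(sum(u^2)) < 1e-6) {
    u <- random_unit_vector()
    u <- u - sum(u * axis) * axis
  }
  u <- u / sqrt(sum(u^2))
  f <- function(phi) sin(m * phi / 2) - (gap / step) * sin(phi / 2)
  phi <- stats::uniroot(f, c(1e-9, 2 * pi / m - 1e-9), tol = 1e-12)$root
  theta <- m * phi
  R <- step / (2 * sin(phi / 2))
  mid <- (p0 + p1) / 2
  centre <- mid - u * sqrt(max(R^2 - (gap / 2)^2, 0))
  e1 <- (p0 - centre) / R
  e2 <- ((p1 - centre) / R - cos(theta) * e1) / sin(theta)
  k <- seq_len(n_pts)
  outer(rep(1, n_pts), centre) +
    R * (outer(cos(k * phi), e1) + outer(sin(k * phi), e2))
}

#' Generate an idealized CA trace from a fold spec
#'
#' Builds each structured element on canonical geometry (helix: 1.5 A rise,
#' 100 degrees and 2.3 A radius per residue; strand: 3.3 A-rise zig-zag),
#' orients it with a rotation drawn from the spec's packing seed, places it
#' at the spec's offset, and joins consecutive structured elements with bent
#' coil linkers sized so that every consecutive CA-CA distance stays in
#' \[3.2, 4.2\] A. Coil elements in the spec set the minimum linker length at
#' their junction; the linker is extended automatically when the spatial gap
#' requires more residues.
#'
#' @param spec A [fold_spec()].
#' @param rng_seed Integer seed for the sequence draw and linker bending.
#' @return A [chain_structure()] with attribute `element_ids` (integer per
#'   residue: index of the structured element, 0 for linker residues).
#' @export
generate_fold <- function(spec, rng_seed = 1L) {
  if (!inherits(spec, "fold_spec")) abort("`spec` must be a fold_spec.")
  el <- spec$elements
  struct_idx <- which(el$kind != "coil")
  if (!length(struct_idx)) abort("spec must contain at least one structured element.")

  orientations <- withr::with_seed(spec$packing_seed, {
    lapply(seq_along(struct_idx), function(i) random_rotation())
  })

  withr::with_seed(rng_seed, {
    placed <- vector("list", length(struct_idx))
    for (i in seq_along(struct_idx)) {
      k <- struct_idx[i]
      tr <- if (el$kind[k] == "helix") helix_trace(el$length[k])
            else strand_trace(el$length[k])
      tr <- sweep(tr, 2L, colMeans(tr))
      placed[[i]] <- sweep(tr %*% orientations[[i]], 2L, spec$offsets[i, ], "+")
    }
    # coil lengths between structured elements (sum of intervening coils)
    linker_len <- integer(length(struct_idx) - 1L)
    if (length(struct_idx) > 1L) {
      for (i in seq_len(length(struct_idx) - 1L)) {
        between <- el$kind[seq.int(struct_idx[i] + 1L, struct_idx[i + 1L] - 1L)]
        lens <- el$length[seq.int(struct_idx[i] + 1L, struct_idx[i + 1L] - 1L)]
        linker_len[i] <- sum(lens[between == "coil"])
      }
    }
    coords <- placed[[1L]]
    elem_ids <- rep(struct_idx[1L], nrow(placed[[1L]]))
    if (length(struct_idx) > 1L) {
      for (i in seq_len(length(struct_idx) - 1L)) {
        p0 <- coords[nrow(coords), ]
        p1 <- placed[[i + 1L]][1L, ]
        gap <- sqrt(sum((p1 - p0)^2))
        n_min <- max(0L, as.integer(ceiling(gap / 3.8)) - 1L)
        n_pts <- max(linker_len[i], n_min)
        if (n_pts > 0L) {
          link <- coil_linker(p0, p1, n_pts)
          coords <- rbind(coords, link)
          elem_ids <- c(elem_ids, rep(0L, n_pts))
        }
        coords <- rbind(coords, placed[[i + 1L]])
        elem_ids <- c(elem_ids, rep(struct_idx[i + 1L], nrow(placed[[i + 1L]])))
      }
    }
    steps <- sqrt(rowSums((coords[-1L, , drop = FALSE] -
                             coords[-nrow(coords), , drop = FALSE])^2))
    if (any(steps < 3.0 | steps > 4.4)) {
      abort("generated trace violates CA-CA spacing; adjust element offsets.")
    }
    chain <- chain_structure(
      chain_id = "A",
      ca_coords = coords,
      sequence = random_sequence(nrow(coords))
    )
    attr(chain, "element_ids") <- elem_ids
    chain
  })
}

random_sequence <- function(L) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L, replace = TRUE),
        collapse = "")
}

#' Perturb a CA trace with coordinate noise and hinge rotations
#'
#' Creates graded structural variants: isotropic Gaussian noise per CA
#' models within-family variation; rigid rotation of the segment downstream
#' of randomly chosen hinge residues models domain/element rearrangement
#' (remote homology). Sequence and length are preserved.
#'
#' @param x A [chain_structure()].
#' @param coordinate_noise_sd Noise standard deviation per coordinate (A), >= 0.
#' @param hinge_count Number of hinge rotations, >= 0.
#' @param hinge_angle_sd Hinge angle standard deviation in degrees.
#' @param rng_seed Integer seed.
#' @return A perturbed [chain_structure()].
#' @export
perturb_structure <- function(x, coordinate_noise_sd = 0, hinge_count = 0L,
                              hinge_angle_sd = 0, rng_seed = 1L) {
  if (coordinate_noise_sd < 0) abort("`coordinate_noise_sd` must be >= 0.")
  if (hinge_count < 0) abort("`hinge_count` must be >= 0.")
  L <- chain_length(x)
  coords <- x$ca_coords
  withr::with_seed(rng_seed, {
    if (hinge_count > 0L && L >= 4L) {
      lo <- min(max(2L, ceiling(L * 0.15)), L - 2L)
      hi <- max(lo, floor(L * 0.85))
      hinge_range <- seq.int(lo, hi)
      hinges <- hinge_range[sample.int(length(hinge_range), hinge_count,
                                       replace = TRUE)]
      for (h in hinges) {
        angle <- stats::rnorm(1, 0, hinge_angle_sd) * pi / 180
        R <- rotation_about_axis(random_unit_vector(), angle)
        pivot <- coords[h, ]
        down <- seq.int(h + 1L, L)
        if (h < L) {
          coords[down, ] <- sweep(sweep(coords[down, , drop = FALSE], 2L, pivot) %*% R,
                                  2L, pivot, "+")
        }
      }
    }
    if (coordinate_noise_sd > 0) {
      coords <- coords + matrix(stats::rnorm(L * 3L, 0, coordinate_noise_sd), L, 3L)
    }
  })
  out <- chain_structure(x$chain_id, coords, x$sequence,
                         labels = x$labels, source = x$source)
  attr(out, "element_ids") <- attr(x, "element_ids")
  out
}

#' Build a homomeric ring assembly from one chain
#'
#' Places `n_copies` rigid copies of the chain on a ring of the given radius.
#' `"cyclic"` gives exact Cn symmetry (each copy is the previous one rotated
#' by 360/n degrees about the ring axis); `"ring"` keeps the ring positions
#' but re-orients every copy independently (a symmetry-free ring).
#'
#' @param chain A [chain_structure()].
#' @param n_copies Number of subunits, >= 2 (max 26 for chain lettering).
#' @param symmetry `"cyclic"` or `"ring"`.
#' @param radius Ring radius in Angstrom.
#' @param rng_seed Seed (used by `"ring"` orientations).
#' @return An [assembly_structure()] with chains `A`, `B`, ...
#' @export
generate_assembly <- function(chain, n_copies, symmetry = c("cyclic", "ring"),
                              radius = 25, rng_seed = 1L) {
  symmetry <- match.arg(symmetry)
  if (n_copies < 2L) abort("`n_copies` must be >= 2.")
  if (n_copies > 26L) abort("`n_copies` must be <= 26.")
  centered <- sweep(chain$ca_coords, 2L, colMeans(chain$ca_coords))
  base <- sweep(centered, 2L, c(radius, 0, 0), "+")
  chains <- withr::with_seed(rng_seed, {
    lapply(seq_len(n_copies) - 1L, function(j) {
      theta <- 2 * pi * j / n_copies
      Rz <- rotation_about_axis(c(0, 0, 1), theta)
      coords <- if (symmetry == "cyclic") {
        base %*% t(Rz)
      } else {
        pos <- c(radius * cos(theta), radius * sin(theta), 0)
        sweep(centered %*% random_rotation(), 2L, pos, "+")
      }
      chain_structure(LETTERS[j + 1L], coords, chain$sequence,
                      labels = chain$labels)
    })
  })
  asm <- assembly_structure(paste0(chain$chain_id, "_x", n_copies), chains)
  min_d <- min_interchain_distance(asm)
  if (min_d < 2.5) {
    abort(sprintf(
      "inter-chain CA clash (%.2f A < 2.5 A); increase `radius`.", min_d))
  }
  asm
}

min_interchain_distance <- function(asm) {
  n <- length(asm$chains)
  md <- Inf
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      A <- asm$chains[[i]]$ca_coords
      B <- asm$chains[[j]]$ca_coords
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      md <- min(md, sqrt(max(0, min(d2))))
    }
  }
  md
}
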