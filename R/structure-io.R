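#' Read a structure file as CA traces
#'
#' Parses a PDB or mmCIF file (via bio3d) and reduces each polymer chain to
#' its C-alpha trace in author residue order. Only residues possessing a CA
#' atom are retained; alternate locations are resolved to the highest
#' occupancy (ties: first encountered). Insertion-coded residues follow their
#' base residue number.
#'
#' @param path Path to a structure file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension;
#'   `.cif`/`.mmcif` are mmCIF, anything else PDB).
#' @return An [assembly_structure()] with one chain per polymer chain.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
      "mmcif"
    } else {
      "pdb"
    }
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
      else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) abort(paste0("could not parse ", path, " as ",
                                     format, ": ", conditionMessage(e)))
  )
  atoms <- parsed$atom
  ca <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (!nrow(ca)) abort(paste0("no polymer CA atoms in ", path))
  ca$o[is.na(ca$o)] <- 1
  ca$insert[is.na(ca$insert)] <- ""
  chains <- list()
  for (ch in unique(ca$chain)) {
    sub <- ca[ca$chain == ch, , drop = FALSE]
    # altloc: per residue keep highest occupancy, first encountered on ties
    key <- paste(sub$resno, sub$insert)
    keep <- unlist(lapply(split(seq_len(nrow(sub)), factor(key, levels = unique(key))),
                          function(ii) ii[which.max(sub$o[ii])]),
                   use.names = FALSE)
    keep <- sort(keep)
    sub <- sub[keep, , drop = FALSE]
    seq1 <- paste(aa_three_to_one(sub$resid), collapse = "")
    chains[[ch]] <- chain_structure(
      chain_id = ch,
      ca_coords = cbind(sub$x, sub$y, sub$z),
      sequence = seq1,
      source = path
    )
  }
  assembly_structure(
    assembly_id = sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path),
                      ignore.case = TRUE),
    chains = chains
  )
}

aa_three_to_one <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  out
}

#' Write an assembly as a CA-only PDB file
#'
#' Fixed-width ATOM records, one CA per residue, sequential author numbering
#' per chain. Coordinates survive a read/write round trip to within the PDB
#' format's 1e-3 Angstrom resolution.
#'
#' @param assembly An [assembly_structure()] (or a single [chain_structure()],
#'   wrapped automatically).
#' @param path Output file path.
#' @param format Only `"pdb"` is supported.
#' @return `path`, invisibly.
#' @export
write_structure <- function(assembly, path, format = "pdb") {
  if (!identical(format, "pdb")) abort("only PDB output is supported.")
  if (inherits(assembly, "chain_structure")) {
    assembly <- assembly_structure(assembly$chain_id, list(assembly))
  }
  if (!inherits(assembly, "assembly_structure")) {
    abort("`assembly` must be an assembly_structure or chain_structure.")
  }
  lines <- character(0)
  serial <- 0L
  for (ch in assembly$chains) {
    L <- chain_length(ch)
    if (L > 9999L) abort("chain exceeds PDB residue-numbering capacity (9999).")
    aa3 <- aa_one_to_three(strsplit(ch$sequence, "")[[1]])
    cid <- substr(ch$chain_id, 1L, 1L)
    for (i in seq_len(L)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial %% 100000L, aa3[i], cid, i,
        ch$ca_coords[i, 1L], ch$ca_coords[i, 2L], ch$ca_coords[i, 3L]))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

aa_one_to_three <- function(aa1) {
  out <- suppressWarnings(bio3d::aa123(aa1))
  out[is.na(out) | nchar(out) != 3L] <- "UNK"
  out
}

#' Read / write label metadata tables
#'
#' Tab-separated metadata with columns `id`, `fold`, `superfamily`, `family`,
#' `topologies` (comma-separated within the field).
#'
#' @param path File path.
#' @return `read_labels()`: a tibble; `write_labels()`: `path`, invisibly.
#' @export
read_labels <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname read_labels
#' @param labels Data frame of label metadata.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(tibble::as_tibble(labels), path)
  invisible(path)
}

#' Read / write structure-pair tables
#'
#' Tab-separated pair lists: `id1`, `id2` plus any score columns (`tm_max`
#' etc.), the interchange format between the TM-score labeler, training and
#' evaluation.
#'
#' @param path File path.
#' @return `read_pairs()`: a tibble; `write_pairs()`: `path`, invisibly.
#' @export
read_pairs <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    id1 = readr::col_character(), id2 = readr::col_character(),
    .default = readr::col_double()))
}

#' @rdname read_pairs
#' @param pairs Data frame with at least `id1`, `id2`.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(tibble::as_tibble(pairs), path)
  invisible(path)
}
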