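# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

# random self-avoiding-ish CA walk with plausible step lengths
rand_walk_chain <- function(L, seed, id = "A") {
  withr::with_seed(seed, {
    steps <- matrix(stats::rnorm(3 * (L - 1)), L - 1, 3)
    steps <- steps / sqrt(rowSums(steps^2)) * stats::runif(L - 1, 3.2, 4.0)
    chain_structure(id, rbind(c(0, 0, 0), apply(steps, 2, cumsum)))
  })
}

demo_fold <- function(seed = 8, lengths = c(18, 4, 14)) {
  spec <- fold_spec(
    data.frame(kind = c("helix", "coil", "strand"), length = lengths),
    packing_seed = seed)
  generate_fold(spec, rng_seed = seed + 1L)
}

shared_benchmark <- function() {
  if (is.null(.fixtures$bench)) {
    .fixtures$bench <- generate_benchmark(4, 2, 2, 3, master_seed = 101)
  }
  .fixtures$bench
}

shared_pairs <- function() {
  if (is.null(.fixtures$pairs)) {
    .fixtures$pairs <- benchmark_pairs(shared_benchmark())
  }
  .fixtures$pairs
}

# pair table annotated with the hierarchy level shared by each pair
shared_pairs_with_level <- function() {
  bench <- shared_benchmark()
  md <- bench$labels[, c("id", "family", "superfamily", "fold")]
  p <- dplyr::left_join(shared_pairs(), md, by = c(id1 = "id"))
  p <- dplyr::left_join(p, md, by = c(id2 = "id"), suffix = c("_1", "_2"))
  p$level <- ifelse(p$family_1 == p$family_2, "family",
             ifelse(p$superfamily_1 == p$superfamily_2, "superfamily",
             ifelse(p$fold_1 == p$fold_2, "fold", "cross")))
  p
}

# the mini model trained on the shared benchmark (used by training and
# acceptance tests); one training run per session
shared_model <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- train_model(
      shared_benchmark()$structures, shared_pairs(),
      encoder_cfg = encoder_config(),
      aggregator_cfg = mini_aggregator_config(),
      training_cfg = training_config(seed = 42L))
  }
  .fixtures$model
}

tiny_pdb_text <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.500   2.500   3.200  1.00  0.00           C",
    "ATOM      4  CA  SER A   3       7.800   3.100   4.000  1.00  0.00           C",
    "TER",
    "END")
}

tiny_cif_text <- function() {
  c("data_tiny",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 1.000 2.000 3.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 4.500 2.500 3.200 1.00 0.00 ? 2 GLY A CA 1",
    "ATOM 3 C CA . SER A 1 3 ? 7.800 3.100 4.000 1.00 0.00 ? 3 SER A CA 1")
}

random_proper_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

rigid_move <- function(chain, R, t) {
  out <- chain
  out$ca_coords <- sweep(chain$ca_coords %*% R, 2, t, "+")
  out
}
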