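---
title: "Structure embeddings for similarity search: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure embeddings for similarity search: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Alignment-based structure comparison (TM-score-style superposition) is
accurate but quadratic in practice: an all-versus-all search over a large
structure repository is prohibitive, and even a single query against
millions of entries is slow. foldvec implements the embedding alternative:
each chain (or assembly) is mapped once to a fixed-length vector, trained so
that the **cosine similarity of two embeddings approximates the TM-score of
the underlying structures**. Retrieval then reduces to (approximate)
nearest-neighbour search in vector space, which is sub-linear and scales to
very large collections.

The package contains the full loop at desk scale: a TM-score engine used as
the labelling oracle, a synthetic structure generator that stands in for a
fold-classification corpus, the embedding network and its twin-network
training, the retrieval benchmark statistics, and an exact + HNSW vector
index.

# TM-score engine

For chains $q$, $t$ and a residue correspondence $\{(i, j)\}$, the TM-score
at a rigid superposition is

$$\mathrm{TM} = \frac{1}{L_{\mathrm{norm}}} \sum_{(i,j)}
  \frac{1}{1 + (d_{ij}/d_0(L_{\mathrm{norm}}))^2},
\qquad d_0(L) = \max\{0.5,\; 1.24\,(L-15)^{1/3} - 1.8\}\ \text{Å},$$

with $d_{ij}$ the post-superposition CA–CA distance and $L_{\mathrm{norm}}$
the length of the normalizing chain. Both normalizations are computed;
`tm_max` (the larger) is the canonical label used everywhere downstream.

The score is maximized over superpositions with the classic fragment-seed
strategy: contiguous windows of the correspondence are superposed by the
Kabsch algorithm (proper rotations only — the SVD determinant correction
excludes reflections), then refined by alternating "keep pairs with
$d_i < d_\mathrm{cut}$ / re-superpose on the kept set" until the kept set is
stable, sweeping $d_\mathrm{cut}$ over $d_0 + \{0.5, 1.5, 2.5, 3.5\}$ Å. The
all-pair superposition is always among the candidates, so the result is
never below the global least-squares fit.

**Seed windows.** For long correspondences the seeds are windows of length
$L$, $L/2$, $L/4$ (minimum 4) at stride $\max(1, L/20)$. For short
correspondences (≤ 20 pairs) the engine enumerates *every* window of length
≥ 3 at stride 1 instead. This is a deliberate design point: short-chain
TM-scores are dominated by small windows that superpose almost perfectly
(with $d_0$ clamped at 0.5 Å a 3-residue exact match already contributes
heavily), and the sparse ladder provably misses them — we measured gaps of
up to 0.56 TM units between the ladder and exhaustive enumeration on random
10-residue chains. Exhaustive seeding is essentially free at these lengths
and makes the engine agree with an independent exhaustive-maximization
oracle to better than 1e-9, which the test suite asserts on 200 random
pairs.

**Correspondence is an input, not inferred.** Sequence-independent alignment
(dynamic programming over structures) is out of scope; the synthetic data
guarantee positional correspondence by construction, and for real
equal-length homologs the positional identity correspondence is the default.
The hot loop (Kabsch + refinement) is implemented in C++ (RcppArmadillo);
the R reference formulation of the same computation lives in the test
helpers as the oracle.

**Assemblies** are compared by concatenating chains under a one-to-one chain
mapping and scoring with identity correspondence. `best_permutation`
exhaustively maximizes `tm_max` over chain permutations (≤ 8 chains), which
resolves the chain-order ambiguity of symmetric homomers.

# Synthetic benchmark generator

The generator emulates the *statistical shape* of a fold/superfamily/family
classification, not protein physics. Structured elements use textbook CA
geometry — helices as a spiral with 1.5 Å rise, 100°/residue and 2.3 Å
radius (3.83 Å between consecutive CAs), strands as 3.3 Å-rise zig-zags —
rigidly placed at packing offsets and joined by bent coil linkers sized so
every consecutive CA–CA distance stays in [3.2, 4.2] Å.

The hierarchy is built by graded perturbation with **oracle-calibrated
rejection**: each derived structure is resampled until its TM-score to its
parent falls in a target band,

* member → family parent: coordinate noise (sd 0.35 Å), band **[0.82, 0.97]**;
* family parent → superfamily parent: one hinge rotation (sd 40°) plus mild
  noise, band **[0.60, 0.78]**;
* superfamily parent → fold base: two hinges (sd 55°), band **[0.40, 0.58]**;
* different folds: independently drawn element lists and packings, giving
  background TM ≈ 0.15–0.25.

These bands are the package's study conditions; on the default
`generate_benchmark(4, 2, 2, 3)` set they yield mean TM of ≈ 0.95 within
families, ≈ 0.57 within superfamilies, ≈ 0.41 within folds and ≈ 0.18 across
folds — monotonically separated with gaps well above 0.05, which the tests
assert. Sequences are drawn per family and members are mutated at 5% of
positions, so within-family identity stays ≥ 90% while cross-family pairs
share background identity only.

Homomeric assemblies place rigid copies of a chain on a ring (exact cyclic
symmetry, or independently re-oriented copies), with a 2.5 Å inter-chain
clash guard. Two rings of the *same* subunit at radii differing by ≥ 2× have
assembly TM < 0.5 — the canonical false-positive regime for
concatenation-based assembly embeddings (below).

What the generator does **not** emulate: real secondary-structure packing
statistics, sequence–structure coupling, domain insertions, length/family
size distributions of curated corpora. Passing tests demonstrate that the
machinery (labelling, training, retrieval, statistics) is correct and that
the model can learn graded structural similarity; they say nothing about
absolute performance on PDB-scale data.

# Embedding model

**Residue encoder.** The frozen per-residue encoder plays the role a large
protein language model plays in production systems. The built-in geometric
encoder collects, per residue: CA–CA distances to the ±1…±16 neighbours
along the chain (zero-padded at the ends, scaled by 1/10), the cosine/sine
of the pseudo-bond angle and pseudo-dihedral of the trace, and an 8-d seeded
residue-type embedding; a fixed random linear map projects these to
`d_in = 32` dimensions. The window half-width of 16 was fixed at design time
by sweeping generator seeds: distances spanning up to 16 residues reach
across element boundaries, which narrower windows miss, and the wider window
made training recovery consistent across seeds. Every feature is an internal distance or angle, so
the encoding is invariant to global rigid motion. The encoder is
deliberately *not* trained (mirroring frozen-PLM practice); external
per-residue embeddings of any provenance can be substituted through the
headered-TSV adapter (`read_residue_embeddings()`).

**Aggregator.** A linear input projection, `n` transformer encoder layers
*without positional encoding* (post-norm; multi-head attention with head
width 32, feedforward with ReLU), **summation pooling** over the residue
axis, and a stack of fully connected residual blocks (two affine layers with
ReLU and identity skip). No positional information plus sum pooling makes
the output exactly permutation-invariant over input rows. The production
preset (6 layers, width 1536, FF 3072, 12 residual blocks) has ~172M
trainable parameters, audited analytically by `count_parameters()`; the mini
preset (2 layers, width 64, FF 128, 3 blocks, `d_in` 32) trains on one CPU
in minutes and is used throughout the tests.

Because chains are encoded independently and concatenated before
aggregation, assembly embeddings are invariant to chain order — and,
necessarily, identical subunits arranged in *different* quaternary
geometries receive identical embeddings. This degeneracy is inherent to the
representation, is reproduced as a regression test, and is the main known
failure mode for assembly-level retrieval.

**Numerical notes.** Layer norm uses $\varepsilon = 10^{-5}$; attention
softmax is max-shifted; each chain is processed unbatched, so no padding or
attention masking is needed; permutation invariance holds to float
reordering error (~1e-13 observed, asserted at 1e-4). The forward pass is
verified against an independent straight-line re-implementation, and the
analytic backward pass (attention, layer norm, FF, residual head) against
central finite differences at 1e-5.

# Training

Training follows the twin-network recipe: both structures of a pair pass
through the same weights; the loss is the squared error between the
embeddings' cosine similarity and the pair's **maximum TM-score rounded to
one decimal** (round-half-up, bins {0.0, …, 1.0}; a flag allows regressing
the raw value). Batches are drawn **uniformly over the TM bins present in
the pool** ("quota" mode assigns exact per-bin shares; "multinomial" mode
draws bins independently), countering the heavy skew of pair TM-scores
toward low values. Optimisation is Adam (β₁ 0.9, β₂ 0.999, ε 1e-8) under a
linear warmup (2 epochs, starting from 0) followed by cosine decay to
peak/100. After each epoch the validation AUPRC is computed (positives:
`tm_max ≥ 0.5`, the conventional same-fold threshold; score: cosine) and the
best-epoch weights are kept (ties → earliest).

Desk-scale defaults: 512 pairs/epoch in batches of 32, 15 epochs, peak
learning rate 2e-3, 10% of pairs held out stratified by bin. These sizes
were chosen so a full run on the default 48-structure benchmark (1128
labelled pairs) takes a few minutes on one CPU while converging reliably;
the production-scale analogue (320k pairs/epoch, 100 epochs, 2% validation)
is configuration, not code. On the default benchmark the trained mini model
reaches held-out Spearman correlation ≥ 0.6 between cosine and oracle
`tm_max` and beats the mean-pooling baseline's AUPRC — the qualitative
ordering that motivates the aggregator in the first place. Training is
exactly reproducible from `training_config(seed = )`: sampling, splits and
initialisation all derive from the master seed, single-threaded.

# Evaluation

Three labelling schemes produce TP/FP/ignore per pair: classification at the
family / superfamily / fold level (TP = same family; same superfamily but
different family; same fold but different superfamily — FP = different fold
in all three), TM thresholds (TP at ≥ 0.6/0.7/0.8, FP < 0.5, in-between
ignored), and topology combinations for multidomain chains (TP = identical
topology multisets, FP = disjoint architecture sets).

Per query, targets are ranked by descending score with ties broken by target
id (documented because sensitivity-to-first-FP is tie-sensitive);
**sensitivity to the first FP** is the fraction (and count — both are
reported) of the query's true positives retrieved before the first false
positive, with ignored pairs neither counting nor blocking; queries with no
true positives are skipped. Pooled over unordered pairs, the
precision–recall curve uses step-wise (rectangular) area
$\sum_i (R_i - R_{i-1}) P_i$ with tied scores sharing a threshold — the
conservative convention, asserted against an independent reference
implementation. Scoring pairs by the oracle `tm_max` itself under a
TM-threshold scheme yields AUPRC 1.0 and perfect sensitivity for every
query, the expected degenerate case when the ground-truth generator is also
the scorer.

Redundancy control mirrors standard practice: `build_family_cv_splits()`
partitions *families* (never structures) into k groups, and
`holdout_superfamilies()` withholds ⌈5%⌉ of superfamilies entirely.

# Index

Embeddings are stored L2-normalized (cosine = dot product) in a single text
container with a JSON manifest. `query_exact()` is the deterministic
reference: full scan, ties by id. The HNSW graph (`build_ann_index()`,
M = 16, ef_construction = 200 — library-conventional defaults recorded in
the index object) is implemented in C++ and returns plain R adjacency data,
so indexes serialize with `saveRDS()`. Similarities reported by
`query_ann()` are exact cosines; only the candidate set is approximate.
Recall@10 against the exact reference exceeds 0.95 on a 10,000-vector store
at ef_search = 128, and measured recall is non-decreasing in ef_search.

# Design points that were genuinely open

* **10 vs 11 TM bins.** Rounding any value in [0, 1] to one decimal yields
  exactly the 11 values {0.0, …, 1.0}; bins are defined that way, with
  round-half-up at the boundaries (plus a 1e-9 guard so decimal halves like
  0.15 round up despite binary representation).
* **Cosine clamping.** `similarity()` clamps cosine to [0, 1] when reporting
  a "predicted TM-score"; ranking always uses the raw cosine, so the clamp
  cannot alter any benchmark result.
* **Validation positives.** The AUPRC threshold `tm_max ≥ 0.5` matches the
  FP convention of the benchmark schemes (different folds score < 0.5).
* **Unmodelled residues.** Residues without a CA atom are dropped at parse
  time, not imputed; alternate locations resolve to the highest occupancy
  (ties: first encountered); insertion codes order after their base residue.
* **Fraction vs count** of TPs before the first FP: both are computed per
  query; the fraction is the primary statistic for the sorted sensitivity
  curves because it is comparable across queries with different family
  sizes.
* **Attention masking for padded positions** never arises: chains are
  processed one at a time, unpadded.

# Known limitations

* The geometric encoder is a stand-in: it carries local trace geometry and
  residue identity only, far less than a structure-aware language model.
* Identical-subunit assemblies in different arrangements collide in
  embedding space (by construction; see above).
* TM-score may understate similarity for multidomain chains with hinge
  motions; the engine inherits this property of the score itself.
* The benchmark generator's realism limits any claim about absolute
  retrieval performance on curated corpora; it is built to validate
  machinery and relative orderings.

# Problem sizes used by the tests

The test suite and the acceptance script use the default
`generate_benchmark(4, 2, 2, 3)` corpus (48 structures, 16 families, 1128
pairs), mini-preset training for 15 epochs, 200 random short-chain pairs for
the oracle-equality check, and a 10,000 × 32 store for retrieval — sizes
chosen so the whole loop runs in minutes on a single CPU while exercising
every code path at non-trivial scale.
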