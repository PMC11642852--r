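---
title: "Attention-weighted token graphs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-weighted token graphs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tokengraph)
```

## The model

A genomic language model (gLM) reads a nucleotide sequence as a series of
tokens — non-overlapping k-mers or byte-pair-encoded (BPE) variable-length
words — and, at every layer `l` and head `h` of its transformer, produces an
attention matrix over those tokens. tokengraph turns this by-product into an
explicit graph over the genome:

* **Nodes** are tokens, each carrying `(token_id, token_string, interval)`
  where the interval is the token's genomic span in 0-based half-open
  coordinates.
* **Edge weights** come from attention. Raw scores are converted to
  probabilities by a row-wise softmax and averaged over all `L x H`
  layer/head slices with equal weight:
  `a = (1/LH) * sum_{l,h} softmax_rows(A^{(l,h)})`.
  The mean of row-stochastic matrices is row-stochastic, so each row of `a`
  sums to one and `a[i, j]` reads as the attention-derived probability from
  token i to token j.
* **Edges** are taken from the upper triangle only: for `i < j` the edge
  `(i, j)` with weight `a[i, j]` exists iff `a[i, j] >= theta` (inclusive).
  One entry per unordered pair keeps the graph undirected with no duplicate
  edges; the mirror entry `a[j, i]` is never consulted and is not averaged
  in.
* **Degree filtering**: after thresholding, nodes with fewer than
  `min_degree` neighbors are removed in a single pass (an iterative k-core
  peel is available via `kcore = TRUE` for users who want the stronger
  guarantee that *surviving* degrees also satisfy the bound).

Each FASTA reference becomes one graph. No edges cross chunk or reference
boundaries: the model never attends across a chunk, and interchromosomal
analysis is done by supplying a merged record.

## From FASTA to tokens

Sequences are processed in chunks of `model_max_tokens - n_special_tokens`
nucleotides. Because every token covers at least one nucleotide, this chunk
size can never exceed the model's token budget, whatever the tokenizer; the
cost is some slack for BPE tokenizers whose tokens average more than one
base. Chunks tile each reference exactly (`ceiling(L / chunk_length)` chunks,
last one short).

Cleaning uppercases each chunk and removes every character outside
`{A, C, G, T}`. Soft-masked (lowercase) bases are therefore retained;
`N` and IUPAC ambiguity codes are removed uniformly — nothing in their
semantics distinguishes them for a tokenizer that only accepts ACGT.
Crucially, removed characters still occupy genomic coordinates: the cleaned
chunk carries a `coord_map` from cleaned index to original coordinate, and
token offsets are lifted through it. A token whose bases straddle a removed
run spans the gap, so its interval endpoints are always true genome
positions. Both `start` and `end` are stored and serialized — a node's
"position" is its interval, not a single point.

Segment fetches go through the `.fai` index byte offsets directly, because
the usual sequence containers normalize soft-masked bases to uppercase and
the raw-segment contract here is byte-exact.

## Attention providers and the offline mock

Any provider that maps token ids to an `L x H x m x m` tensor can back the
pipeline. The built-in mock emulates a transformer deterministically: each
score hashes `(seed, layer, head)` together with the token identities and
positions of the `(i, j)` pair through multiplicative-congruential mixing
(multiplier 69069, modulus 2^32, carried exactly in doubles so results are
bit-identical across platforms). The identity component gets weight 0.75 and
the positional component 0.25, so repeated tokens yield structured,
non-uniform graphs while exact ties remain broken. What the mock does *not*
emulate is any biological or linguistic structure in attention — passing
tests with it demonstrates the pipeline's bookkeeping (coordinates,
normalization, filtering, serialization), not that attention from a real gLM
is informative.

The softmax is applied to provider scores by default even though transformer
attention is typically already normalized; providers that emit probabilities
can set `renormalize = FALSE` (`--no-renormalize` on the command line), which
skips the softmax and only averages. Softmax rows are computed with row-max
subtraction; by shift-invariance the result is unchanged and overflow is
impossible.

## Numerical and design choices

* Coordinates: 0-based, half-open everywhere (BED convention).
* Threshold comparison is inclusive (`>= theta`); ties are kept.
* `theta` lives in `[0, 1]` because aggregated weights are probabilities.
* Degree filtering runs after the per-reference union of chunk graphs;
  since no cross-chunk edges exist this equals filtering each chunk
  (asserted as a test), but the union-first order is what users observe.
* Serialization (GraphML, node-link JSON, TSV) writes doubles with 17
  significant digits, so `read(write(g))` is exactly `g`.
* The k-mer adapter drops a trailing remainder shorter than `k`; the toy
  BPE adapter applies its fixed merge table greedily left-to-right. Both
  exclude special tokens from output — a class or separator token has no
  genomic position, so it can never be a node, and attention rows/columns
  must arrive with special tokens already removed.

## The GCN classifier

For enhancer-promoter interaction (EPI) prediction, each sequence of a pair
is pushed through the full pipeline as a single-reference genome, giving two
token graphs. The classifier is deliberately plain:

1. node features: a learned embedding of `token_id` (width `d = 32`);
2. two graph-convolution layers
   `H' = ReLU(D^-1/2 (A + I) D^-1/2 H W)` with unit self-loops, where `A`
   is the attention-weighted adjacency — edge weights are the pipeline's
   core signal and are not binarized;
3. mean pooling over nodes (permutation- and duplication-invariant);
4. an affine + sigmoid readout on the concatenated pair of graph
   embeddings, ordered (enhancer, promoter) — the readout is not symmetric.

Training minimizes binary cross-entropy with Adam (lr `5e-3`, 50 epochs by
default), one pair per step, all randomness seeded. The learning rate was
chosen for reliable convergence on the synthetic co-occurrence task: at
`1e-3` the embedding table — by far the largest parameter block — moves too
slowly relative to memorization of the small training set, and held-out MCC
scatters widely across seeds, while `5e-3` converges consistently within 50
epochs. A held-out split
(20% by default) is scored by MCC at threshold 0.5 after every epoch and the
best-scoring parameters are returned. The widths, optimizer and schedule are
this package's declared choices; nothing deeper than "a straightforward
2-layer GCN" is claimed for them, and all are arguments of `epi_gcn()`.

MCC is computed as
`(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the standard
convention that a zero factor under the root yields 0. It equals the Pearson
correlation between the binary prediction and truth vectors, which the test
suite verifies exhaustively for every confusion table with at most 12
observations.

## What the synthetic data emulates — and what it does not

All tests and the acceptance script run on generated inputs
(scheme `tg-rng-1`: Mersenne-Twister with inversion sampling, one integer
seed, byte-identical reruns).

`synth_genome()` emulates the awkward mechanics of real references:
multi-record FASTA, line wrapping, soft-masked lowercase runs, and invalid
characters (N-heavy mix of ambiguity codes) at a configurable rate, with a
truth sidecar for coordinate audits. It does not model GC content, repeats,
or any real genomic composition — it exercises bookkeeping, not biology.

`synth_epi_dataset()` emulates an EPI benchmark as motif co-occurrence:
positive pairs carry an enhancer-like element in `seq_a` *and* a
promoter-like element in `seq_b`; negatives carry at most one (one of
a-only / b-only / neither, uniformly). The defaults are chosen so the signal
is strong by construction, in a way that is transparent about how k-mer
tokenization sees it:

* each planted element is 29 nt long. A length of `6q + 5` yields exactly
  `q` complete in-frame 6-mers regardless of the planting frame, so every
  planted copy contributes exactly 4 motif tokens — the class signal has no
  frame jitter;
* positives plant 4 copies per sequence in disjoint slots (regulatory
  elements are typically clusters of binding sites, and disjoint placement
  keeps the per-sequence motif-token count exact);
* by default sequences are 5,000 nt, the EPI benchmark setting; tests and
  the acceptance script use 300 nt so a training run takes tens of seconds
  on one CPU.

Chance occurrences of motif 6-mers in uniform background exist (about 0.3
expected per 300-nt sequence and motif: 24 distinct 6-mer substrings against
50 token draws from a 4096-word vocabulary) and are the irreducible noise
floor of the task. Because planted counts are exact, a margin of several tokens
separates the classes, and the learned solution only has to approximate a
linear rule in the two motif-token counts with an AND-like threshold.
Passing the learning check therefore shows that the pipeline's graphs
preserve token identity and that the GCN can extract a planted
co-occurrence — it says nothing about real enhancer-promoter biology, real
gLM attention, or benchmark MCC values, which require external data and
pretrained models and are explicitly out of scope.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` use: 200 random references up to
2,000 nt for tiling laws; 2,500–3,000 nt genomes with 5–10% invalid
characters for coordinate soundness; brute-force edge-rule equivalence up to
m = 12 tokens; 50–100 random graphs/tensors for round-trip and conservation
properties; and 200 pairs x 300 nt x 3 seeds for the learning check. These
sizes were picked so the whole suite runs in a few minutes on a single CPU
while every law is still exercised across its edge cases (empty references,
empty graphs, all-invalid chunks, isolated nodes, ties at the threshold).

## Known limitations

* The hub adapters for real tokenizers/models are interface stubs by
  design; only the offline adapters ship. Wiring a real gLM means
  implementing the two provider contracts documented in
  `?mock_attention_provider` and `?kmer_tokenizer`.
* Degree filtering defaults to the literal single pass; a node can survive
  with fewer than `min_degree` neighbors *after* filtering (use
  `kcore = TRUE` if that matters for your analysis).
* The HTTP server is single-threaded, one request per connection, intended
  for local exploration only.
* `epi_gcn()` converges on the synthetic task in minutes but is a reference
  implementation; GPU-scale training on real benchmarks is out of scope.
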