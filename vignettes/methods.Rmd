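---
title: "Predicting RNA secondary structure with a dense encoder-decoder network and constrained decoding"
author: "rnafoldnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RNA secondary structure with a dense encoder-decoder network and constrained decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnafoldnet)
```

## The problem

The secondary structure of an RNA — the set of hydrogen-bonded base pairs,
abstracted from three-dimensional geometry — governs much of its stability
and function. Classical predictors minimize a thermodynamic free energy by
dynamic programming, which costs $O(N^3)$ for nested structures and becomes
impractical for structures with *pseudoknots* (crossing pairs
$i_1 < i_2 < j_1 < j_2$ with pairs $(i_1, j_1), (i_2, j_2)$).

`rnafoldnet` takes the learning route: a convolutional encoder–decoder
network scores every candidate base pair of a sequence at once, and a
constrained-optimization decoder extracts a feasible pair set from the score
map. Because the decoder is an optimization over arbitrary pair sets rather
than a nested-structure recursion, pseudoknots come for free.

## Input encoding

A sequence $B = (b_1, \dots, b_L)$ over $\{A, C, G, U\}$ is encoded as a
stack of binary $L \times L$ *contact matrices*:

* **10 dinucleotide channels** — one per unordered base pair
  ($\{AU, UA\}$ share a channel, etc.; $\binom{4}{2} + 4 = 10$). Channel
  $c$ holds a 1 at $(i, j)$ iff $\{b_i, b_j\}$ falls in class $c$.
* **136 tetranucleotide channels** — one per unordered pair of consecutive
  dimers ($\binom{16}{2} + 16 = 136$), built from the dimer starting at
  each position. The terminal position uses the wrap dimer
  $(b_L, b_1)$, which keeps the encoding well-defined on the last
  row/column and compatible with circular RNAs.

Together: a $146 \times L \times L$ binary tensor (stored channel-last in R,
`dim = c(L, L, 146)`). For any cell, exactly one dinucleotide and one
tetranucleotide channel are hot, and every channel slice is symmetric — the
test suite asserts both as invariants. Channel order is frozen
(lexicographic over sorted class members) so saved models stay portable.
Diagonal cells are encoded like any other; the network can learn to ignore
them, and the decoder's separation constraint excludes them regardless.
Length-1 sequences are accepted with a warning (the wrap dimer degenerates
to $(b_1, b_1)$). Strict input validation rejects non-ACGU characters; a
lenient mode maps T→U and carries other IUPAC codes as `N`, which receive
no feature channel.

## Network

The scoring network is a fusion of the fully-convolutional DenseNet
("Tiramisu") segmentation design with residual skip connections:

* **BCM** (basic convolution module): convolution → batch normalization →
  ReLU.
* **Feature extraction**: three BCMs condense the sparse 146-channel input
  to a 16-channel feature map.
* **Encoder**: at each of 4 levels, a **DCM** (dense connected module — a
  BCM stack where each layer receives the concatenation of the block input
  and all preceding layer outputs; the block output includes the input) is
  followed by a transition down (1×1 BCM, then 2×2 max pooling).
* **Bottleneck** DCM, then a mirrored **decoder**: transition up
  (nearest-neighbour 2× upsampling + BCM), a *residual skip-add* of the
  same-size encoder map, and a DCM whose output keeps only the new maps.
* **Head**: 1×1 projection to a single raw $L \times L$ map, which is added
  to its own transpose and batch-normalized. Because that normalization is
  elementwise-uniform, the output score map is exactly symmetric for any
  weights — an invariant the tests check at lengths up to 720.

Defaults (all configurable through `network_config()`): 16 feature
channels, 3-layer DCMs with growth 16, 4 levels, 3×3 kernels — 39
convolutions end to end. Inputs are zero-padded to a multiple of
$2^{\text{levels}}$ and cropped back after the head; sequences longer than
`max_length` (default 720) are refused with an explicit error rather than
truncated. Maps are processed one sequence at a time, so variable lengths
need no batching mask; batch-norm statistics are per-map during training
and running averages at inference.

The layers (convolution via the shift decomposition onto BLAS matrix
products, batch norm, pooling, upsampling) and their backward passes are
implemented in the package; the test suite verifies every analytic gradient
against central finite differences at several depths of the network.

## Decoding as constrained optimization

The decoder selects a binary contact map $P$ maximizing

$$\langle S, P\rangle - \rho\,\lVert P\rVert_1
\quad \text{s.t.} \quad \tfrac{1}{2}(P + P^T)\mathbf{1} \preceq \mathbf{1},
\quad P \in \Omega,$$

where $\Omega$ restricts support to *admissible* cells: canonical
Watson–Crick ($A\!\cdot\!U$, $C\!\cdot\!G$) or wobble ($G\!\cdot\!U$) pairs
at separation $|i - j| \ge 4$. The $\ell_1$ term is implemented as a
*sparsity penalty* (its stated purpose); `rho` may be set negative to
recover the reward-signed variant of the same program. The row-sum
constraint enforces at most one partner per base.

The relaxed program ($P \in [0,1]^{L\times L}$) is solved by projected
gradient ascent on $P$ against nonnegative multipliers $\lambda_i$ on the
row sums: each sweep takes a gradient step on
$S - \rho - (\lambda_i + \lambda_j)$, re-symmetrizes, clips to the box,
zeroes off-mask cells, then updates
$\lambda \leftarrow \max(0, \lambda + \beta\,(P\mathbf{1} - \mathbf{1}))$.
Rounding is threshold-plus-greedy: cells at or above the threshold
(default 0.5) are accepted in descending relaxed value (ties to the
smallest $(i,j)$), skipping any cell that conflicts with an accepted one.
Feasibility of the output therefore never depends on convergence.

**Numerical choices.** Constant steps of 0.1 (primal) and 0.05 (dual) for
400 sweeps. These were frozen after a quality study against an exhaustive
oracle on random small instances: on $L \le 12$ the decoded integer
objective reaches within 1% of the true optimum in ≥ 98% of instances
across independent seed sets, and constant steps outperformed
diminishing-step schedules there. The exhaustive oracle itself
(`brute_force_optimum`, a branch-and-bound over positive-weight admissible
pairs — the integer program is a maximum-weight matching with weight
$2(s_{ij} - \rho)$ per pair) is cross-checked in the tests against an
independent bitmask dynamic program.

Because nothing in the program forbids crossing pairs, instances whose
optimum is pseudoknotted decode correctly; the tests construct such a
witness and verify both crossing pairs are returned, which no nested-only
decoder could do.

## Evaluation metrics

Counting is **per base**, not per cell. For each base: TP if paired in both
reference and prediction *with the same partner*; TN if unpaired in both;
FP if unpaired in the reference but paired in the prediction; FN if paired
in the reference and unpaired *or wrongly partnered* in the prediction —
note a wrongly partnered reference base is FN only, never also FP
(conventions differ between tools, so this is worth stating). Then

$$\mathrm{ACC} = \frac{TP + TN}{TP+TN+FP+FN},\quad
\mathrm{SEN} = \frac{TP}{TP+FN},\quad
\mathrm{PPV} = \frac{TP}{TP+FP},\quad
F = \frac{2}{1/\mathrm{SEN} + 1/\mathrm{PPV}}.$$

Undefined ratios (zero denominators) are reported as 0 with an explicit
flag. Aggregation across sequences is micro-averaged (counts pooled before
ratios), with a macro option. Partner matching is exact — no ±1 slack.
`crossval_split()` provides seed-deterministic k-fold partitions with fold
sizes differing by at most one.

## Training

The training objective is not part of the published method description, so
the package declares its own: class-weighted binary cross-entropy of the
sigmoid-transformed scores against the reference contact map, restricted to
upper-triangle cells at separation ≥ 4 (the only cells the decoder could
ever select). Paired cells are rare (about $L/2$ of $\sim L^2/2$ valid
cells), so positives are up-weighted by valid/positive count, capped at
300; the weight can be fixed instead. Optimization is Adam
(default $10^{-3}$), seeded mini-batches, one map per forward pass;
records over `max_length` are skipped with a warning. Model selection
tracks a decoded micro F-score on a monitoring set every few epochs, and
the best weights are kept (optionally checkpointed together with the
configuration and a training log).

## Synthetic corpora

`simulate_corpus()` generates offline test corpora that are feasible *by
construction*: recursively placed nested stems with hairpin loops of at
least 3 unpaired bases (so every pair satisfies $|i-j| \ge 4$ — the
operational separation rule, chosen over the looser prose convention
precisely so the generator can never emit a structure the decoder forbids),
and, with configurable probability, one H-type crossing stem pair placed
first with nested stems filled into the remaining gaps. Paired positions
draw from $\{AU, CG\}$ plus wobble $GU$ at a configurable fraction
(default 0.1); unpaired positions are uniform. Corpora are byte-identical
functions of the seed.

These fixtures exercise code paths; they do not mimic the family
composition, length distribution, or sequence statistics of curated
databases. A passing training-sanity check on them demonstrates that the
encoder, network, gradients, decoder, and metrics compose into a system
that can learn structure from sequence — it says nothing about accuracy on
real RNA families, which requires training at full scale on curated data.

## Problem sizes used by the checks

The package's own verification runs at desk scale, chosen once: decoder
feasibility on 1000 random instances ($L \in [20, 80]$); decoder
near-optimality on 200 instances ($L \le 12$) against the exhaustive
oracle; network contracts at $L \in \{17, 64, 100, 720\}$; the training
sanity check on 30 generated records of length 24–48 with a reduced
configuration (16 feature channels, 2 levels, 2-layer DCMs, growth 8) for
at most 200 epochs with early stopping once the training F-score reaches
0.95 — small enough for a single CPU, large enough that an untrained or
miswired network cannot pass; and format round-trips on 1000 generated
records. `scripts/acceptance.R` recomputes all of these from scratch.

## Known limitations

* No pretrained weights ship with the package; training is the user's task,
  and reproducing published benchmark accuracies requires the full curated
  corpora and long training runs.
* The decoder is approximate: near-optimal with high empirical frequency,
  never below feasibility, but without a per-instance optimality
  certificate.
* Scores are consumed as raw network outputs (no sigmoid) — the scale of
  `rho` is therefore coupled to the score scale; an affine shift of the
  scores changes the effective sparsity.
* Per-map batch normalization means training statistics depend on sequence
  length composition; floating-point reduction order makes bit-exact
  reproducibility hardware-specific, though seeds fix everything
  algorithmic.
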