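---
title: "Compressing sequences with partition Markov models and canonical Huffman codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressing sequences with partition Markov models and canonical Huffman codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmmcodec)
```

## The problem

A lossless compressor built on a Markov model transmits two things: a
description of the model (its order and the transition frequencies that the
receiver needs to rebuild the codebooks) and the coded data. Given the
model, conditional Huffman coding is optimal for the data part; the model
part, however, grows linearly in the number of states, `|A|^o`, and quickly
dominates the output for higher-order chains on small samples. DNA is the
motivating case: a genome of thirty thousand bases modelled at order 3 over
`{a, c, g, t}` already needs 64 conditional laws, and a gapped order-3 model
(see below) needs 256.

A **partition Markov model** (PMM) attacks exactly this overhead. States
`s, r` are grouped into the same *part* `L` when they share a conditional
law, `P(a | s) = P(a | r)` for every symbol `a`. The chain's parameters then
reduce to one probability row per part, `(|A| - 1)|L|` numbers instead of
`(|A| - 1)|A|^o`, and the transmitted model shrinks accordingly — at the
price of also transmitting *which* part each state belongs to, itself coded
compactly with a canonical Huffman code on the part sizes.

## Model estimation

For a sample `x` of length `n`, `N(s, a)` counts occurrences of state `s`
followed by symbol `a`; part-level counts are sums over member states. The
partition is selected by maximising the Bayesian Information Criterion

```
BIC(L, x) = ln ML(L, x) - (|A| - 1) |L| / 2 * ln(n),
```

where `ln ML` is the log pseudo-likelihood `sum N(L, a) ln(N(L, a)/N(L))`.
`bic_value()` computes this decomposition exactly; parts with zero counts
contribute no likelihood term and are not counted in `|L|` in the penalty.

`estimate_partition()` maximises the BIC by greedy agglomeration: starting
from singleton parts over the observed states, it repeatedly merges the
pair of parts with the largest strictly positive BIC gain and stops when no
merge improves the criterion. Merging two parts with identical empirical
rows always gains (the likelihood is unchanged while the penalty drops by
`(|A| - 1)/2 ln n`), so redundant states are absorbed. The procedure is
deterministic: ties in the merge gain are broken towards the pair with the
smallest part indices. The precise clustering algorithm was a genuinely
open design point; greedy pairwise agglomeration was chosen because it is
deterministic, `O(|S|^3 |A|)` in the worst case (entirely adequate for
`|S| <= 256`), and satisfies the selection criterion's required behaviour.
`exhaustive_partition_search()` enumerates all set partitions for small
state spaces and is used as the test oracle. Two guard rails hold by
construction: the returned BIC is at least that of the singleton partition
and at least that of the single-part partition (the latter is checked
explicitly and substituted if it wins).

Unobserved states carry no information about the law; they are excluded
from estimation and the penalty, flagged on the result, and attached to the
part with index 1 for serialisation, because a decoder needs a total map
from states to parts. This is an implementation convention, not something
the estimation theory dictates.

### Entropy and the minimum codeword rate

The entropy rate of a stationary PMM in base `D` is
`-sum_L P(L) sum_a P(a|L) log_D P(a|L)` (`entropy_closed_form()`); for a
fitted model the plug-in estimate is `-ln ML(L, x) / (n ln D)`
(`entropy_plugin()`), which is algebraically identical to weighting each
part's empirical entropy by `N(L)/n`. This quantity is also the estimated
minimum expected codeword length per symbol achievable by block coding
(`min_codeword_rate()`), and the realised per-symbol rate of the block-4
codec approaches it from above in the tests. The definition divides by `n`
even though only `n - o` transitions contribute; a `denominator =
"transitions"` argument exposes the other convention, which matters only at
the `o/n` order.

## Coding

`huffman_codelengths()` implements the classical binary merge with a fixed
tie rule (among equal weights, the group whose lexically smallest member
comes first is merged first), and returns lengths in canonical order:
ascending codelength, then descending weight, then lexical order. Sorting
on the length first rather than the weight matters only when analytically
equal probabilities differ by floating-point noise — block probabilities
are products of count ratios, and two such products that are equal on paper
routinely differ in the last bit — and keeps the canonical ordering
consistent with the lengths in that case. `canonical_codebook()` then
assigns codewords by counting upwards in binary, zero-padding on the right
at each length increase: the codebook is fully determined by the codelength
sequence, which is why only lengths ever need to be transmitted.

Data are coded in `b`-symbol blocks (`b = 4` in the benchmark experiments):
the block law given a state is the product of one-step laws along the
block, and a canonical Huffman code is built per state over the blocks of
positive probability. A trailing remainder shorter than `b` is coded
symbol-by-symbol with the `b = 1` codebooks. Larger `b` brings the
per-symbol rate closer to the entropy at an exponential cost in codebook
size, which is why 4 is a sensible default for alphabets up to size 4.

When some states are unobserved (legitimately, for large state spaces on
short samples), block laws are computed with zero mass on continuations
through unobserved states. A block that actually occurs in the sample never
passes through such a state — every in-block intermediate state is itself
an observed context — so encoder and decoder, which derive codebooks from
the same transmitted counts by the same deterministic procedure, agree
bit-for-bit on every realizable block.

## Serialisation and bit accounting

The container is an ordered list of bit fields (`assemble_container()`,
`bit_accounting()`), all fixed-width integers big-endian:

* **order**: `floor(log2(log_|A|(n) - 1)) + 1` bits. Gapped models instead
  use 4 bits for `o` and 8 for `G`.
* **partition index** (by-parts only): per state in lexical order, the
  canonical Huffman codeword of its part index, the code built on the part
  sizes `|L_i|/|S|`; plus a codelength-description field — the first
  codelength and one increment per subsequent index. The faithful 1-bit
  increment scheme cannot represent an increment of 2 or more (possible for
  skewed part-size distributions), so an "escape" mode coding each
  increment in unary is available and flagged; the classical tallies all
  use the 1-bit form.
* **frequencies**: every transition count at the common width
  `floor(log2 n) + 1`, contexts in scan order, symbols in alphabet order.
* **initial symbols** and **data**: the first `o` (or `G`) symbols by
  lexical position, then the block-coded body.

Two accounting conventions are implemented. The classical (`"paper"`)
tallies count order + frequencies for the by-states model and order +
partition index + part frequencies for the by-parts model, with the
codelength description carried as its own field. A receiver additionally
needs `n`, `b`, and `|L|`, which the classical tallies leave implicit;
`"self_contained"` mode prepends them (32, 8, and `floor(log2 |S|) + 1`
bits) plus a 3-bit flag field, so that `parse_container()` can rebuild the
model and decode the sequence with no side information beyond the alphabet.
`.pmz` files wrap the bit payload with magic bytes, a version byte, and a
pad-length flag byte.

The compression ratio is `Rc = n * (floor(log2(|A| - 1)) + 1) /
total_bits`, i.e. against a fixed-width uncompressed encoding (1 bit per
symbol for binary alphabets, 2 bits for alphabets of size 3 or 4). For
three-letter alphabets no integer-width convention reproduces published
ratio tables exactly; the definition above is used uniformly and reported
as such.

### Gapped states

For DNA the conditional law of a base depends on the preceding codon
(order 3) and, usefully, on the base one codon-triplet period further back:
a state is then the pair (symbol at lag `G = 9`, contiguous triple at lags
3..1), giving `|A|^(o+1)` states. The state tuple is serialised gap symbol
first, then the contiguous tuple, in lexical order — the window layout
itself does not dictate a serialisation order, so one was fixed for
determinism. Gapped models are supported throughout fitting, entropy
estimation, and the codec at block size 1; block coding with `b > 1` under
a gap would need conditioning contexts larger than a single state (the
lag-`G` symbol of later in-block positions is not determined by the
block's starting state), so it is rejected rather than approximated.

## What the simulator emulates

`random_pmm()` draws a generating model with a prescribed shape: states are
shuffled into balanced parts with a seeded permutation, and part rows are
drawn from a Dirichlet (concentration 1 by default) and redrawn until every
pair of rows is at least `separation` apart in total variation — the knob
that controls how identifiable the partition is. `sample_sequence()` starts
from a uniformly drawn state and discards a burn-in of `10 |S|` symbols to
approximate stationarity (the stationary law is never computed explicitly).

The benchmark (`run_comparison()`) mirrors a standard experimental design:
eight model shapes crossing small/large state spaces with small/large
partitions, sample sizes in the thousands, block-4 coding, and means over
replicates of model bits, data bits, total bits, and `Rc` for both
serialisation strategies. The generating probabilities behind published
versions of this design are not available, so the experiments regenerate
random models of the same shapes and the expected findings are qualitative:
the by-parts model description is smaller in every replicate, its data
stream is slightly longer (fewer parameters mean a smaller maximised
likelihood, hence a slightly higher coding rate), and the totals favour
by-parts. Because a mean compression ratio can average per-replicate ratios
or divide mean sizes, `summarize_comparison()` reports both (`rc_mean`,
`rc_of_means`).

What the simulator does **not** emulate about real data: long-range and
non-stationary structure (genomes drift in composition), states whose true
laws are near-identical but not equal (the PMM is then an approximation,
not the truth), and alphabet extensions such as ambiguity codes. Passing
recovery tests on simulated data therefore demonstrates correctness of the
estimator and codec under the model, not that any particular real sequence
is PMM-distributed.

## Numerical choices and test scale

* `0 ln 0 = 0` throughout the likelihood; probability rows must sum to 1
  within `1e-12`; the plug-in/closed-form entropy identities are asserted
  at `1e-10` and `1e-12`.
* Merge gains are compared exactly; a merge happens only for strictly
  positive gain.
* Codeword construction is double-precision; codelengths are capped at 53
  bits (unreachable for realistic counts; a count table would need
  Fibonacci-like skew and astronomically long inputs to exceed it).
* The recovery study in the test suite uses 100 seeded replicates of a
  three-part order-2 model on a three-letter alphabet with total-variation
  separation 0.4 at `n = 10^4`; the benchmark reproduces the eight study
  shapes with 20 replicates at `n = 5000` (plus the oversized shape at
  `n = 1000`). These sizes were chosen to make the statistical assertions
  sharp while keeping the default test run comfortably fast.

## Known limitations

* Symbols are single characters; multi-character tokens are not supported.
* One gap lag at most; multi-interstice patterns and variable-length
  (context-tree) memories are out of scope.
* Huffman coding only — no arithmetic coding, and emitted codes are binary
  even though entropies can be computed in any base `D >= 2`.
* Compression is whole-sequence, two-pass (counts first, then coding);
  there is no streaming or adaptive mode.
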