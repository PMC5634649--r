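---
title: "Approximate string matching with k differences: models, engines, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximate string matching with k differences: models, engines, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdiffasm)
```

## The problem

Given a text `T[0..n-1]`, a pattern `P[0..m-1]` and a threshold `k`, the
*k-differences* problem asks for every text position `j` at which some
factor (contiguous substring) of `T` ends whose Levenshtein distance to
`P` — the minimum number of single-symbol insertions, deletions and
substitutions — is at most `k`.  The intended regime is online search of
long DNA texts with short patterns and small `k` (`n > m > k`); the
package warns, but still answers, outside that regime.

All three engines in this package compute the same object, the
semi-global dynamic-programming grid `D` of size `(m+1) × (n+1)`:

```
D[0, j] = 0
D[i, 0] = i
D[i, j] = D[i-1, j-1]                              if T[j-1] = P[i-1]
        = 1 + min(D[i-1, j], D[i, j-1], D[i-1, j-1])   otherwise
```

The zero top row lets a match start anywhere, so `D[m, j]` is the
distance of the *best* factor ending at text position `j-1` (0-based).
The reporting rule is then a threshold scan of the bottom row: position
`j` is reported with distance `D[m, j+1]` iff `D[m, j+1] <= k`.
Internally the scan also produces the sentinel encoding used by GPU
implementations of this rule (`result[j] = j` on a hit, `-1` otherwise);
`extract_matches()` exposes it as an attribute.

Note one semantic choice: the classical problem statement restricts
factors to length exactly `m`, but the recurrence above — and the
reporting rule built on it — scores factors of *any* length.  The two
differ only in edge cases (a shorter or longer factor can be closer to
the pattern than any length-`m` factor).  This package implements the
recurrence's semantics throughout, because that is what the row-parallel
and warp formulations below compute, and it is the more useful notion in
practice: reported distance is the true distance of the best factor.

## Engine 1: the sequential oracle

`edit_distance_matrix()` evaluates the recurrence exactly as written, in
C (the inner loop carries the `D[i, j-1]` dependency, so it cannot be
vectorised; a compiled loop is the natural expression, as in every
alignment package).  It is the package's ground truth: both other
engines are required — and tested — to reproduce it cell for cell.  Its
correctness is itself established against an independent brute-force
oracle (exhaustive factor enumeration scored with `utils::adist`) on
randomised instances; the validation sizes are listed at the end.

`global_edit_distance()` is the standard Levenshtein distance
(`D[0, j] = j` initialisation), used by the synthetic generator's
guarantees and by tests.  Note its equality semantics are plain symbol
identity, while the *search* engines treat alphabet-external symbols
(e.g. `N`) as matching nothing, not even themselves — the conservative
choice for ambiguity codes in a search: an `N` in the text can never
produce a spurious exact hit.  The distance between two explicit strings,
by contrast, should be zero when they are identical.

## Engine 2: dependency elimination

The obstacle to computing a DP row in parallel is the in-row term
`D[i, j-1]`.  It can be removed with a *last-occurrence index* `X`: for
each alphabet symbol `s` and column `j`, `X[s, j]` is the largest 1-based
position `p <= j` with `T[p-1] = s`, or `0` if none.  Each row of `X` is
a running maximum over the text, so rows are mutually independent and
`build_occurrence_index()` can build any subset of them in isolation
(the engines index only the symbols that actually occur in the pattern;
unknown pattern symbols get an all-zero row, which is exactly the
"no occurrence" case).

With `X` in hand, the recurrence becomes, for `x = X[P[i-1], j]`:

```
D[i, j] = i                                        if j = 0
        = D[i-1, j-1]                              if T[j-1] = P[i-1]
        = 1 + min(D[i-1, j], D[i-1, j-1], i+j-1)   if x = 0
        = 1 + min(D[i-1, j], D[i-1, j-1],
                  D[i-1, x-1] + (j-1-x))           otherwise
```

Row `i` now reads only row `i-1`.  The intuition: unrolling the
horizontal chain `D[i, j-1] + 1` expresses `D[i, j]` as
`min over p <= j of (entry cost at p) + (j - p)` insertions.  Vertical
and mismatch-diagonal entries at `p < j` are dominated by their `p = j`
counterparts (the grid is 1-Lipschitz along rows), so the only chain
entry that can win is a *match* diagonal, and among match columns the
last occurrence `x` dominates the earlier ones.  The `x = 0` branch's
`i + j - 1` term is the all-insertions chain back to column 0.  We treat
this identity as a claim to be verified, not assumed: the test suite
asserts cell-for-cell equality with the sequential oracle exhaustively
over a small universe and on hundreds of random instances, and
separately asserts the chain upper bound on every mismatch cell.

`compute_row()` exposes the single-row step; `run_row_parallel()` runs
it for `i = 1..m`.  Because no output column reads another output
column, the columns of a row may be computed in any order — a property
the tests check by evaluating rows forward, backward and in shuffled
order.  The implementation computes each row with whole-vector
operations, the serial-R stand-in for one-thread-per-column; the
row-to-row loop is the only serialisation, mirroring the per-row barrier
a parallel implementation needs.

## Engine 3: warp-shuffle dataflow simulation

On SIMT hardware, threads (lanes) within a warp of width `w` can
exchange registers directly (`shfl_up`), which is cheaper than a
shared-memory write/sync/read triple.  Mapping lane `j` to DP column
`j`, the operands of the dependency-eliminated recurrence split by
provenance after row `i-1`, when lane `j` holds `D[i-1, j]` in register
`Dvar`:

* `Avar = D[i-1, j-1]`: the left neighbour's register — one `shfl_up`
  exchange, **except** at warp boundaries (`j mod w = 0`), where the
  neighbour is in another warp and the value must come from memory;
* `Bvar = D[i-1, j]`: the lane's own register — free;
* `Cvar = D[i-1, X-1]`: an arbitrary column — always a memory read;
* the updated `Dvar` is written back to the row store, because other
  lanes' `Cvar` reads in the next row may target any column.

`run_warp_sim()` reproduces this dataflow row-synchronously with
whole-row register vectors (`shfl_up()` is also exported as the
single-warp primitive, with the hardware semantics: lanes below `delta`
retain their own value and are handled by the memory path).  Column
`j = 0` is the first warp's boundary lane but performs no `Avar` read at
all: its cell is the constant `i`.  The boundary condition is applied to
the column index `j`, the quantity lanes are numbered by — it is the
lane's position in its warp, not the row number, that decides whether a
left neighbour is reachable by register exchange.

Since no timing can be measured without hardware, the simulator's
testable output is its *operation accounting*, tallied as the dataflow
executes:

* D-row reads: `n+1` `Cvar` reads per row (the `Cvar` load is issued
  unconditionally for every lane, mirroring a branchless kernel, even
  where the `x = 0` branch then ignores it) plus `floor(n/w)` boundary
  `Avar` reads, times `m` rows;
* occurrence-index reads: `n+1` per row; writes: `n+1` per row; one
  barrier per row;
* shuffles: one per non-boundary lane, `n - floor(n/w)` per row;
* text/pattern reads (`n` each per row) are labelled *shared* rather
  than *global*, modelling the standard block-local substring cache;
  the cache changes an access's label, which is the only effect visible
  without a timing model.

`predicted_counters()` gives the closed form; the tests require the
simulation to match it exactly, on top of width-invariance of the
distances.  The payoff being modelled: a plain row-parallel evaluation
reads all three operands from memory, `3mn` D-row reads
(`rowparallel_replay_counters()`), whereas the warp engine needs
`m(n + 1 + floor(n/w))` — a ratio approaching `(1 + 1/w)/3` ≈ 0.344 at
`w = 32`.  The tests assert the strict inequality on every instance with
`n >= w` and the asymptotic ratio; no wall-clock claim is made anywhere.

## Tunable parameters

* `k` (non-negative integer): the edit budget.  No default — it is the
  scientific question.  `k >= m` makes every position a match (a factor
  can always be built with at most `m` edits from the empty string);
  the package warns when `m <= k`.
* `warp_width` (integer `>= 2`, default 32): lanes per warp in the
  simulator.  32 is the ubiquitous hardware warp size; results are
  provably width-invariant, only the counters change.
* `alphabet` (default `{A, C, G, T}`): declared symbol set.  Symbols
  outside it are kept in sequences but never match (see above).  Case
  folding is on by default in FASTA input.

## The synthetic generator

`random_dna()` draws i.i.d. uniform symbols.  `plant_occurrence()`
applies exactly `e` edit operations (uniform among insertion, deletion,
substitution) to a copy of the pattern and splices the mutated factor
into the text by *overwriting* a window, so coordinates elsewhere never
shift and multiple plants cannot displace each other.  Insertions are
interior-only — an insertion at either end would redefine where the
factor begins or ends and make the recorded end position ambiguous —
and deletions never empty the factor.  Substitutions may redraw the
same base, and operations may cancel; consequently the contract is an
upper bound, `dist(factor, P) <= e`, which is also the only property
the DP guarantees at the planted end (`D[m, end+1] <= e`, since the
planted factor is one of the candidates the semi-global minimum ranges
over).  `synth_dataset()` places one plant per equal-length text
segment, which keeps plants disjoint by construction.

The benchmark configuration used in validation — 10 kb texts, pattern
length 16, edit budgets 0..6 at `k = 6` — reflects the regime this kind
of search is typically run and reported in: short probes against long
stretches of DNA with a permissive budget.  What the generator does
*not* emulate: base composition bias, repeats and low-complexity
regions, ambiguity codes, or sequencing-error profiles.  Passing the
planted-recovery tests therefore demonstrates the *correctness
guarantee* (planted matches are never missed) on realistic sizes, not
robustness of match counts on real genomes — on repetitive real
sequence the reported hit lists will simply be longer, with no change
to the guarantee.

## Numerical and degenerate-input choices

* Coordinates: sequences are 0-based; grid row `i`/column `j` run from
  0 to `m`/`n`; reported end positions are 0-based inclusive (`j`
  corresponds to grid column `j+1`).  Occurrence-index positions are
  1-based, which keeps the `x - 1` and `j - 1 - x` terms of the
  eliminated recurrence literal; conversion happens only when indexing
  a sequence.
* Grid cells are small non-negative integers (never exceeding the row
  index); everything is exact integer arithmetic, no tolerances exist
  anywhere.
* Ties in the `min` are value-ties only; since only distances (never
  tracebacks) are computed, no tie-breaking policy is needed.
* Empty pattern: the grid is the single all-zero row, and every
  position matches at distance 0 with `k = 0`.  The search front end
  rejects empty patterns (`m >= 1`); the engines themselves handle
  `m = 0` and `n = 0` so the boundary algebra stays total.
* By default engines return only the final row (O(n) state, the
  streaming mode for long texts); `keep_matrix = TRUE` materialises the
  full grid, which is what all equivalence tests compare.

## Validation sizes

The test suite's equivalence evidence, chosen to be exhaustive where a
small universe suffices and randomised where it cannot: all
(text, pattern) pairs with `n <= 12`, `m <= 5` over `{A, C}` (507,780
pairs, full-grid identity of all engines at widths 2, 4, 8, 32), plus
500 seeded random DNA instances with `n <= 200`, `m <= 30`; brute-force
factor enumeration on 100 instances with `n <= 40`, `m <= 8`; 100
seeded planted-recovery trials at the benchmark configuration above;
counter-model identity on 50 random `(n <= 1000, m <= 32, w)` triples;
and 100 `k = 0` instances against a naive overlapping substring scan.
`scripts/acceptance.R` re-runs this battery (at reduced instance counts
where the full count adds nothing but time) from a caller-supplied seed
and writes the resulting rates as JSON.

## Known limitations

* No start positions or alignment traceback: the grid stores distances
  only, so BED output marks single-base end positions.
* The simulator models dataflow and traffic, not time: no occupancy,
  latency, coalescing or block-size effects.  Its counters support the
  memory-traffic argument, nothing more.
* No banded, bit-parallel or diagonal-wavefront accelerations; the
  sequential oracle is O(mn) and intentionally plain, as the package's
  ground truth.
* Multi-pattern search is by iteration; there is no dictionary
  automaton.
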