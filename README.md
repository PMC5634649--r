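# kdiffasm

Approximate string matching with *k* differences over DNA (and other
small-alphabet) texts: find every position of a text at which a substring
ends that lies within `k` Levenshtein edits — insertions, deletions,
substitutions — of a query pattern.  This is the classic online
"k-differences" search used across computational biology, from probe and
primer placement to motif screening, whenever exact matching is too
brittle.

The package is aimed at two audiences: users who simply need the matches
(via `asm_search()` or the `kdiffasm` command-line script), and readers
studying how this search parallelises, for whom the package provides
three interchangeable engines over the same semi-global
dynamic-programming grid

    D[0, j] = 0,   D[i, 0] = i,
    D[i, j] = D[i-1, j-1]                                if T[j-1] = P[i-1],
            = 1 + min(D[i-1, j], D[i, j-1], D[i-1, j-1]) otherwise,

with position `j` reported iff `D[m, j+1] <= k`:

* **oracle** — the sequential recurrence above, in C; the ground truth;
* **rowparallel** — a dependency-eliminated form in which row `i` is a
  function of row `i-1` alone, obtained by collapsing the in-row
  insertion chain onto a per-symbol last-occurrence index `X[s, j]`; all
  columns of a row become mutually independent;
* **warpsim** — a dataflow simulator of the warp-mapped formulation of
  that recurrence: one lane per column, `D[i-1, j-1]` obtained by
  register exchange (`shfl_up`) except at warp boundaries where it falls
  back to memory, and full accounting of modeled memory reads, writes,
  shuffles and barriers.  The counters substantiate the memory-traffic
  argument for the warp formulation — `m(n + 1 + ⌊n/w⌋)` D-row reads
  versus `3mn` for the plain row-parallel replay — without any hardware
  timing claims.

All three engines are required to agree cell-for-cell on the full grid;
the test suite enforces this exhaustively on a small universe and on
hundreds of seeded random instances, and checks the oracle itself
against brute-force factor enumeration.  See the methods vignette
(`vignettes/kdiffasm-methods.Rmd`) for the models, the parameter
choices, and what the synthetic benchmarks do and do not demonstrate.

## Worked example

Searching `T = CATGACTG` for `P = TACTG` within `k = 2` edits:

```r
library(kdiffasm)
hits <- asm_search("CATGACTG", "TACTG", k = 2, engine = "warpsim", warp_width = 4)
print(hits)
#> k-differences matches on 'seq' (n=8, m=5, k=2, engine=warpsim): 3 hit(s)
#>  end distance
#>    3        2
#>    6        2
#>    7        1
```

Three factors end within two edits of the pattern: at 0-based positions
3 and 6 at distance 2 (e.g. the factor `ATG` ending at position 3
becomes `TACTG` with two insertions), and at position 7 at distance 1
(the factor `ACTG` at positions 4–7 needs only the leading `T`
inserted).  The distances are the bottom row of the grid:

```r
edit_distance_matrix("CATGACTG", "TACTG")
#>     C A T G A C T G
#>   0 0 0 0 0 0 0 0 0
#> T 1 1 1 0 1 1 1 0 1
#> A 2 2 1 1 1 1 2 1 1
#> C 3 2 2 2 2 2 1 2 2
#> T 4 3 3 2 3 3 2 1 2
#> G 5 4 4 3 2 3 3 2 1
```

The warp engine also reports its modeled traffic (here 4 lanes per
warp, so per row: 9 unconditional `Cvar` reads plus 2 warp-boundary
reads, 6 register exchanges at the 6 non-boundary columns):

```r
print(attr(hits, "counters"))
#> <asm_counters> n=8 m=5 w=4
#>   global reads : 100 (D rows 55, occurrence index 45)
#>   shared reads : 80 (text 40, pattern 40)
#>   writes 45 | shuffles 30 | syncs 5
```

## Command line

```sh
# synthesise a 2 kb text with three planted 2-edit occurrences
kdiffasm synth --length 2000 --pattern ACGTTGCAACGTTGCA --plant 3 \
         --edits 2 --seed 5 --out-fasta t.fa --out-truth truth.tsv

# search it (TSV or BED out; counters for the warp engine)
kdiffasm search --text t.fa --pattern ACGTTGCAACGTTGCA -k 6 \
         --engine warpsim --warp-width 32 --out hits.tsv --counters ops.txt
```

The script is installed at `exec/kdiffasm` inside the package directory
(`system.file("exec", "kdiffasm", package = "kdiffasm")`); run it with
`Rscript <path>` or add it to your `PATH`.

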