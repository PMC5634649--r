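# Dependency-eliminated engine.  With the last-occurrence index X in hand,
# the semi-global recurrence can be rewritten so that row i of D reads only
# row i-1 (never D[i, j-1]): the horizontal insertion chain collapses onto
# the last occurrence of the current pattern symbol,
#
#   D[i, j] = i                                    if j = 0
#           = D[i-1, j-1]                          if T[j] == P[i]
#           = 1 + min(D[i-1, j], D[i-1, j-1], i + j - 1)        if X = 0
#           = 1 + min(D[i-1, j], D[i-1, j-1],
#                     D[i-1, X-1] + (j - 1 - X))   otherwise,  X = X[P[i], j].
#
# Every column of the output row is therefore independent of the others;
# the vectorised kernel below is the bulk-array counterpart of assigning
# one thread per column, with the row loop as the only serial order.

# prev: previous row (length n+1); occ_int: occurrence values at j=1..n;
# mcols: columns j (1..n) where T[j] matches the row's pattern symbol;
# jv: 1:n precomputed by the caller.
.row_kernel <- function(prev, i, occ_int, mcols, n, jv) {
  if (n == 0L) return(i)
  chain <- i + jv - 1L
  pos <- which(occ_int > 0L)
  if (length(pos))
    chain[pos] <- prev[occ_int[pos]] + (jv[pos] - 1L - occ_int[pos])
  val <- 1L + pmin.int(prev[-1L], prev[-(n + 1L)], chain)
  if (length(mcols)) val[mcols] <- prev[mcols]
  c(i, val)
}

#' Compute one DP row from the previous row alone
#'
#' The single-row step of the dependency-eliminated recurrence.  No output
#' column reads any other output column: each entry is a function of the
#' previous row, the row number, and the occurrence-index row of the
#' current pattern symbol.
#'
#' @param previous integer vector of length n+1: DP row i−1.
#' @param i current row number, 1..m.
#' @param pattern_symbol the symbol `P[i]` (1-based pattern position i).
#' @param occ_row integer vector of length n+1: the occurrence-index row of
#'   `pattern_symbol` (see [build_occurrence_index()]).
#' @param text the text as [asm_seq()] or string (used only for the
#'   symbol-match test).
#' @return Integer vector of length n+1: DP row i.
#' @examples
#' D <- edit_distance_matrix("CATGACTG", "TACTG")
#' idx <- build_occurrence_index("CATGACTG")
#' compute_row(D[5, ], 5, "G", idx["G", ], "CATGACTG")  # equals D[6, ]
#' @export
compute_row <- function(previous, i, pattern_symbol, occ_row, text) {
  text <- as_asm_seq(text)
  n <- length(text)
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 1L)
    stop("i must be a row number >= 1")
  if (length(previous) != n + 1L)
    stop("previous row must have length n+1 = ", n + 1L)
  if (length(occ_row) != n + 1L)
    stop("occ_row must have length n+1 = ", n + 1L)
  mcols <- which(text$symbols == pattern_symbol & text$codes > 0L)
  out <- .row_kernel(as.integer(previous), i, as.integer(occ_row)[-1L],
                     mcols, n, seq_len(n))
  as.integer(out)
}

#' Run the row-parallel engine
#'
#' Builds the last-occurrence index for the pattern's symbols, then applies
#' the single-row recurrence for i = 1..m.  The row-to-row order is the
#' only serialisation (the analogue of a per-row barrier); within a row all
#' columns are computed as one bulk operation.  Output is identical,
#' cell-for-cell, to [edit_distance_matrix()].
#'
#' @param text,pattern an [asm_seq()] or character string.
#' @param keep_matrix return the full (m+1) x (n+1) grid (`TRUE`) or only
#'   the final row (`FALSE`, O(n) working state).
#' @return Integer matrix (as [edit_distance_matrix()]) or the final row.
#' @examples
#' run_row_parallel("CATGACTG", "TACTG")
#' @export
run_row_parallel <- function(text, pattern, keep_matrix = FALSE) {
  text <- as_asm_seq(text)
  pattern <- as_asm_seq(pattern)
  n <- length(text$symbols)
  m <- length(pattern$symbols)
  tcodes <- .text_codes(text)
  pcodes <- .pattern_codes(pattern)
  ucodes <- unique(pcodes)
  tabs <- .occ_tables_for_codes(tcodes, ucodes, n)
  key <- match(pcodes, ucodes)
  jv <- seq_len(n)
  prev <- integer(n + 1L)
  if (keep_matrix) {
    D <- matrix(0L, nrow = m + 1L, ncol = n + 1L)
    if (m > 0L) D[, 1L] <- 0:m
  }
  for (i in seq_len(m)) {
    r <- key[i]
    prev <- .row_kernel(prev, i, tabs$occ_int[[r]], tabs$mcols[[r]], n, jv)
    if (keep_matrix) D[i + 1L, ] <- prev
  }
  if (keep_matrix) {
    dimnames(D) <- .dp_dimnames(text, pattern)
    D
  } else {
    structure(as.integer(prev), row_index = m)
  }
}
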