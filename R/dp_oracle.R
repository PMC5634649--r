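# Reference engine: the classic sequential semi-global recurrence.
#
# D[i, j] is the minimum number of edits converting some factor of the text
# ending at column j into the pattern prefix P[1..i].  Row 0 is all zeros
# (a match may start anywhere), column 0 equals i (the empty factor needs i
# insertions).  The C kernels in src/dp.cpp implement the recurrence.

# Integer codings used by every engine: text symbols outside the alphabet
# code to 0, pattern symbols outside the alphabet to -1, so an external
# symbol (e.g. N) never equals any symbol, including itself.
.text_codes <- function(seq) seq$codes

.pattern_codes <- function(seq) {
  codes <- seq$codes
  codes[codes == 0L] <- -1L
  codes
}

.dp_dimnames <- function(text, pattern) {
  list(c("", pattern$symbols), c("", text$symbols))
}

#' Semi-global edit-distance matrix
#'
#' Computes the full (m+1) x (n+1) dynamic-programming grid `D` for a text
#' of length n and pattern of length m, by the classic sequential
#' recurrence.  `D[i+1, j+1]` (1-based R indexing of cell (i, j)) is the
#' minimum edit distance between `P[1..i]` and the best factor of the text
#' ending at text position j.  This engine is the ground-truth oracle the
#' row-parallel and warp-shuffle engines are checked against.
#'
#' @param text,pattern an [asm_seq()] or character string.
#' @param ... passed to [asm_seq()] when coercing character input.
#' @return Integer matrix with dimnames spelling out pattern (rows) and
#'   text (columns); attribute `row_index` on rows is implicit (row r holds
#'   DP row r−1).
#' @examples
#' edit_distance_matrix("CATGACTG", "TACTG")
#' @export
edit_distance_matrix <- function(text, pattern, ...) {
  text <- as_asm_seq(text, ...)
  pattern <- as_asm_seq(pattern, ...)
  D <- .dp_matrix_c(.text_codes(text), .pattern_codes(pattern))
  dimnames(D) <- .dp_dimnames(text, pattern)
  D
}

# Final-row-only variant (O(n) working state) used by the search front end.
.oracle_final_row <- function(text, pattern) {
  .dp_final_row_c(.text_codes(text), .pattern_codes(pattern))
}

#' Global (standard) Levenshtein distance
#'
#' Minimum number of single-symbol insertions, deletions and substitutions
#' converting `a` into `b`.  Unlike the search engines, plain symbol
#' equality is used (so `global_edit_distance(x, x)` is 0 for any string);
#' the distance is symmetric in its arguments.
#'
#' @param a,b an [asm_seq()] or character string.
#' @return Non-negative integer.
#' @examples
#' global_edit_distance("ACTG", "TACTG")  # 1
#' @export
global_edit_distance <- function(a, b) {
  a <- as_asm_seq(a)
  b <- as_asm_seq(b)
  # shared code table so arbitrary symbols compare by identity
  tab <- unique(c(a$symbols, b$symbols))
  .levenshtein_c(match(a$symbols, tab), match(b$symbols, tab))
}

#' Extract matches from the final DP row
#'
#' Applies the k-differences reporting rule to the bottom row of the grid:
#' text end position `j` (0-based) is reported iff `D[m, j+1] <= k`.  The
#' attribute `result` carries the equivalent sentinel encoding: an integer
#' vector over positions 0..n−1 holding `j` where position j matches and
#' `-1` elsewhere.
#'
#' @param final_row integer vector of length n+1: the last row of the grid
#'   (e.g. `edit_distance_matrix(...)[m + 1, ]`).
#' @param k non-negative distance threshold.
#' @return `data.frame(end, distance)` with 0-based inclusive end
#'   positions in increasing order; attribute `result` as described.
#' @examples
#' D <- edit_distance_matrix("CATGACTG", "TACTG")
#' extract_matches(D[6, ], k = 2)
#' @export
extract_matches <- function(final_row, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    stop("k must be a single non-negative integer")
  vals <- as.integer(final_row)
  n <- length(vals) - 1L
  if (n < 0L) stop("final_row must have at least one cell")
  if (n == 0L) {
    out <- data.frame(end = integer(0L), distance = integer(0L))
    attr(out, "result") <- integer(0L)
    return(out)
  }
  ends <- 0:(n - 1L)
  dist <- vals[-1L]
  hit <- dist <= k
  out <- data.frame(end = ends[hit], distance = dist[hit])
  result <- rep(-1L, n)
  result[hit] <- ends[hit]
  attr(out, "result") <- result
  out
}
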