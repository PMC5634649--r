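# Seeded synthetic data: random DNA texts with planted approximate
# occurrences of a pattern, plus the small worked example used throughout
# the documentation.  All randomness is drawn from R's RNG inside a
# save/restore guard, so a fixed seed gives byte-identical output and the
# caller's RNG state is never disturbed.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

#' Random DNA sequence
#'
#' Symbols drawn i.i.d. uniformly over the alphabet; deterministic for a
#' fixed seed.
#'
#' @param length non-negative sequence length.
#' @param seed integer seed, or `NULL` to draw from the current RNG state.
#' @param alphabet an [asm_alphabet()]; default `{A, C, G, T}`.
#' @param id sequence label.
#' @return An [asm_seq()].
#' @examples
#' random_dna(20, seed = 1)
#' @export
random_dna <- function(length, seed = NULL, alphabet = dna_alphabet(),
                       id = "synthetic") {
  length <- as.integer(length)
  if (is.na(length) || length < 0L) stop("length must be non-negative")
  syms <- .with_seed(seed,
    sample(unclass(alphabet), length, replace = TRUE))
  asm_seq(syms, id = id, alphabet = alphabet, case_fold = FALSE)
}

# Apply exactly `edits` random operations to a symbol vector.  Insertions
# are interior-only (never before the first or after the last symbol), so
# the factor's boundaries — and hence its spliced end offset — stay well
# defined; deletions may remove any symbol but never empty the factor;
# substitutions draw uniformly from the alphabet (a redraw of the same
# base is allowed: the edit count is an upper bound on the true distance).
.mutate_factor <- function(symbols, edits, alphabet) {
  alpha <- unclass(alphabet)
  for (e in seq_len(edits)) {
    len <- length(symbols)
    ops <- c("sub",
             if (len >= 2L) "ins",    # interior slot exists
             if (len >= 2L) "del")    # keep the factor non-empty
    op <- if (length(ops) == 1L) ops else sample(ops, 1L)
    if (op == "sub") {
      p <- sample.int(len, 1L)
      symbols[p] <- sample(alpha, 1L)
    } else if (op == "ins") {
      p <- sample.int(len - 1L, 1L)   # insert between positions p and p+1
      symbols <- append(symbols, sample(alpha, 1L), after = p)
    } else {
      p <- sample.int(len, 1L)
      symbols <- symbols[-p]
    }
  }
  symbols
}

#' Plant an approximate occurrence of a pattern into a text
#'
#' Applies exactly `edits` random edit operations (insertion, deletion,
#' substitution; uniform choice) to a copy of the pattern and splices the
#' mutated factor into the text by overwriting the window starting at
#' `position`, so the surrounding coordinates are unchanged.  The true
#' edit distance of the planted factor to the pattern is guaranteed to be
#' at most `edits` (operations may cancel, so equality is not promised),
#' and the semi-global grid therefore satisfies
#' `D[m, end_position + 1] <= edits`: a search with `k >= edits` must
#' report the planted end position.
#'
#' @param text,pattern an [asm_seq()] or character string.
#' @param edits non-negative number of operations to apply.
#' @param position 0-based start offset of the splice window; the mutated
#'   factor must fit within the text.
#' @param seed integer seed, or `NULL` to draw from the current RNG state.
#' @return List with `text` (the mutated [asm_seq()]) and `truth`, a
#'   `data.frame(end_position, planted_edits, mutated_factor)` with the
#'   0-based inclusive end offset of the planted factor.
#' @examples
#' p <- plant_occurrence(random_dna(60, seed = 1), "TACGGTAC",
#'                       edits = 2, position = 10, seed = 2)
#' p$truth
#' @export
plant_occurrence <- function(text, pattern, edits, position, seed = NULL) {
  text <- as_asm_seq(text)
  pattern <- as_asm_seq(pattern)
  edits <- as.integer(edits)
  position <- as.integer(position)
  if (is.na(edits) || edits < 0L) stop("edits must be non-negative")
  if (length(pattern) < 1L) stop("pattern must be non-empty")
  .with_seed(seed, {
    factor_syms <- .mutate_factor(pattern$symbols, edits, text$alphabet)
    lf <- length(factor_syms)
    n <- length(text)
    if (is.na(position) || position < 0L || position + lf > n)
      stop(sprintf("impossible splice: factor of length %d does not fit at position %d in text of length %d",
                   lf, position, n))
    syms <- text$symbols
    syms[(position + 1L):(position + lf)] <- factor_syms
    list(
      text = asm_seq(syms, id = text$id, alphabet = text$alphabet,
                     case_fold = FALSE),
      truth = data.frame(
        end_position = position + lf - 1L,
        planted_edits = edits,
        mutated_factor = paste(factor_syms, collapse = ""),
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Generate a benchmark text with several planted occurrences
#'
#' Draws a uniform random DNA text of length `n`, partitions it into
#' `length(edits)` equal segments and plants one mutated copy of the
#' pattern at a random admissible offset inside each segment, so plants
#' never overlap.  This emulates the experimental regime the engines are
#' benchmarked under (long random DNA, short pattern, a handful of edits).
#'
#' @param n text length; must leave each segment room for a factor of
#'   length up to `m + max(edits)`.
#' @param pattern an [asm_seq()] or character string.
#' @param edits integer vector: the number of edit operations for each
#'   planted occurrence.
#' @param seed integer seed for the whole construction.
#' @param alphabet an [asm_alphabet()].
#' @return List with `text` (an [asm_seq()]) and `truth` (one row per
#'   plant, ascending `end_position`).
#' @examples
#' d <- synth_dataset(500, "ACGTTGCAACGTTGCA", edits = 0:3, seed = 7)
#' d$truth
#' @export
synth_dataset <- function(n, pattern, edits, seed = NULL,
                          alphabet = dna_alphabet()) {
  pattern <- as_asm_seq(pattern)
  edits <- as.integer(edits)
  if (any(is.na(edits) | edits < 0L)) stop("edits must be non-negative")
  nplant <- length(edits)
  m <- length(pattern)
  seg <- if (nplant) n %/% nplant else n
  if (nplant && seg < m + max(edits) + 1L)
    stop("text too short for the requested number of plants")
  .with_seed(seed, {
    text <- random_dna(n, seed = NULL, alphabet = alphabet, id = "synthetic")
    rows <- vector("list", nplant)
    for (p in seq_len(nplant)) {
      lo <- (p - 1L) * seg                     # 0-based segment start
      hi <- lo + seg - (m + edits[p])          # last admissible offset
      position <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      planted <- plant_occurrence(text, pattern, edits[p], position,
                                  seed = NULL)
      text <- planted$text
      rows[[p]] <- planted$truth
    }
    truth <- do.call(rbind, rows)
    if (nplant) truth <- truth[order(truth$end_position), , drop = FALSE]
    list(text = text, truth = truth)
  })
}

#' The packaged worked example
#'
#' The small instance used throughout the documentation: text `CATGACTG`,
#' pattern `TACTG`, threshold `k = 2`.  The expectations are computed by
#' the reference oracle at call time, never read from stored constants.
#'
#' @return List with `text`, `pattern`, `k`, the oracle's `final_row`,
#'   `expected_ends` (0-based), `expected_distances`, and `result` (the
#'   sentinel vector: j where matched, −1 elsewhere).
#' @examples
#' worked_example()$expected_ends  # 3 6 7
#' @export
worked_example <- function() {
  text <- asm_seq("CATGACTG", id = "T")
  pattern <- asm_seq("TACTG", id = "P")
  k <- 2L
  final_row <- .oracle_final_row(text, pattern)
  hits <- extract_matches(final_row, k)
  list(text = text, pattern = pattern, k = k,
       final_row = as.integer(final_row),
       expected_ends = hits$end,
       expected_distances = hits$distance,
       result = attr(hits, "result"))
}
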