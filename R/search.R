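#' Search a text for approximate occurrences of a pattern
#'
#' Reports every 0-based text position `j` at which some factor (substring)
#' of the text ends whose Levenshtein distance to the pattern is at most
#' `k`, together with that distance — the k-differences reporting rule
#' applied to the bottom row of the semi-global DP grid.  The three engines
#' are interchangeable and must produce identical reports.
#'
#' A factor of any length may end at a reported position: the semi-global
#' initialisation scores the best factor per end column, which is exactly
#' what the reporting rule consumes.
#'
#' @param text,pattern an [asm_seq()] or character string.
#' @param k non-negative edit-distance threshold.
#' @param engine `"oracle"` (classic sequential DP, C), `"rowparallel"`
#'   (dependency-eliminated row recurrence) or `"warpsim"` (warp-shuffle
#'   dataflow simulator).
#' @param warp_width lanes per warp for `engine = "warpsim"` (>= 2).
#' @return An `asm_matches`: a `data.frame(end, distance)` in increasing
#'   end order, with attributes `record_id`, `k`, `engine`, `n`, `m`,
#'   `result` (the sentinel vector: position j where matched, −1
#'   elsewhere), and for `"warpsim"` also `counters`.
#' @examples
#' asm_search("CATGACTG", "TACTG", k = 2)
#' @export
asm_search <- function(text, pattern, k,
                       engine = c("oracle", "rowparallel", "warpsim"),
                       warp_width = 32L) {
  engine <- match.arg(engine)
  text <- as_asm_seq(text)
  pattern <- as_asm_seq(pattern)
  n <- length(text)
  m <- length(pattern)
  if (m < 1L) stop("pattern must have length >= 1")
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    stop("k must be a single non-negative integer")
  k <- as.integer(k)
  if (n <= m)
    warning(sprintf("text length (%d) is not greater than pattern length (%d); the k-differences setting assumes n > m > k", n, m))
  else if (m <= k)
    warning(sprintf("pattern length (%d) is not greater than k (%d); every position will match", m, k))
  counters <- NULL
  final_row <- switch(engine,
    oracle = .oracle_final_row(text, pattern),
    rowparallel = run_row_parallel(text, pattern, keep_matrix = FALSE),
    warpsim = {
      res <- run_warp_sim(text, pattern, warp_width = warp_width,
                          keep_matrix = FALSE)
      counters <- res$counters
      res$distances
    })
  out <- extract_matches(final_row, k)
  structure(out,
            class = c("asm_matches", "data.frame"),
            record_id = text$id, k = k, engine = engine,
            n = n, m = m,
            warp_width = if (engine == "warpsim") as.integer(warp_width) else NA_integer_,
            counters = counters)
}

#' @export
print.asm_matches <- function(x, ...) {
  cat(sprintf("k-differences matches on '%s' (n=%d, m=%d, k=%d, engine=%s): %d hit(s)\n",
              attr(x, "record_id"), attr(x, "n"), attr(x, "m"),
              attr(x, "k"), attr(x, "engine"), nrow(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a match report to TSV or BED
#'
#' TSV: a header line `record_id  end  distance`, then one row per match
#' (end positions 0-based inclusive, ascending).  BED: one single-base
#' half-open interval `[end, end + 1)` per match with name `ed=<distance>`
#' (the engines compute distances only, not start positions, so matches
#' are endpoint markers).  Byte output is deterministic for a fixed
#' report.
#'
#' @param report an `asm_matches` from [asm_search()].
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_matches <- function(report, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "asm_matches"))
  id <- attr(report, "record_id")
  lines <- switch(format,
    tsv = c("record_id\tend\tdistance",
            if (nrow(report))
              sprintf("%s\t%d\t%d", id, report$end, report$distance)),
    bed = if (nrow(report))
            sprintf("%s\t%d\t%d\ted=%d", id, report$end,
                    report$end + 1L, report$distance)
          else character(0L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSV match report back
#'
#' Inverse of [write_matches()] for the TSV format; the round trip
#' reproduces the entries exactly.
#'
#' @param path path to a TSV written by [write_matches()].
#' @return A `data.frame(record_id, end, distance)`.
#' @export
read_matches <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "integer"))
  names(df) <- c("record_id", "end", "distance")
  df
}
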