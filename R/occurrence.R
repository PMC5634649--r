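# Last-occurrence index: the table that removes the within-row dependency
# from the semi-global recurrence.  For symbol s and column j (0..n),
# X[s, j] is the largest 1-based text position p <= j with T[p] == s, or 0
# if s does not occur in T[1..j].  Each row depends on the text alone, so
# all rows can be built independently.

#' Build the last-occurrence index of a text
#'
#' @param text an [asm_seq()] or character string.
#' @param alphabet alphabet whose symbols index the rows; defaults to the
#'   text's own alphabet.
#' @param symbols optional character vector restricting the build to these
#'   symbols (the engines index only the symbols present in the pattern;
#'   rows are independent, so a partial build equals the matching rows of
#'   the full build).  `NULL` builds every alphabet row.
#' @return An `occ_index`: integer matrix with one row per indexed symbol
#'   (rownames are the symbols) and n+1 columns for j = 0..n, plus
#'   attributes `n` and `alphabet`.
#' @examples
#' build_occurrence_index("CATGACTG")
#' @export
build_occurrence_index <- function(text, alphabet = NULL, symbols = NULL) {
  text <- as_asm_seq(text)
  if (is.null(alphabet)) alphabet <- text$alphabet
  alphabet <- if (inherits(alphabet, "asm_alphabet")) alphabet
              else asm_alphabet(alphabet)
  if (is.null(symbols)) symbols <- unclass(alphabet)
  bad <- setdiff(symbols, unclass(alphabet))
  if (length(bad))
    stop("symbols not in alphabet: ", paste(bad, collapse = ", "))
  n <- length(text)
  tab <- matrix(0L, nrow = length(symbols), ncol = n + 1L,
                dimnames = list(symbols, NULL))
  for (r in seq_along(symbols)) {
    tab[r, ] <- .occ_row(text$symbols, symbols[r], n)
  }
  structure(tab, n = n, alphabet = alphabet, class = c("occ_index", "matrix"))
}

# One row: running maximum of positions where the symbol occurs.
.occ_row <- function(tsymbols, symbol, n) {
  if (n == 0L) return(0L)
  pos <- integer(n)
  hit <- which(tsymbols == symbol)
  pos[hit] <- hit
  c(0L, cummax(pos))
}

# Per-symbol engine precomputation, keyed by position in `codes`: the
# occurrence row at j = 1..n and the matching text columns.  Code 0 (text
# unknowns) and -1 (pattern unknowns) yield an all-zero row / no matches.
.occ_tables_for_codes <- function(tcodes, codes, n) {
  occ_int <- mcols <- vector("list", length(codes))
  for (r in seq_along(codes)) {
    if (codes[r] < 1L) {
      occ_int[[r]] <- integer(n)
      mcols[[r]] <- integer(0L)
    } else {
      hit <- which(tcodes == codes[r])
      pos <- integer(n)
      pos[hit] <- hit
      occ_int[[r]] <- cummax(pos)
      mcols[[r]] <- hit
    }
  }
  list(occ_int = occ_int, mcols = mcols)
}

#' Query a last-occurrence index
#'
#' @param index an `occ_index` from [build_occurrence_index()].
#' @param symbol a single alphabet symbol; must be among the indexed rows.
#' @param j column, 0..n.
#' @return The largest 1-based position p <= j at which `symbol` occurs in
#'   the text, or 0 if none.
#' @examples
#' idx <- build_occurrence_index("CATGACTG")
#' last_occurrence(idx, "G", 7)  # 4
#' @export
last_occurrence <- function(index, symbol, j) {
  if (!inherits(index, "occ_index")) stop("index must be an occ_index")
  if (!symbol %in% rownames(index))
    stop("symbol not indexed: ", symbol)
  n <- attr(index, "n")
  if (!is.numeric(j) || length(j) != 1L || j < 0 || j > n)
    stop("j must lie in [0, ", n, "]")
  index[symbol, as.integer(j) + 1L][[1L]]
}

#' @export
print.occ_index <- function(x, ...) {
  cat(sprintf("<occ_index> %d symbol row(s), text length %d\n",
              nrow(x), attr(x, "n")))
  print(`attributes<-`(unclass(x), list(dim = dim(x), dimnames = dimnames(x))))
  invisible(x)
}
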