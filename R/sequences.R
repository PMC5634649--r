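#' Symbol alphabets
#'
#' An alphabet is an ordered set of distinct single-character symbols.  The
#' ordinal of a symbol (its position in the alphabet) indexes the rows of an
#' occurrence index, so the order is part of the object's identity.
#'
#' @param symbols character vector of distinct single-character symbols.
#' @return An `asm_alphabet`: the symbol vector with a class attribute.
#' @examples
#' dna_alphabet()
#' alphabet_ordinal(dna_alphabet(), "G")
#' @export
asm_alphabet <- function(symbols) {
  symbols <- as.character(symbols)
  if (length(symbols) == 0L)
    stop("alphabet must contain at least one symbol")
  if (any(nchar(symbols) != 1L))
    stop("alphabet symbols must be single characters")
  if (anyDuplicated(symbols))
    stop("alphabet symbols must be distinct")
  structure(symbols, class = "asm_alphabet")
}

#' @rdname asm_alphabet
#' @export
dna_alphabet <- function() asm_alphabet(c("A", "C", "G", "T"))

#' @rdname asm_alphabet
#' @param alphabet an [asm_alphabet()].
#' @param symbol a single character.
#' @return `alphabet_ordinal()`: the 1-based position of `symbol` in the
#'   alphabet, or `NA_integer_` if absent.
#' @export
alphabet_ordinal <- function(alphabet, symbol) {
  match(symbol, unclass(alphabet))
}

#' @export
print.asm_alphabet <- function(x, ...) {
  cat("<alphabet> {", paste(unclass(x), collapse = ", "), "}\n")
  invisible(x)
}

#' Sequences over an alphabet
#'
#' A sequence is an identified string of symbols, stored both as characters
#' and as integer codes against its alphabet (code 0 marks symbols outside
#' the alphabet; such symbols are kept but never match any pattern symbol,
#' not even an identical one — the conservative treatment of N and other
#' ambiguity codes).
#'
#' @param x a single character string, a character vector of single symbols,
#'   or an existing `asm_seq`.
#' @param id sequence label.
#' @param alphabet an [asm_alphabet()]; default DNA.
#' @param case_fold uppercase symbols before coding (default `TRUE`).
#' @return An `asm_seq` with fields `id`, `symbols`, `codes`, `alphabet`.
#' @examples
#' asm_seq("catgactg", id = "s1")
#' @export
asm_seq <- function(x, id = "seq", alphabet = dna_alphabet(), case_fold = TRUE) {
  if (inherits(x, "asm_seq")) return(x)
  if (is.character(x) && length(x) == 1L) {
    symbols <- strsplit(x, "", fixed = TRUE)[[1L]]
  } else {
    symbols <- as.character(x)
    if (any(nchar(symbols) != 1L))
      stop("sequence symbols must be single characters")
  }
  if (case_fold) symbols <- toupper(symbols)
  codes <- match(symbols, unclass(alphabet))
  codes[is.na(codes)] <- 0L
  structure(
    list(id = as.character(id), symbols = symbols, codes = as.integer(codes),
         alphabet = alphabet),
    class = "asm_seq"
  )
}

#' @rdname asm_seq
#' @param ... passed on to [asm_seq()].
#' @export
as_asm_seq <- function(x, ...) {
  if (inherits(x, "asm_seq")) x else asm_seq(x, ...)
}

#' @export
length.asm_seq <- function(x) length(x$symbols)

#' @export
as.character.asm_seq <- function(x, ...) paste(x$symbols, collapse = "")

#' @export
print.asm_seq <- function(x, ...) {
  n <- length(x)
  shown <- if (n > 60L) paste0(substr(as.character(x), 1L, 57L), "...")
           else as.character(x)
  cat(sprintf("<asm_seq> %s (%d bp): %s\n", x$id, n, shown))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Parses a (multi-record) FASTA file into a list of [asm_seq()] objects,
#' one per record in file order.  The record id is the header token up to
#' the first whitespace.
#'
#' @param path path to a FASTA file.
#' @param alphabet alphabet used to code the symbols.
#' @param case_fold uppercase the symbols (default `TRUE`).
#' @return A list of `asm_seq`.
#' @export
read_fasta <- function(path, alphabet = dna_alphabet(), case_fold = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    stop("empty FASTA file: ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop(sprintf("malformed FASTA: sequence data before any header at line %d of %s",
                 first, path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (r in seq_along(set)) {
    out[[r]] <- asm_seq(as.character(set[[r]]), id = ids[r],
                        alphabet = alphabet, case_fold = case_fold)
  }
  out
}

#' Write sequences to a FASTA file
#'
#' Deterministic byte output for a fixed input (fixed 70-column wrapping),
#' so identical seeds in the synthetic generator yield byte-identical files.
#'
#' @param seqs an `asm_seq` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "asm_seq")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, as.character, character(1L)))
  names(set) <- vapply(seqs, function(s) s$id, character(1L))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
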