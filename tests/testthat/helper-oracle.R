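# Independent brute-force oracle for the semi-global grid: cell (i, j) is
# the minimum, over every factor of the text ending at column j (including
# the empty factor), of the Levenshtein distance to the pattern prefix of
# length i.  Distances come from utils::adist, so no package DP code is on
# this path.
brute_force_matrix <- function(text, pattern) {
  n <- nchar(text)
  m <- nchar(pattern)
  prefixes <- substring(pattern, 1L, 0:m)
  D <- matrix(0L, nrow = m + 1L, ncol = n + 1L)
  D[, 1L] <- 0:m                       # column 0: only the empty factor
  for (j in seq_len(n)) {
    factors <- substring(text, 1:(j + 1L), j)   # start j+1 gives ""
    d <- utils::adist(factors, prefixes)
    D[, j + 1L] <- apply(d, 2L, min)
  }
  storage.mode(D) <- "integer"
  D
}

rand_string <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# 0-based end positions of every (possibly overlapping) exact occurrence.
naive_exact_ends <- function(text, pattern) {
  n <- nchar(text)
  m <- nchar(pattern)
  if (m == 0L || n < m) return(integer(0))
  starts <- which(vapply(seq_len(n - m + 1L),
                         function(s) substr(text, s, s + m - 1L) == pattern,
                         logical(1)))
  as.integer(starts + m - 2L)
}

# Scalar reference for a single dependency-eliminated row, evaluated
# column-by-column in an arbitrary order (used to check that no output
# column depends on another output column).
scalar_row <- function(previous, i, occ_row, tsyms, psym, order) {
  n <- length(tsyms)
  out <- integer(n + 1L)
  for (j in order) {
    out[j + 1L] <- if (j == 0L) {
      i
    } else if (tsyms[j] == psym) {
      previous[j]
    } else {
      x <- occ_row[j + 1L]
      third <- if (x == 0L) i + j - 1L else previous[x] + (j - 1L - x)
      1L + min(previous[j + 1L], previous[j], third)
    }
  }
  out
}

# Bare (dimname-free) grids for fast cell-for-cell comparison.
grid_oracle <- function(text, pattern) unname(edit_distance_matrix(text, pattern))
grid_rowpar <- function(text, pattern) unname(run_row_parallel(text, pattern, TRUE))
grid_warp <- function(text, pattern, w)
  unname(run_warp_sim(text, pattern, w, TRUE)$distances)
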