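# Warp-shuffle dataflow simulator.
#
# The GPU formulation maps one lane (thread) to each DP column.  After row
# i-1, lane j holds D[i-1, j] in its register Dvar.  For row i each lane
# needs three previous-row values:
#
#   Avar = D[i-1, j-1]  -- register of the lane one below: a shfl_up
#                          exchange, except at warp boundaries (j mod w = 0),
#                          where the neighbour lives in another warp and the
#                          value is read from the row store in memory;
#   Bvar = D[i-1, j]    -- the lane's own Dvar, no traffic;
#   Cvar = D[i-1, X-1]  -- an arbitrary column: always a memory read.
#
# Dvar is then updated by the dependency-eliminated recurrence and written
# back to the row store (the write is required: Cvar reads reach arbitrary
# columns of the previous row).  Rows advance synchronously behind a
# counted barrier.  The simulator reproduces this dataflow one row at a
# time with whole-row register vectors, and tallies every modeled access:
# D-row and occurrence-index reads count as global memory, text/pattern
# reads as shared memory (the per-block substring cache), one shuffle per
# exchanging lane, one sync per row.

#' Warp register exchange (shift up)
#'
#' Simulates the `shfl_up` primitive on one warp's register snapshot: lane
#' x receives the value held by lane x − delta; lanes with lane id below
#' `delta` have no source lane and retain their own value (callers must not
#' rely on those lanes — in the engine they take the memory path instead).
#'
#' @param values the per-lane register values of one warp (length = warp
#'   width, at least 2).
#' @param delta positive lane offset, strictly less than the warp width.
#' @return Vector of the same length: the post-exchange register values.
#' @examples
#' shfl_up(c(10, 11, 12, 13), 1)  # 10 10 11 12
#' @export
shfl_up <- function(values, delta) {
  w <- length(values)
  if (w < 2L) stop("a warp needs at least 2 lanes")
  delta <- as.integer(delta)
  if (length(delta) != 1L || is.na(delta) || delta <= 0L || delta >= w)
    stop("delta must satisfy 1 <= delta < warp width (", w, ")")
  out <- values
  out[(delta + 1L):w] <- values[1:(w - delta)]
  out
}

# Whole-row shfl_up(Dvar, 1) across consecutive warps of width w: within
# each warp, lane 0 retains its own value, every other lane takes its left
# neighbour's register.
.shfl_up_row <- function(v, w) {
  L <- length(v)
  if (L == 1L) return(v)
  out <- c(v[1L], v[-L])
  lane0 <- seq.int(1L, L, by = w)
  out[lane0] <- v[lane0]
  out
}

.counters <- function(reads_D = 0, reads_X = 0, reads_text = 0,
                      reads_pattern = 0, mem_writes = 0, shuffles = 0,
                      syncs = 0, w = NA_real_, n = NA_real_, m = NA_real_) {
  structure(list(
    mem_reads_global = reads_D + reads_X,
    mem_reads_shared = reads_text + reads_pattern,
    reads_D = reads_D, reads_X = reads_X,
    reads_text = reads_text, reads_pattern = reads_pattern,
    mem_writes = mem_writes, shuffles = shuffles, syncs = syncs,
    w = w, n = n, m = m
  ), class = "asm_counters")
}

#' @export
print.asm_counters <- function(x, ...) {
  cat(sprintf("<asm_counters> n=%g m=%g w=%g\n", x$n, x$m, x$w))
  cat(sprintf("  global reads : %g (D rows %g, occurrence index %g)\n",
              x$mem_reads_global, x$reads_D, x$reads_X))
  cat(sprintf("  shared reads : %g (text %g, pattern %g)\n",
              x$mem_reads_shared, x$reads_text, x$reads_pattern))
  cat(sprintf("  writes %g | shuffles %g | syncs %g\n",
              x$mem_writes, x$shuffles, x$syncs))
  invisible(x)
}

#' Write operation counters as a key=value text file
#'
#' @param counters an `asm_counters` (from [run_warp_sim()] or
#'   [predicted_counters()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counters <- function(counters, path) {
  stopifnot(inherits(counters, "asm_counters"))
  keys <- c("mem_reads_global", "mem_reads_shared", "mem_writes",
            "shuffles", "syncs", "w", "n", "m",
            "reads_D", "reads_X", "reads_text", "reads_pattern")
  writeLines(sprintf("%s=%g", keys, vapply(keys, function(k)
    as.numeric(counters[[k]]), numeric(1L))), path)
  invisible(path)
}

#' Run the warp-shuffle engine
#'
#' Simulates the warp-mapped formulation of the row-parallel recurrence
#' (see the dataflow description above) and tallies its modeled memory
#' traffic.  Columns 0..n are partitioned into warps of `warp_width`
#' consecutive lanes; for every row, non-boundary lanes obtain
#' `D[i-1, j-1]` by register exchange while warp-boundary lanes
#' (j mod w = 0, j >= 1) read it from the modeled row store.  Final
#' distances are identical to [edit_distance_matrix()] for every warp
#' width.
#'
#' @param text,pattern an [asm_seq()] or character string.
#' @param warp_width lanes per warp, integer >= 2 (default 32).
#' @param keep_matrix return the full grid instead of the final row.
#' @return List with `distances` (matrix or final row, as
#'   [run_row_parallel()]) and `counters` (an `asm_counters`).
#' @examples
#' run_warp_sim("CATGACTG", "TACTG", warp_width = 4)
#' @export
run_warp_sim <- function(text, pattern, warp_width = 32L, keep_matrix = FALSE) {
  w <- as.integer(warp_width)
  if (length(w) != 1L || is.na(w) || w < 2L)
    stop("warp_width must be an integer >= 2")
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
  boundary_j <- if (n >= w) seq.int(w, n, by = w) else integer(0L)
  n_boundary <- length(boundary_j)

  reads_D <- reads_X <- reads_text <- reads_pattern <- 0
  mem_writes <- shuffles <- syncs <- 0

  prev <- integer(n + 1L)     # modeled row store, D[i-1, ]
  if (keep_matrix) {
    D <- matrix(0L, nrow = m + 1L, ncol = n + 1L)
    if (m > 0L) D[, 1L] <- 0:m
  }
  for (i in seq_len(m)) {
    r <- key[i]
    oin <- tabs$occ_int[[r]]
    Dvar <- prev                       # per-lane registers after row i-1
    Avar <- .shfl_up_row(Dvar, w)      # register exchange, lane 0 retains
    shuffles <- shuffles + (n - n_boundary)
    if (n_boundary) {                  # cross-warp fallback: memory read
      Avar[boundary_j + 1L] <- prev[boundary_j]
      reads_D <- reads_D + n_boundary
    }
    if (n > 0L) {
      A_int <- Avar[-1L]               # Avar of lanes j = 1..n
      B_int <- Dvar[-1L]               # Bvar = own register, no traffic
      chain <- i + jv - 1L             # X = 0 branch term
      pos <- which(oin > 0L)
      if (length(pos))                 # Cvar = D[i-1, X-1] + insertions
        chain[pos] <- prev[oin[pos]] + (jv[pos] - 1L - oin[pos])
      val <- 1L + pmin.int(A_int, B_int, chain)
      mc <- tabs$mcols[[r]]
      if (length(mc)) val[mc] <- A_int[mc]   # match: Dvar = Avar
      prev <- c(i, val)
    } else {
      prev <- i
    }
    reads_D <- reads_D + (n + 1L)      # Cvar issued for every lane
    reads_X <- reads_X + (n + 1L)      # X[l, j] for every lane
    reads_text <- reads_text + n       # T[j-1], lanes j >= 1 (shared)
    reads_pattern <- reads_pattern + n # P[i-1] broadcast to lanes j >= 1
    mem_writes <- mem_writes + (n + 1L)  # write-back D[i, j] = Dvar
    syncs <- syncs + 1                 # row barrier
    if (keep_matrix) D[i + 1L, ] <- prev
  }
  counters <- .counters(reads_D, reads_X, reads_text, reads_pattern,
                        mem_writes, shuffles, syncs, w = w, n = n, m = m)
  distances <- if (keep_matrix) {
    dimnames(D) <- .dp_dimnames(text, pattern)
    D
  } else {
    structure(as.integer(prev), row_index = m)
  }
  list(distances = distances, counters = counters)
}

#' Closed-form operation counts of the warp-shuffle engine
#'
#' Analytic model of the simulator's access pattern for a text of length n,
#' pattern of length m and warp width w; [run_warp_sim()] must reproduce
#' these numbers exactly.  Per row: one Cvar D-read and one occurrence-index
#' read per lane (n+1 each), one boundary Avar D-read per warp start after
#' the first (floor(n/w)), one shuffle per non-boundary lane j in 1..n
#' (n − floor(n/w)), n text and n pattern reads (shared), n+1 write-backs,
#' one barrier.
#'
#' @param n,m text and pattern lengths (>= 0).
#' @param w warp width (>= 2).
#' @return An `asm_counters`.
#' @examples
#' predicted_counters(8, 5, 4)$shuffles  # 30
#' @export
predicted_counters <- function(n, m, w) {
  n <- as.integer(n); m <- as.integer(m); w <- as.integer(w)
  if (is.na(n) || n < 0L || is.na(m) || m < 0L)
    stop("n and m must be non-negative")
  if (is.na(w) || w < 2L) stop("w must be >= 2")
  b <- n %/% w
  .counters(
    reads_D = m * (n + 1 + b),
    reads_X = m * (n + 1),
    reads_text = m * n,
    reads_pattern = m * n,
    mem_writes = m * (n + 1),
    shuffles = m * (n - b),
    syncs = m,
    w = w, n = n, m = m
  )
}

#' Counted memory replay of the plain row-parallel engine
#'
#' The row-parallel recurrence without register exchange reads all three
#' previous-row operands — `D[i-1, j-1]`, `D[i-1, j]` and `D[i-1, X-1]` —
#' from memory for every interior cell (j >= 1), i.e. 3·m·n D-row reads.  This
#' is the baseline against which the warp-shuffle engine's
#' m·(n + 1 + floor(n/w)) D-row reads are compared; their ratio approaches
#' (1 + 1/w)/3 as n grows.
#'
#' @param n,m text and pattern lengths (>= 0).
#' @return An `asm_counters` (shuffles are 0 by construction).
#' @export
rowparallel_replay_counters <- function(n, m) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || n < 0L || is.na(m) || m < 0L)
    stop("n and m must be non-negative")
  .counters(
    reads_D = 3 * m * n,
    reads_X = m * n,
    reads_text = m * n,
    reads_pattern = m * n,
    mem_writes = m * (n + 1),
    shuffles = 0,
    syncs = m,
    w = NA_real_, n = n, m = m
  )
}
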