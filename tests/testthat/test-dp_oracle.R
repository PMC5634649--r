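test_that("worked example grid matches the hand-derived rows", {
  D <- edit_distance_matrix("CATGACTG", "TACTG")
  expect_identical(unname(D[1, ]), rep(0L, 9))
  expect_identical(unname(D[2, ]), c(1L, 1L, 1L, 0L, 1L, 1L, 1L, 0L, 1L))
  expect_identical(unname(D[6, ]), c(5L, 4L, 4L, 3L, 2L, 3L, 3L, 2L, 1L))
  expect_identical(rownames(D), c("", "T", "A", "C", "T", "G"))
})

test_that("degenerate inputs give the boundary rows and columns only", {
  expect_identical(unname(edit_distance_matrix("ACGT", "")),
                   matrix(0L, nrow = 1, ncol = 5))
  expect_identical(unname(edit_distance_matrix("", "TACTG")),
                   matrix(0:5, ncol = 1))
  expect_identical(unname(edit_distance_matrix("", "")),
                   matrix(0L, 1, 1))
})

test_that("grid equals the brute-force minimum over factors", {
  set.seed(101)
  for (r in 1:20) {
    t <- rand_string(sample(5:40, 1))
    p <- rand_string(sample(1:8, 1))
    expect_identical(grid_oracle(t, p), brute_force_matrix(t, p),
                     label = sprintf("instance %d (t=%s, p=%s)", r, t, p))
  }
})

test_that("grid cells respect the Lipschitz and envelope bounds", {
  set.seed(102)
  for (r in 1:10) {
    t <- rand_string(sample(1:50, 1))
    p <- rand_string(sample(1:10, 1))
    D <- unname(edit_distance_matrix(t, p))
    m <- nrow(D) - 1L
    n <- ncol(D) - 1L
    # neighbouring cells differ by at most one in both directions
    if (n > 0) expect_true(all(abs(D[, -1, drop = FALSE] - D[, -(n + 1), drop = FALSE]) <= 1))
    if (m > 0) expect_true(all(abs(D[-1, , drop = FALSE] - D[-(m + 1), , drop = FALSE]) <= 1))
    iv <- matrix(0:m, m + 1L, n + 1L)
    jv <- matrix(0:n, m + 1L, n + 1L, byrow = TRUE)
    expect_true(all(D <= iv))
    expect_true(all(D >= pmax(0, iv - jv)))
  }
})

test_that("appending text never changes existing columns", {
  set.seed(103)
  for (r in 1:5) {
    t <- rand_string(30)
    p <- rand_string(6)
    D1 <- unname(edit_distance_matrix(t, p))
    D2 <- unname(edit_distance_matrix(paste0(t, rand_string(10)), p))
    expect_identical(D2[, 1:31], D1)
  }
})

test_that("global edit distance is the standard Levenshtein distance", {
  expect_identical(global_edit_distance("ACTG", "TACTG"), 1L)
  expect_identical(global_edit_distance("TACTG", "ACTG"), 1L)
  expect_identical(global_edit_distance("GATTACA", "GATTACA"), 0L)
  expect_identical(global_edit_distance("", "TACTG"), 5L)
  # plain symbol identity: ambiguity codes equal themselves here
  expect_identical(global_edit_distance("ANA", "ANA"), 0L)
  set.seed(104)
  for (r in 1:25) {
    a <- rand_string(sample(0:20, 1), c("A", "C", "G", "T", "N"))
    b <- rand_string(sample(0:20, 1), c("A", "C", "G", "T", "N"))
    expect_identical(global_edit_distance(a, b),
                     as.integer(utils::adist(a, b)))
    expect_identical(global_edit_distance(a, b), global_edit_distance(b, a))
  }
})

test_that("match extraction applies the thresholding rule with sentinels", {
  final_row <- c(5L, 4L, 4L, 3L, 2L, 3L, 3L, 2L, 1L)
  hits <- extract_matches(final_row, 2)
  expect_identical(hits$end, c(3L, 6L, 7L))
  expect_identical(hits$distance, c(2L, 2L, 1L))
  expect_identical(attr(hits, "result"),
                   c(-1L, -1L, -1L, 3L, -1L, -1L, 6L, 7L))
  # k >= m reports every position (cells never exceed the row index)
  all_hits <- extract_matches(final_row, 5)
  expect_identical(all_hits$end, 0:7)
  # an all-zero row (empty pattern) matches everywhere at distance 0
  zero <- extract_matches(rep(0L, 9), 0)
  expect_identical(zero$end, 0:7)
  expect_identical(zero$distance, rep(0L, 8))
  expect_error(extract_matches(final_row, -1), "non-negative")
})
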