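# Independent oracles used across the suite. Each is deliberately naive:
# correctness over speed, and no code shared with the implementation path
# it checks.

# Brute-force isotopologue distribution: multiply single-atom polynomials
# one atom at a time.
oracle_isotope_dist <- function(counts, n_dist = NULL) {
  abund <- list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001)
  )
  if (!is.null(n_dist)) abund$N <- n_dist
  poly <- 1
  for (el in names(counts)) {
    for (i in seq_len(counts[[el]])) {
      a <- abund[[el]]
      new <- numeric(length(poly) + length(a) - 1L)
      for (j in seq_along(poly)) {
        new[j:(j + length(a) - 1L)] <- new[j:(j + length(a) - 1L)] +
          poly[j] * a
      }
      poly <- new
    }
  }
  poly
}

# Exhaustive grid-search NNLS: evaluates the residual sum of squares at
# every point of a regular non-negative amplitude grid and returns the
# minimizer. The search is exhaustive; only the residual evaluation is
# vectorized (||y - Ga||^2 = ||y||^2 - 2 a'G'y + a'G'G a).
oracle_grid_nnls <- function(tmat, y, a_max, step) {
  axes <- rep(list(seq(0, a_max, by = step)), ncol(tmat))
  grid <- as.matrix(expand.grid(axes))
  gty <- crossprod(tmat, y)
  gtg <- crossprod(tmat)
  ss <- sum(y^2) - 2 * as.vector(grid %*% gty) +
    rowSums((grid %*% gtg) * grid)
  i <- which.min(ss)
  list(amplitudes = unname(grid[i, ]), ss = ss[i])
}

# Exact permutation null for class enrichment by exhaustive enumeration of
# class memberships (all ways the permuted labels can place the class).
oracle_exact_enrichment_p <- function(ids, hits, class_size, observed) {
  stopifnot(length(ids) <= 8)
  combos <- utils::combn(ids, class_size, simplify = FALSE)
  null_props <- vapply(combos, function(cls) {
    length(intersect(cls, hits)) / class_size
  }, numeric(1))
  mean(null_props >= observed)
}

# Direct set-filter oracle for the compound hit gate.
oracle_gate <- function(od15, od37) {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  names(od15)[od15 < mean(od15) - 3 * pop_sd(od15) &
                od37 > mean(od37) - 2 * pop_sd(od37)]
}

# Compare two probability-by-shift vectors, zero-padding the shorter, on
# absolute scale.
expect_dist_equal <- function(actual, expected, tol = 1e-10, label = NULL) {
  n <- max(length(actual), length(expected))
  a <- c(actual, numeric(n - length(actual)))
  e <- c(expected, numeric(n - length(expected)))
  testthat::expect_lt(max(abs(a - e)), tol)
}

# Build a noiseless stick spectrum from templates and amplitudes.
make_spectrum <- function(templates, amplitudes) {
  mz <- unlist(lapply(templates, function(t) t$mz))
  int <- unlist(mapply(function(t, a) a * t$probability, templates,
                       amplitudes, SIMPLIFY = FALSE))
  agg <- tapply(int, round(mz, 6), sum)
  data.frame(mz = as.numeric(names(agg)), intensity = as.numeric(agg))
}
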