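# Independent brute-force oracles. These deliberately take a different
# route from the package implementation: stats::t.test where the package
# vectorises the formula by hand, explicit formulas where the package calls
# stats::t.test, and from-scratch recomputation where the package uses an
# incremental update.

# pooled-variance two-tailed t-test, one protein at a time, via stats::t.test
oracle_pooled_t <- function(x0, x1) {
  if (stats::sd(c(x0, x1)) == 0) return(1)
  if (stats::sd(x0) == 0 && stats::sd(x1) == 0)
    return(if (mean(x0) == mean(x1)) 1 else 0)
  stats::t.test(x1, x0, var.equal = TRUE)$p.value
}

# Welch t-test by the explicit statistic + CDF
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df)
}

# average-linkage agglomeration recomputing every inter-cluster average
# from the original pairwise similarity matrix at every step (O(n^3));
# same tie-break as the package: lowest first cluster slot, then second.
# Returns the leaf-set merged at each step plus the merge similarity.
oracle_average_linkage <- function(S) {
  n <- nrow(S)
  clusters <- as.list(seq_len(n))
  alive <- rep(TRUE, n)
  steps <- list()
  for (step in seq_len(n - 1)) {
    best <- -Inf; bi <- NA; bj <- NA
    idx <- which(alive)
    for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx)) {
      i <- idx[a]; j <- idx[b]
      s <- mean(S[clusters[[i]], clusters[[j]]])
      if (s > best) { best <- s; bi <- i; bj <- j }
    }
    steps[[step]] <- list(members = sort(c(clusters[[bi]], clusters[[bj]])),
                          similarity = best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    alive[bj] <- FALSE
  }
  steps
}

# leaf sets merged at each step of an hclust-style merge matrix
merge_leaf_sets <- function(merge) {
  sets <- vector("list", nrow(merge))
  grab <- function(v) if (v < 0) -v else sets[[v]]
  for (s in seq_len(nrow(merge)))
    sets[[s]] <- sort(c(grab(merge[s, 1]), grab(merge[s, 2])))
  sets
}

# a small field with all masks, for imaging unit tests
make_test_field <- function(seed = 1, n_cells = 20, fraction = 0.5,
                            shape = c(192L, 192L), ...) {
  gen_image_field(field_truth(n_cells = n_cells,
                              inclusion_fraction = fraction,
                              seed = seed, ...),
                  shape = shape)
}
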