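test_that("threshold derivation reproduces the 1.57-fold arithmetic", {
  expect_equal(derive_threshold(rep(0, 150))$fold_threshold, 1)

  # sample with SD exactly 0.65/3 -> 0.65 log2, 1.57-fold at 2 d.p.
  x <- stats::rnorm(500)
  x <- (x - mean(x)) / stats::sd(x) * (0.65 / 3)
  thr <- derive_threshold(x)
  expect_equal(thr$log2_threshold, 0.65, tolerance = 1e-12)
  expect_equal(round(thr$fold_threshold, 2), 1.57)
  expect_equal(thr$fold_threshold, 2^thr$log2_threshold)

  # Gaussian(0, 0.22) at n = 15000: fold within 2% of 2^0.66
  g <- gen_self_self(15000L, sd = 0.22, seed = 31L)
  expect_lt(abs(derive_threshold(g)$fold_threshold - 2^0.66) / 2^0.66, 0.02)

  expect_error(derive_threshold(rep(0.1, 50)), ">= 100")
  expect_message(derive_threshold(c(stats::rnorm(200), NA, Inf)),
                 "2 non-finite")
})

test_that("threshold converges to 2^(k*sigma) at large n", {
  g <- gen_self_self(1e5, sd = 0.3, seed = 41L)
  expect_lt(abs(derive_threshold(g)$fold_threshold - 2^0.9) / 2^0.9, 0.01)
})

test_that("replicate averaging matches a brute-force mean", {
  e <- gen_array_experiment(array_truth(n_genes = 120L, seed = 6L),
                            strains = c("wt", "m"), n_replicates = 3L)
  avg <- average_replicates(e)
  for (j in seq_len(nrow(avg$strata))) {
    cols <- e$arrays$strain == avg$strata$strain[j] &
      e$arrays$timepoint == avg$strata$timepoint[j]
    expect_equal(avg$means[, j], rowMeans(e$ratios[, cols]),
                 tolerance = 1e-12)
  }
  # single usable replicate passes through; zero replicates flagged NA
  e$ratios[1, e$arrays$strain == "m" & e$arrays$timepoint == 0][2:3] <- NA
  e$ratios[2, e$arrays$strain == "m" & e$arrays$timepoint == 0] <- NA
  avg2 <- average_replicates(e)
  jm0 <- which(avg2$strata$strain == "m" & avg2$strata$timepoint == 0)
  expect_equal(avg2$n[1, jm0], 1L)
  expect_true(is.na(avg2$means[2, jm0]))
})

test_that("mutant effects subtract wild type at the matched timepoint", {
  e <- gen_array_experiment(array_truth(n_genes = 80L, seed = 7L),
                            strains = c("wt", "m"), n_replicates = 2L)
  avg <- average_replicates(e)
  eff <- mutant_effect(avg)
  for (j in seq_len(nrow(eff$strata))) {
    wt <- avg$means[, paste0("wt_", eff$strata$timepoint[j])]
    expect_equal(eff$effects[, j],
                 avg$means[, eff$strata$column[j]] - wt, tolerance = 1e-12)
  }
  # wild type against itself is identically zero
  self <- avg
  self$means[, self$strata$strain == "m"] <-
    self$means[, paste0("wt_", self$strata$timepoint[self$strata$strain == "m"])]
  eff0 <- mutant_effect(self)
  expect_true(all(eff0$effects == 0))

  # planted effect recovery
  tr <- array_truth(n_genes = 200L,
                    planted_effects = data.frame(gene = 5L, strain = "m",
                                                 timepoint = 30, shift = 1),
                    seed = 12L)
  e2 <- gen_array_experiment(tr, strains = c("wt", "m"),
                             timepoints = c(0, 30), n_replicates = 4L)
  eff2 <- mutant_effect(average_replicates(e2))
  se <- 0.22 * sqrt(2 / 4)   # difference of two 4-replicate means
  expect_lt(abs(eff2$effects[5, "m_30"] - 1), 3 * se)
})

test_that("significance calling is boundary-inclusive and monotone", {
  m <- matrix(c(0.65, 0.64, -0.7, 0.2), 4, 1,
              dimnames = list(c("a", "b", "c", "d"), "m_30"))
  expect_identical(call_significant(m, 0.65, "both")$m_30, c("a", "c"))
  expect_identical(call_significant(m, 0.65, "up")$m_30, "a")
  expect_identical(call_significant(m, 0.65, "down")$m_30, "c")

  set.seed(8)
  r <- matrix(rnorm(300), 100, 3,
              dimnames = list(sprintf("g%d", 1:100), c("x", "y", "z")))
  got <- call_significant(r, 0.5, "both")
  for (j in 1:3)
    expect_identical(got[[j]], rownames(r)[abs(r[, j]) >= 0.5])
  # counts monotone non-increasing in the threshold
  counts <- vapply(seq(0, 2, 0.25), function(th)
    sum(lengths(call_significant(r, th, "both"))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("telomere proximity matches brute-force distances", {
  ann <- synthetic_annotation(200L)
  got <- telomere_proximity(ann$genes, ann$chrom_lengths, 25000)
  want <- vapply(seq_len(nrow(ann$genes)), function(i) {
    g <- ann$genes[i, ]
    min(g$start - 1, ann$chrom_lengths[[g$chrom]] - g$end) <= 25000
  }, logical(1))
  expect_identical(got, want)
  expect_true(got[1])                       # first gene starts at bp 1
  expect_error(telomere_proximity(data.frame(chrom = "chrX", start = 1,
                                             end = 10),
                                  ann$chrom_lengths), "unknown")
})

test_that("aneuploidy scan recovers planted segments and masks them", {
  e0 <- gen_array_experiment(array_truth(n_genes = 400L, seed = 14L),
                             strains = c("wt", "m"), n_replicates = 2L)
  scan0 <- detect_aneuploid_region(e0, "m", min_run = 5L,
                                   elevation_cutoff = 0.4)
  expect_identical(nrow(scan0$regions), 0L)

  tr <- array_truth(n_genes = 400L,
                    aneuploid_segment = list(first = 101L, last = 120L,
                                             shift = 0.8, strain = "m",
                                             replicate = 1L),
                    seed = 15L)
  e <- gen_array_experiment(tr, strains = c("wt", "m"), n_replicates = 2L)
  sel <- e$arrays$strain == "m" & e$arrays$replicate == 1L
  scan <- detect_aneuploid_region(e, sel, min_run = 5L,
                                  elevation_cutoff = 0.4)
  expect_identical(scan$regions$first_index, 101L)
  expect_identical(scan$regions$last_index, 120L)
  expect_identical(nrow(scan$masked$ratios), 380L)
  expect_identical(nrow(scan$masked$genes), 380L)

  expect_error(detect_aneuploid_region(e, sel, min_run = 2L), "min_run")
  expect_error(detect_aneuploid_region(e, rep(FALSE, nrow(e$arrays))),
               "no arrays")
})

test_that("two segments on different chromosomes never merge", {
  # chrI holds genes 1..180 of 400; plant one segment per chromosome edge
  ann <- synthetic_annotation(400L)
  chr_end <- max(which(ann$genes$chrom == "chrI"))
  tr <- array_truth(n_genes = 400L,
                    aneuploid_segment = list(first = chr_end - 9L,
                                             last = chr_end, shift = 1,
                                             strain = "m"),
                    seed = 16L)
  e <- gen_array_experiment(tr, strains = c("wt", "m"), n_replicates = 2L)
  # plant a second segment by hand right across the boundary
  sel <- e$arrays$strain == "m"
  e$ratios[(chr_end + 1):(chr_end + 10), sel] <-
    e$ratios[(chr_end + 1):(chr_end + 10), sel] + 1
  scan <- detect_aneuploid_region(e, "m", min_run = 5L,
                                  elevation_cutoff = 0.4)
  expect_identical(nrow(scan$regions), 2L)
  expect_identical(scan$regions$chrom, c("chrI", "chrII"))
})

test_that("set overlaps match brute-force enumeration", {
  a <- c("g1", "g2", "g3"); b <- c("g3", "g4"); c3 <- c("g3", "g5", "g1")
  ov <- set_overlaps(list(A = a, B = b, C = c3))
  expect_identical(unname(ov$pairwise["A", "B"]), 1L)
  expect_identical(unname(ov$regions[["A&B&C"]]), 1L)
  expect_identical(unname(ov$regions[["A&C"]]), 1L)   # g1 only
  expect_identical(unname(ov$regions[["B"]]), 1L)     # g4 only
  disj <- set_overlaps(list(X = c("a", "b"), Y = c("c")))
  expect_identical(unname(disj$pairwise["X", "Y"]), 0L)
  ident <- set_overlaps(list(X = a, Y = a))
  expect_identical(unname(ident$pairwise["X", "Y"]), 3L)

  set.seed(30)
  for (i in 1:20) {
    s1 <- sample(letters, 10); s2 <- sample(letters, 8); s3 <- sample(letters, 12)
    ov <- set_overlaps(list(p = s1, q = s2, r = s3))
    expect_identical(unname(ov$pairwise["p", "q"]),
                     length(intersect(s1, s2)))
    expect_identical(unname(ov$regions[["p&q&r"]]),
                     length(intersect(intersect(s1, s2), s3)))
    expect_identical(unname(ov$regions[["p"]]),
                     length(setdiff(setdiff(s1, s2), s3)))
  }
})
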