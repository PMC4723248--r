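test_that("spectral-count generator is deterministic and matches its own law", {
  tr <- spectral_truth(n_proteins = 500L, planted_proteins = c(1L, 2L),
                       planted_fold = 10, baseline_mean = 20,
                       n_replicates = 3L, seed = 11L)
  a <- gen_spectral_counts(tr)
  b <- gen_spectral_counts(tr)
  expect_identical(a, b)

  # null case: no planted effect -> equal expected sums in both groups
  tr0 <- spectral_truth(n_proteins = 200L, seed = 3L)
  s <- gen_spectral_counts(tr0)
  tp <- s$samples$timepoint[match(colnames(s$truth_counts),
                                  s$samples$sample_id)]
  m0 <- mean(s$truth_counts[, tp == 0])
  m15 <- mean(s$truth_counts[, tp == 15])
  # both are means of 200*3 Poisson(20) draws; SE of the difference ~ 0.26
  expect_lt(abs(m0 - m15), 3 * sqrt(2 * 20 / (200 * 3)))

  # law-of-large-numbers on the planted fold
  tp_a <- a$samples$timepoint[match(colnames(a$truth_counts),
                                    a$samples$sample_id)]
  planted <- a$truth_counts[1:2, , drop = FALSE]
  ratio <- mean(planted[, tp_a == 15]) / mean(planted[, tp_a == 0])
  se <- sqrt(200 / 6 + 100 * 20 / 6) / 20   # delta-method SE of the ratio
  expect_lt(abs(ratio - 10), 3 * se)
})

test_that("filtered peptide sums reproduce the generator's ground truth", {
  s <- gen_spectral_counts(spectral_truth(n_proteins = 120L, seed = 5L))
  kept <- filter_peptides(s$peptides, 0.55)
  pcm <- sum_counts(kept, samples = s$samples)
  expect_identical(unname(pcm$counts[rownames(s$truth_counts),
                                     colnames(s$truth_counts)]),
                   unname(s$truth_counts))
  # unfiltered sums must NOT match: decoys carry extra counts
  pcm_raw <- sum_counts(s$peptides, samples = s$samples)
  expect_gt(sum(pcm_raw$counts), sum(pcm$counts))
})

test_that("array generator plants effects, segments and noise as stated", {
  expect_error(array_truth(replicate_sd = 0), "replicate_sd")
  expect_error(
    array_truth(n_genes = 100L,
                aneuploid_segment = list(first = 40L, last = 50L, shift = 0.8,
                                         strain = "m")),
    "contiguous")
  expect_error(
    gen_array_experiment(
      array_truth(n_genes = 100L,
                  planted_effects = data.frame(gene = 1L, strain = "nope",
                                               timepoint = 30, shift = 1)),
      strains = c("wt", "m"), timepoints = c(0, 30), n_replicates = 2L),
    "unknown strains")

  # no planted effects, no segment -> mean over many arrays near 0
  e0 <- gen_array_experiment(array_truth(n_genes = 300L, seed = 2L),
                             strains = c("wt", "m"), n_replicates = 3L)
  expect_lt(abs(mean(e0$ratios)), 3 * 0.22 / sqrt(length(e0$ratios)))

  # planted +1.0 at (m, 30): recovered within 3 SD/sqrt(n)
  tr <- array_truth(n_genes = 300L,
                    planted_effects = data.frame(gene = 7L, strain = "m",
                                                 timepoint = 30, shift = 1),
                    seed = 4L)
  e <- gen_array_experiment(tr, strains = c("wt", "m"),
                            timepoints = c(0, 30), n_replicates = 4L)
  cols <- e$arrays$strain == "m" & e$arrays$timepoint == 30
  expect_lt(abs(mean(e$ratios[7, cols]) - 1), 3 * 0.22 / sqrt(sum(cols)))

  # aneuploid segment elevates its genes in every flagged array
  tr2 <- array_truth(n_genes = 300L,
                     aneuploid_segment = list(first = 20L, last = 39L,
                                              shift = 0.8, strain = "m",
                                              replicate = 1L),
                     seed = 8L)
  e2 <- gen_array_experiment(tr2, strains = c("wt", "m"), n_replicates = 2L)
  flagged <- which(e2$arrays$strain == "m" & e2$arrays$replicate == 1L)
  for (j in flagged)
    expect_gt(mean(e2$ratios[20:39, j]), mean(e2$ratios[-(20:39), j]))
})

test_that("self-self generator matches its stated moments", {
  x <- gen_self_self(15000L, sd = 0.22, seed = 9L)
  expect_identical(x, gen_self_self(15000L, sd = 0.22, seed = 9L))
  expect_lt(abs(stats::sd(x) - 0.22) / 0.22, 0.02)
  expect_lt(abs(mean(x)), 3 * 0.22 / sqrt(15000))
  expect_error(gen_self_self(1L, 0.22), "n_genes")
  expect_error(gen_self_self(100L, sd = -1), "sd")
})

test_that("image fields honor their ground truth contracts", {
  f0 <- make_test_field(seed = 2, fraction = 0)
  expect_identical(nrow(f0$truth$spots), 0L)

  # spots lie inside their cell, outside the nucleus; cells do not overlap
  f <- make_test_field(seed = 3, fraction = 1)
  idx <- cbind(f$truth$spots$y + 1L, f$truth$spots$x + 1L)
  expect_true(all(f$cell_mask[idx] == f$truth$spots$cell))
  expect_true(all(f$nuclear_mask[idx] == 0L))
  expect_true(all(f$nuclear_mask[f$nuclear_mask > 0] ==
                    f$cell_mask[f$nuclear_mask > 0]))

  # overlap probability 1 with a shared noise draw -> identical channels
  f2 <- gen_image_field(field_truth(n_cells = 15L, inclusion_fraction = 1,
                                    seed = 4L),
                        shape = c(192L, 192L), channels = 2L,
                        overlap_prob = 1, share_noise = TRUE)
  expect_identical(f2$channels[[1]], f2$channels[[2]])

  # binomial check on the planted positive count
  fbig <- gen_image_field(field_truth(n_cells = 200L,
                                      inclusion_fraction = 0.5, seed = 6L),
                          shape = c(640L, 640L))
  ci <- stats::qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(sum(fbig$truth$positive), ci[1])
  expect_lte(sum(fbig$truth$positive), ci[2])

  # infeasible packing fails loudly
  expect_error(gen_image_field(field_truth(n_cells = 100L, seed = 1L),
                               shape = c(64L, 64L)),
               "non-overlapping")
})

test_that("time-course fields follow the trajectory and the master seed", {
  traj <- c("0" = 0, "15" = 0.6, "60" = 0)
  fl <- gen_timecourse_fields(traj, fields_per_timepoint = 2L,
                              template = field_truth(n_cells = 15L),
                              master_seed = 7L, shape = c(192L, 192L))
  expect_length(fl, 6L)
  tps <- vapply(fl, function(f) f$metadata$timepoint, numeric(1))
  pos <- vapply(fl, function(f) sum(f$truth$positive), numeric(1))
  expect_true(all(pos[tps == 0] == 0))
  expect_true(all(pos[tps == 60] == 0))
  expect_gt(sum(pos[tps == 15]), 0)

  fl2 <- gen_timecourse_fields(traj, fields_per_timepoint = 2L,
                               template = field_truth(n_cells = 15L),
                               master_seed = 7L, shape = c(192L, 192L))
  expect_identical(fl, fl2)
  expect_error(gen_timecourse_fields(numeric(0)), "non-empty")

  # pooled planted fraction within its 99% binomial interval
  fl3 <- gen_timecourse_fields(c("15" = 0.3), fields_per_timepoint = 6L,
                               template = field_truth(n_cells = 50L),
                               master_seed = 13L, shape = c(288L, 288L))
  npos <- sum(vapply(fl3, function(f) sum(f$truth$positive), numeric(1)))
  ci <- stats::qbinom(c(0.005, 0.995), 300, 0.3)
  expect_gte(npos, ci[1])
  expect_lte(npos, ci[2])
})
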