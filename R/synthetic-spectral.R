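#' Describe the ground truth of a synthetic spectral-count experiment
#'
#' The MS stage of the pipeline consumes peptide identification tables
#' (protein, peptide, sample, identification probability, spectral count)
#' and calls proteins whose summed counts rise at 15 min of hyperosmotic
#' stress relative to 0 min. This constructor holds the parameters of a
#' simulated affinity-purification experiment with planted stress-enriched
#' proteins, so the caller can be exercised against known truth.
#'
#' Summed per-protein counts are modelled as Poisson with mean
#' `baseline_mean` at 0 min and `baseline_mean * fold` at 15 min for planted
#' proteins (negative-binomial overdispersion available via `dispersion`).
#'
#' @param n_proteins number of proteins in the roster.
#' @param planted_proteins integer indices (into the roster) of proteins with
#'   a planted stress effect. May be empty.
#' @param planted_fold fold enrichment at 15 min for each planted protein
#'   (recycled); all values must be >= 1.
#' @param baseline_mean expected summed spectral count per protein per
#'   sample at 0 min; must be > 0.
#' @param n_replicates replicates per timepoint group; must be >= 2.
#' @param peptides_per_protein number of distinct peptides each protein's
#'   summed count is split across (uniform multinomial split).
#' @param frac_below_cutoff expected fraction of peptide records that are
#'   low-confidence decoys with identification probability below
#'   `prob_cutoff`; these carry extra counts that the probability filter
#'   must remove before sums match the ground truth.
#' @param prob_cutoff identification-probability boundary separating decoy
#'   records from confident ones (default 0.55, the filter's default).
#' @param dispersion negative-binomial size parameter; `Inf` (default)
#'   gives pure Poisson counts.
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return an object of class `spectral_truth`.
#' @export
spectral_truth <- function(n_proteins = 500L,
                           planted_proteins = integer(0),
                           planted_fold = numeric(0),
                           baseline_mean = 20,
                           n_replicates = 3L,
                           peptides_per_protein = 4L,
                           frac_below_cutoff = 0.1,
                           prob_cutoff = 0.55,
                           dispersion = Inf,
                           seed = 1L) {
  if (!is.numeric(baseline_mean) || baseline_mean <= 0)
    stop("baseline_mean must be a positive number")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  planted_proteins <- as.integer(planted_proteins)
  if (length(planted_proteins)) {
    if (any(planted_proteins < 1 | planted_proteins > n_proteins))
      stop("planted_proteins must index the protein roster")
    planted_fold <- rep_len(planted_fold, length(planted_proteins))
    if (any(planted_fold < 1)) stop("planted_fold must be >= 1")
  }
  if (frac_below_cutoff < 0 || frac_below_cutoff >= 1)
    stop("frac_below_cutoff must be in [0, 1)")
  structure(list(n_proteins = as.integer(n_proteins),
                 planted_proteins = planted_proteins,
                 planted_fold = planted_fold,
                 baseline_mean = baseline_mean,
                 n_replicates = as.integer(n_replicates),
                 peptides_per_protein = as.integer(peptides_per_protein),
                 frac_below_cutoff = frac_below_cutoff,
                 prob_cutoff = prob_cutoff,
                 dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "spectral_truth")
}

#' Generate a synthetic peptide identification table
#'
#' Emulates the structure of a filtered X!Tandem search result: one row per
#' (protein, peptide, sample) with an identification probability and a
#' spectral count. Confident records carry probabilities in
#' `[prob_cutoff, 1]` and their per-protein sums reproduce the Poisson (or
#' negative-binomial) draws of the truth model exactly; decoy records carry
#' probabilities below the cutoff and extra counts, so downstream sums match
#' the ground truth only after probability filtering.
#'
#' @param truth a [spectral_truth()] object.
#' @return list with `peptides` (data.frame: protein_id, peptide, sample_id,
#'   timepoint, replicate, probability, spectral_count), `truth_counts`
#'   (protein x sample matrix of true summed counts), `samples` (data.frame
#'   of sample metadata) and `truth` (the input object).
#' @export
gen_spectral_counts <- function(truth) {
  stopifnot(inherits(truth, "spectral_truth"))
  set.seed(truth$seed)
  np <- truth$n_proteins
  proteins <- sprintf("P%04d", seq_len(np))
  fold <- rep(1, np)
  fold[truth$planted_proteins] <- truth$planted_fold

  samples <- expand.grid(replicate = seq_len(truth$n_replicates),
                         timepoint = c(0L, 15L))
  samples <- samples[, c("timepoint", "replicate")]
  samples$sample_id <- sprintf("t%02d_r%d", samples$timepoint, samples$replicate)
  ns <- nrow(samples)

  mu <- matrix(truth$baseline_mean, np, ns)
  mu[, samples$timepoint == 15L] <- truth$baseline_mean * fold
  counts <- if (is.finite(truth$dispersion)) {
    matrix(stats::rnbinom(np * ns, mu = mu, size = truth$dispersion), np, ns)
  } else {
    matrix(stats::rpois(np * ns, lambda = mu), np, ns)
  }
  dimnames(counts) <- list(proteins, samples$sample_id)

  k <- truth$peptides_per_protein
  recs <- vector("list", ns)
  for (s in seq_len(ns)) {
    split <- matrix(0L, k, np)
    nz <- which(counts[, s] > 0L)
    if (length(nz))
      split[, nz] <- vapply(nz, function(p)
        as.integer(stats::rmultinom(1L, counts[p, s], rep(1 / k, k))),
        integer(k))
    keep <- which(split > 0L, arr.ind = TRUE)
    recs[[s]] <- data.frame(
      protein_id = proteins[keep[, 2L]],
      peptide = sprintf("%s_pep%d", proteins[keep[, 2L]], keep[, 1L]),
      sample_id = samples$sample_id[s],
      timepoint = samples$timepoint[s],
      replicate = samples$replicate[s],
      spectral_count = split[keep],
      stringsAsFactors = FALSE)
  }
  pep <- do.call(rbind, recs)
  pep$probability <- stats::runif(nrow(pep), truth$prob_cutoff, 1)

  # low-confidence decoys: extra counts that only survive if the caller
  # forgets to filter on identification probability
  f <- truth$frac_below_cutoff
  n_decoy <- round(nrow(pep) * f / (1 - f))
  if (n_decoy > 0) {
    dp <- sample.int(np, n_decoy, replace = TRUE)
    ds <- sample.int(ns, n_decoy, replace = TRUE)
    decoys <- data.frame(
      protein_id = proteins[dp],
      peptide = sprintf("%s_decoy%d", proteins[dp], seq_len(n_decoy)),
      sample_id = samples$sample_id[ds],
      timepoint = samples$timepoint[ds],
      replicate = samples$replicate[ds],
      spectral_count = 1L + stats::rpois(n_decoy, 1),
      stringsAsFactors = FALSE)
    decoys$probability <- stats::runif(n_decoy, 0, truth$prob_cutoff - 1e-9)
    pep <- rbind(pep, decoys)
  }
  pep <- pep[order(pep$sample_id, pep$protein_id, pep$peptide), ]
  rownames(pep) <- NULL
  pep <- pep[, c("protein_id", "peptide", "sample_id", "timepoint",
                 "replicate", "probability", "spectral_count")]

  list(peptides = pep, truth_counts = counts,
       samples = samples[, c("sample_id", "timepoint", "replicate")],
       truth = truth)
}
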