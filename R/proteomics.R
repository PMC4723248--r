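#' Filter peptide identifications by probability
#'
#' Keeps exactly the records whose identification probability (e.g. a
#' PeptideProphet posterior) is at or above the cutoff; the boundary is
#' inclusive. Row order is preserved.
#'
#' @param records data.frame with at least a `probability` column in
#'   \[0, 1\].
#' @param min_probability cutoff in \[0, 1\] (default 0.55).
#' @return the retained rows of `records`.
#' @export
filter_peptides <- function(records, min_probability = 0.55) {
  stopifnot(is.data.frame(records), "probability" %in% names(records),
            min_probability >= 0, min_probability <= 1)
  p <- records$probability
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("identification probabilities must be finite and in [0, 1]")
  records[p >= min_probability, , drop = FALSE]
}

#' Sum spectral counts to a protein x sample matrix
#'
#' Cell (protein, sample) holds the sum of spectral counts over all peptide
#' records of that protein in that sample; proteins or samples with no
#' record get 0 (and appear only if present in the records or declared in
#' the roster). Records are assumed already probability-filtered.
#'
#' @param records data.frame with columns protein_id, sample_id,
#'   spectral_count, timepoint, replicate.
#' @param proteins optional character roster of protein ids to force into
#'   the matrix (rows of all-zero counts if unobserved).
#' @param samples optional data.frame roster (sample_id, timepoint,
#'   replicate) declaring samples even if unobserved.
#' @return object of class `protein_counts`: list with `counts` (integer
#'   matrix) and `samples` (data.frame: sample_id, timepoint, replicate).
#' @export
sum_counts <- function(records, proteins = NULL, samples = NULL) {
  stopifnot(is.data.frame(records),
            all(c("protein_id", "sample_id", "spectral_count") %in%
                  names(records)))
  if (nrow(records) && any(records$spectral_count < 0))
    stop("spectral counts must be non-negative")
  if (is.null(samples)) {
    samples <- unique(records[, c("sample_id", "timepoint", "replicate")])
    samples <- samples[order(samples$timepoint, samples$replicate), ]
  }
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique")
  rownames(samples) <- NULL
  prot <- sort(unique(c(records$protein_id, proteins)))
  counts <- matrix(0L, length(prot), nrow(samples),
                   dimnames = list(prot, samples$sample_id))
  if (nrow(records)) {
    agg <- stats::aggregate(spectral_count ~ protein_id + sample_id,
                            data = records, FUN = sum)
    counts[cbind(match(agg$protein_id, prot),
                 match(agg$sample_id, samples$sample_id))] <-
      as.integer(agg$spectral_count)
  }
  structure(list(counts = counts, samples = samples),
            class = "protein_counts")
}

#' Test per-protein enrichment of 15-min over 0-min spectral counts
#'
#' For each protein: fold change is the ratio of total summed counts in the
#' 15-min samples to the 0-min samples (`Inf` when the 0-min total is 0 and
#' the 15-min total is positive; 1 with p = 1 when both are 0); the p value
#' is a two-tailed pooled-variance (homoscedastic) t test comparing the
#' per-replicate summed counts between the two timepoint groups. When both
#' groups are constant the p value is 1 for equal means and 0 otherwise.
#'
#' The t statistics are computed row-wise (vectorised over proteins) with
#' the classical pooled-variance formula and `stats::pt`.
#'
#' @param pcm a `protein_counts` object from [sum_counts()]; each timepoint
#'   group must have >= 2 replicates.
#' @param pseudocount added to both totals before the ratio (default 0, i.e.
#'   zero denominators yield `Inf`).
#' @return data.frame: protein_id, sum0, sum15, fold_change, p_value.
#' @export
test_enrichment <- function(pcm, pseudocount = 0) {
  stopifnot(inherits(pcm, "protein_counts"), pseudocount >= 0)
  g0 <- pcm$samples$timepoint == 0
  g15 <- pcm$samples$timepoint == 15
  n0 <- sum(g0); n1 <- sum(g15)
  if (n0 < 2 || n1 < 2)
    stop("need >= 2 replicates per timepoint group (have ", n0, " and ", n1,
         "); the t-test is undefined otherwise")
  x0 <- pcm$counts[, g0, drop = FALSE]
  x1 <- pcm$counts[, g15, drop = FALSE]
  s0 <- rowSums(x0); s1 <- rowSums(x1)
  m0 <- s0 / n0; m1 <- s1 / n1
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
  se <- sqrt(sp2 * (1 / n0 + 1 / n1))
  tstat <- (m1 - m0) / se
  p <- 2 * stats::pt(-abs(tstat), df = n0 + n1 - 2)
  degen <- se == 0
  p[degen] <- ifelse(m0[degen] == m1[degen], 1, 0)

  fold <- (s1 + pseudocount) / (s0 + pseudocount)
  both0 <- s0 + pseudocount == 0 & s1 + pseudocount == 0
  fold[both0] <- 1
  p[both0] <- 1
  data.frame(protein_id = rownames(pcm$counts), sum0 = s0, sum15 = s1,
             fold_change = fold, p_value = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Call stress-enriched proteins
#'
#' A protein passes when its fold change is at least `fold_min` and its
#' p value at most `p_max`; both boundaries inclusive (the defaults encode
#' the gate: >= 3-fold and p <= 0.01). Output is sorted by descending fold
#' change, ties broken by ascending p value, then protein id.
#'
#' @param results data.frame from [test_enrichment()].
#' @param fold_min minimum fold change (default 3).
#' @param p_max maximum p value (default 0.01).
#' @return `results` with a logical `passes` column, sorted.
#' @export
call_enriched <- function(results, fold_min = 3, p_max = 0.01) {
  stopifnot(is.data.frame(results),
            all(c("protein_id", "fold_change", "p_value") %in% names(results)))
  results$passes <- results$fold_change >= fold_min & results$p_value <= p_max
  ord <- order(-results$fold_change, results$p_value, results$protein_id)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
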