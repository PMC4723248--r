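#' Deterministic synthetic genome annotation
#'
#' Three chromosomes with evenly spaced genes (width 1000 bp, spacing
#' 2000 bp, 1-based inclusive coordinates), split 45/35/20 percent across
#' chromosomes in genome order. Chromosome length equals the span of its
#' genes, so the first and last genes of each chromosome sit at the
#' telomeres. Purely deterministic, so telomere-proximity and aneuploidy
#' tests have exact expected answers.
#'
#' @param n_genes total number of genes.
#' @return list with `genes` (data.frame: gene_id, chrom, start, end, in
#'   genome order) and `chrom_lengths` (named integer vector).
#' @export
synthetic_annotation <- function(n_genes) {
  stopifnot(n_genes >= 3)
  props <- c(chrI = 0.45, chrII = 0.35, chrIII = 0.20)
  n_per <- diff(c(0L, round(cumsum(props) * n_genes)))
  names(n_per) <- names(props)
  genes <- do.call(rbind, lapply(names(n_per), function(ch) {
    k <- n_per[[ch]]
    start <- 2000L * (seq_len(k) - 1L) + 1L
    data.frame(chrom = ch, start = start, end = start + 999L,
               stringsAsFactors = FALSE)
  }))
  genes <- data.frame(gene_id = sprintf("G%05d", seq_len(nrow(genes))), genes,
                      stringsAsFactors = FALSE)
  lengths <- vapply(split(genes$end, genes$chrom), max, integer(1))
  list(genes = genes, chrom_lengths = lengths[names(n_per)])
}

#' Describe the ground truth of a synthetic two-color array experiment
#'
#' Per-gene log2 expression ratios are modelled as
#' planted effect + aneuploid shift + Gaussian(0, replicate_sd) noise.
#' `replicate_sd` defaults to 0.22 log2 units, the technical spread of a
#' self-self (wt x wt) hybridization.
#'
#' @param n_genes number of genes (synthetic annotation is derived from it).
#' @param replicate_sd per-array Gaussian noise SD in log2 units; > 0.
#' @param planted_effects NULL or a data.frame with columns `gene` (integer
#'   index in genome order), `strain`, `timepoint`, `shift` (log2 units).
#' @param aneuploid_segment NULL or a list with `first`, `last` (global gene
#'   indices, contiguous on one chromosome), `shift` (log2), `strain`, and
#'   optional `replicate` (the flagged biological sample; NULL = all
#'   replicates of the strain).
#' @param seed integer seed.
#' @return an object of class `array_truth`.
#' @export
array_truth <- function(n_genes = 1500L, replicate_sd = 0.22,
                        planted_effects = NULL, aneuploid_segment = NULL,
                        seed = 1L) {
  if (!is.numeric(replicate_sd) || replicate_sd <= 0)
    stop("replicate_sd must be > 0")
  ann <- synthetic_annotation(n_genes)
  if (!is.null(planted_effects)) {
    stopifnot(is.data.frame(planted_effects),
              all(c("gene", "strain", "timepoint", "shift") %in%
                    names(planted_effects)))
    if (any(planted_effects$gene < 1 | planted_effects$gene > n_genes))
      stop("planted_effects$gene out of range")
  }
  if (!is.null(aneuploid_segment)) {
    seg <- aneuploid_segment
    stopifnot(all(c("first", "last", "shift", "strain") %in% names(seg)))
    if (seg$first > seg$last || seg$first < 1 || seg$last > n_genes)
      stop("aneuploid segment indices out of range")
    if (length(unique(ann$genes$chrom[seg$first:seg$last])) != 1L)
      stop("aneuploid segment must be contiguous on one chromosome")
  }
  structure(list(n_genes = as.integer(n_genes), replicate_sd = replicate_sd,
                 planted_effects = planted_effects,
                 aneuploid_segment = aneuploid_segment,
                 annotation = ann, seed = as.integer(seed)),
            class = "array_truth")
}

#' Generate a synthetic gene-expression experiment
#'
#' One array per (strain, timepoint, replicate); each array's per-gene log2
#' ratio is the planted effect (0 for unplanted genes) plus the aneuploid
#' shift (for genes inside the segment on arrays of the flagged biological
#' sample) plus Gaussian noise of SD `replicate_sd`.
#'
#' @param truth an [array_truth()] object.
#' @param strains character vector of strain labels; must include
#'   `wild_type`.
#' @param timepoints numeric vector of timepoints in minutes.
#' @param n_replicates replicates per (strain, timepoint); >= 2.
#' @param wild_type the wild-type strain label (default `"wt"`).
#' @return an expression set: list with `ratios` (gene x array matrix),
#'   `arrays` (data.frame: array_id, strain, timepoint, replicate), `genes`,
#'   `chrom_lengths`, and `truth`. Class `expr_set`.
#' @export
gen_array_experiment <- function(truth, strains = c("wt", "mut"),
                                 timepoints = c(0, 30, 60),
                                 n_replicates = 2L, wild_type = "wt") {
  stopifnot(inherits(truth, "array_truth"))
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (!wild_type %in% strains) stop("strains must include the wild-type label")
  pe <- truth$planted_effects
  if (!is.null(pe)) {
    if (!all(pe$strain %in% strains))
      stop("planted_effects reference unknown strains: ",
           paste(setdiff(pe$strain, strains), collapse = ", "))
    if (!all(pe$timepoint %in% timepoints))
      stop("planted_effects reference unknown timepoints: ",
           paste(setdiff(pe$timepoint, timepoints), collapse = ", "))
  }
  set.seed(truth$seed)
  arrays <- expand.grid(replicate = seq_len(n_replicates),
                        timepoint = timepoints, strain = strains,
                        stringsAsFactors = FALSE)
  arrays <- arrays[, c("strain", "timepoint", "replicate")]
  arrays$array_id <- sprintf("%s_%g_%d", arrays$strain, arrays$timepoint,
                             arrays$replicate)
  ng <- truth$n_genes
  na <- nrow(arrays)

  signal <- matrix(0, ng, na, dimnames = list(truth$annotation$genes$gene_id,
                                              arrays$array_id))
  if (!is.null(pe)) {
    for (i in seq_len(nrow(pe))) {
      cols <- arrays$strain == pe$strain[i] & arrays$timepoint == pe$timepoint[i]
      signal[pe$gene[i], cols] <- signal[pe$gene[i], cols] + pe$shift[i]
    }
  }
  seg <- truth$aneuploid_segment
  if (!is.null(seg)) {
    cols <- arrays$strain == seg$strain
    if (!is.null(seg$replicate)) cols <- cols & arrays$replicate == seg$replicate
    signal[seg$first:seg$last, cols] <- signal[seg$first:seg$last, cols] +
      seg$shift
  }
  ratios <- signal + matrix(stats::rnorm(ng * na, 0, truth$replicate_sd), ng, na)
  dimnames(ratios) <- dimnames(signal)

  structure(list(ratios = ratios,
                 arrays = arrays[, c("array_id", "strain", "timepoint",
                                     "replicate")],
                 genes = truth$annotation$genes,
                 chrom_lengths = truth$annotation$chrom_lengths,
                 wild_type = wild_type,
                 truth = truth),
            class = "expr_set")
}

#' Generate self-self (wt x wt) hybridization log2 ratios
#'
#' A self-self array cohybridizes two aliquots of the same unstressed
#' wild-type sample, so its log2 ratios are pure technical noise; their
#' spread defines the empirical null used to threshold real expression
#' changes. Modelled as i.i.d. Gaussian(0, sd).
#'
#' @param n_genes number of features; >= 2.
#' @param sd technical noise SD in log2 units; > 0 (default 0.22).
#' @param seed integer seed.
#' @return numeric vector of length `n_genes`.
#' @export
gen_self_self <- function(n_genes, sd = 0.22, seed = 1L) {
  if (!is.numeric(sd) || sd <= 0) stop("sd must be > 0")
  if (n_genes < 2) stop("n_genes must be >= 2")
  set.seed(as.integer(seed))
  stats::rnorm(n_genes, 0, sd)
}
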