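#' Derive an expression-change threshold from a self-self null
#'
#' The spread of log2 ratios on a self-self (wt x wt) hybridization is pure
#' technical noise; a change is called real when it exceeds `k` standard
#' deviations of that null (default k = 3). The threshold is centered at 0
#' (the null mean is reported for QC but not subtracted). The sample SD
#' uses the n-1 denominator. With a null SD of 0.22 log2 units the default
#' gives +/-0.65 log2 units, a 1.57-fold change.
#'
#' @param self_self_ratios numeric vector of log2 ratios; >= 100 finite
#'   values required (non-finite values are dropped with a message).
#' @param k number of null SDs (default 3); > 0.
#' @return object of class `threshold_result`: list with `null_sd`,
#'   `null_mean`, `k`, `log2_threshold` (= k * null_sd), `fold_threshold`
#'   (= 2^log2_threshold), `n_used`, `n_dropped`.
#' @export
derive_threshold <- function(self_self_ratios, k = 3) {
  stopifnot(is.numeric(self_self_ratios), k > 0)
  fin <- is.finite(self_self_ratios)
  if (any(!fin))
    message("derive_threshold: dropping ", sum(!fin), " non-finite ratios")
  x <- self_self_ratios[fin]
  if (length(x) < 100)
    stop("need >= 100 finite self-self ratios to estimate the null (have ",
         length(x), ")")
  s <- stats::sd(x)
  structure(list(null_sd = s, null_mean = mean(x), k = k,
                 log2_threshold = k * s, fold_threshold = 2^(k * s),
                 n_used = length(x), n_dropped = sum(!fin)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "empirical-null threshold: SD %.4f log2 (n = %d), k = %g -> +/-%.2f log2 = %.2f-fold\n",
    x$null_sd, x$n_used, x$k, x$log2_threshold, x$fold_threshold))
  invisible(x)
}

#' Average log2 ratios across replicate arrays
#'
#' Arithmetic mean per gene within each (strain, timepoint) stratum.
#' Missing values are excluded pairwise and the per-cell count of usable
#' replicates is recorded; a cell with zero usable replicates is NA.
#'
#' @param expr an `expr_set` (see [gen_array_experiment()] or
#'   [read_expr_set()]).
#' @return list with `means` (gene x stratum matrix, columns named
#'   strain_timepoint), `n` (matrix of per-cell replicate counts), and
#'   `strata` (data.frame: column, strain, timepoint).
#' @export
average_replicates <- function(expr) {
  stopifnot(inherits(expr, "expr_set"))
  key <- paste(expr$arrays$strain, expr$arrays$timepoint, sep = "_")
  strata <- unique(data.frame(column = key, strain = expr$arrays$strain,
                              timepoint = expr$arrays$timepoint,
                              stringsAsFactors = FALSE))
  rownames(strata) <- NULL
  means <- matrix(NA_real_, nrow(expr$ratios), nrow(strata),
                  dimnames = list(rownames(expr$ratios), strata$column))
  nmat <- matrix(0L, nrow(expr$ratios), nrow(strata),
                 dimnames = dimnames(means))
  for (j in seq_len(nrow(strata))) {
    cols <- key == strata$column[j]
    sub <- expr$ratios[, cols, drop = FALSE]
    nmat[, j] <- rowSums(is.finite(sub))
    means[, j] <- rowMeans(sub, na.rm = TRUE)
    means[nmat[, j] == 0, j] <- NA_real_
  }
  list(means = means, n = nmat, strata = strata)
}

#' Mutant-effect ratios
#'
#' Per gene, the averaged mutant log2 ratio minus the averaged wild-type
#' log2 ratio at the matched timepoint (a subtraction in log2 space). Cells
#' whose wild-type counterpart is missing are NA.
#'
#' @param avg result of [average_replicates()].
#' @param wild_type wild-type strain label.
#' @return list with `effects` (gene x mutant-stratum matrix) and `strata`
#'   (data.frame for the retained mutant columns).
#' @export
mutant_effect <- function(avg, wild_type = "wt") {
  stopifnot(is.list(avg), !is.null(avg$means), !is.null(avg$strata))
  st <- avg$strata
  if (!any(st$strain == wild_type))
    stop("wild-type strain '", wild_type, "' absent from the averaged data")
  mut <- st[st$strain != wild_type, , drop = FALSE]
  effects <- matrix(NA_real_, nrow(avg$means), nrow(mut),
                    dimnames = list(rownames(avg$means), mut$column))
  for (j in seq_len(nrow(mut))) {
    wcol <- st$column[st$strain == wild_type & st$timepoint == mut$timepoint[j]]
    if (length(wcol) == 1L)
      effects[, j] <- avg$means[, mut$column[j]] - avg$means[, wcol]
    else
      warning("no wild-type arrays at timepoint ", mut$timepoint[j],
              "; mutant effects undefined there")
  }
  rownames(mut) <- NULL
  list(effects = effects, strata = mut)
}

#' Select genes beyond a log2 threshold
#'
#' Per column of a log2-value matrix, the genes at or beyond the threshold:
#' `up` means value >= threshold, `down` means value <= -threshold, `both`
#' means |value| >= threshold. Boundaries are inclusive. NA values never
#' qualify.
#'
#' @param values numeric matrix (genes x conditions) of log2 values with
#'   rownames.
#' @param log2_threshold non-negative threshold in log2 units.
#' @param direction one of "both", "up", "down".
#' @return named list (one element per column) of gene-id character
#'   vectors.
#' @export
call_significant <- function(values, log2_threshold,
                             direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(values), log2_threshold >= 0)
  sel <- switch(direction,
                up = values >= log2_threshold,
                down = values <= -log2_threshold,
                both = abs(values) >= log2_threshold)
  sel[is.na(sel)] <- FALSE
  lapply(seq_len(ncol(values)), function(j) rownames(values)[sel[, j]]) |>
    stats::setNames(colnames(values))
}

#' Flag telomere-proximal genes
#'
#' A gene is telomere-proximal when its distance to the nearer chromosome
#' end — min(start - 1, chromosome length - end) with 1-based inclusive
#' coordinates — is at most `max_distance_bp`.
#'
#' @param genes data.frame with columns chrom, start, end.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param max_distance_bp distance cutoff in bp; > 0 (default 25000).
#' @return logical vector, one per gene.
#' @export
telomere_proximity <- function(genes, chrom_lengths, max_distance_bp = 25000) {
  stopifnot(is.data.frame(genes),
            all(c("chrom", "start", "end") %in% names(genes)),
            max_distance_bp > 0)
  unknown <- setdiff(unique(genes$chrom), names(chrom_lengths))
  if (length(unknown))
    stop("genes on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  len <- chrom_lengths[genes$chrom]
  pmin(genes$start - 1, len - genes$end) <= max_distance_bp
}

#' Detect and mask aneuploid chromosome segments
#'
#' A copy-number gain in one biological sample shows as a contiguous run of
#' genes with uniformly elevated log2 ratios on every array of that sample.
#' Per gene, the mean ratio across the selected arrays is computed; maximal
#' runs of at least `min_run` consecutive genes (genome order, one
#' chromosome) whose mean exceeds `elevation_cutoff` AND which sit above 0
#' on every individual selected array are reported, and a copy of the
#' expression set with those genes removed is returned.
#'
#' @param expr an `expr_set`.
#' @param arrays_select which arrays belong to the suspect biological
#'   sample: a strain label (all its arrays), a logical vector over arrays,
#'   or integer indices.
#' @param min_run minimum run length in genes; >= 3.
#' @param elevation_cutoff log2 elevation the run mean must exceed
#'   (typically 3x the null SD).
#' @return list with `regions` (data.frame: chrom, first_gene, last_gene,
#'   first_index, last_index, n_genes, span_bp, mean_elevation) and
#'   `masked` (the expression set without the region genes).
#' @export
detect_aneuploid_region <- function(expr, arrays_select, min_run = 5L,
                                    elevation_cutoff = 3 * 0.22) {
  stopifnot(inherits(expr, "expr_set"))
  if (min_run < 3) stop("min_run must be >= 3")
  sel <- if (is.character(arrays_select)) expr$arrays$strain %in% arrays_select
         else if (is.logical(arrays_select)) arrays_select
         else seq_len(nrow(expr$arrays)) %in% arrays_select
  if (!any(sel)) stop("arrays_select selects no arrays")
  ord <- order(match(expr$genes$chrom, unique(expr$genes$chrom)),
               expr$genes$start)
  sub <- expr$ratios[ord, sel, drop = FALSE]
  genes <- expr$genes[ord, , drop = FALSE]
  m <- rowMeans(sub)
  all_above0 <- rowSums(sub > 0) == ncol(sub)
  cand <- m > elevation_cutoff & all_above0

  regions <- list()
  r <- rle(paste(cand, genes$chrom))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths)) {
    if (startsWith(r$values[i], "TRUE") && r$lengths[i] >= min_run) {
      a <- starts[i]; b <- ends[i]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = genes$chrom[a],
        first_gene = genes$gene_id[a], last_gene = genes$gene_id[b],
        first_index = a, last_index = b, n_genes = b - a + 1L,
        span_bp = genes$end[b] - genes$start[a] + 1L,
        mean_elevation = mean(m[a:b]),
        stringsAsFactors = FALSE)
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(0), first_gene = character(0),
               last_gene = character(0), first_index = integer(0),
               last_index = integer(0), n_genes = integer(0),
               span_bp = integer(0), mean_elevation = numeric(0),
               stringsAsFactors = FALSE)

  masked <- expr
  if (nrow(regions)) {
    drop <- unlist(lapply(seq_len(nrow(regions)), function(i)
      genes$gene_id[regions$first_index[i]:regions$last_index[i]]))
    keep <- !rownames(expr$ratios) %in% drop
    masked$ratios <- expr$ratios[keep, , drop = FALSE]
    masked$genes <- expr$genes[!expr$genes$gene_id %in% drop, , drop = FALSE]
  }
  list(regions = regions, masked = masked)
}

#' Uncentered correlation (cosine similarity)
#'
#' sum(x*y) / sqrt(sum(x^2) * sum(y^2)) over the positions where both
#' vectors are finite — Pearson correlation without mean-centering, the
#' similarity classically used for expression clustering.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return a value in \[-1, 1\].
#' @export
uncentered_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("vectors must have length >= 2")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  nx <- sum(x^2); ny <- sum(y^2)
  if (nx == 0 || ny == 0)
    stop("uncentered correlation undefined: a vector has zero norm")
  sum(x * y) / sqrt(nx * ny)
}

# hclust merge-row convention: singletons (negative) before internal nodes
# (positive); two singletons by ascending label, two nodes ascending.
order_merge_pair <- function(a, b) {
  if (a < 0 && b < 0) c(-min(-a, -b), -max(-a, -b))
  else if (a < 0 || b < 0) c(min(a, b), max(a, b))
  else c(min(a, b), max(a, b))
}

#' Average-linkage hierarchical clustering on a similarity
#'
#' Agglomerative clustering of matrix rows: at each step the pair of
#' clusters with the largest average inter-cluster similarity merges (ties
#' broken deterministically by the lowest pair of cluster indices in
#' creation order). Merge heights are 1 - similarity. The average linkage
#' is maintained by the weighted (Lance-Williams) update
#' s(i+j, k) = (n_i s(i,k) + n_j s(j,k)) / (n_i + n_j), which equals the
#' mean pairwise similarity between cluster members.
#'
#' @param mat numeric matrix, >= 2 rows; rows are clustered.
#' @param similarity function(x, y) -> similarity in \[-1, 1\] (default
#'   [uncentered_correlation()]).
#' @return an object of class `hclust` (merge, height, order, labels),
#'   plus component `merge_similarity` with the similarity at each merge.
#' @export
hcluster_average <- function(mat, similarity = uncentered_correlation) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  n <- nrow(mat)
  labels <- rownames(mat)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  S <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    S[i, j] <- S[j, i] <- tryCatch(similarity(mat[i, ], mat[j, ]),
                                   error = function(e) NA_real_)
  bad <- which(!is.finite(S) & row(S) < col(S), arr.ind = TRUE)
  if (nrow(bad))
    stop("undefined similarity between rows: ",
         paste(apply(bad, 1, paste, collapse = "-"), collapse = ", "))
  diag(S) <- -Inf

  size <- rep(1L, n)
  id <- -seq_len(n)              # hclust convention: negatives = leaves
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  msim <- numeric(n - 1)
  S[lower.tri(S, diag = TRUE)] <- -Inf   # work on the upper triangle only
  for (step in seq_len(n - 1)) {
    best <- max(S)
    cand <- which(S == best, arr.ind = TRUE)
    # ties: lowest first cluster index, then lowest second
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    bi <- cand[1, 1]; bj <- cand[1, 2]
    merge[step, ] <- order_merge_pair(id[bi], id[bj])
    height[step] <- 1 - best
    msim[step] <- best
    upd <- which(is.finite(S[bi, ]) | is.finite(S[, bi]))
    upd <- setdiff(upd, c(bi, bj))
    for (k in upd) {
      sik <- if (k > bi) S[bi, k] else S[k, bi]
      sjk <- if (k > bj) S[bj, k] else S[k, bj]
      v <- (size[bi] * sik + size[bj] * sjk) / (size[bi] + size[bj])
      if (k > bi) S[bi, k] <- v else S[k, bi] <- v
    }
    S[bj, ] <- -Inf
    S[, bj] <- -Inf
    size[bi] <- size[bi] + size[bj]
    id[bi] <- step
  }

  ord <- integer(0)
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  ord <- walk(n - 1L)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "average",
                 call = match.call(), dist.method = "1 - similarity",
                 merge_similarity = msim),
            class = "hclust")
}

#' Pairwise and three-way overlaps between gene sets
#'
#' Exact intersection counts for Venn-style summaries. For two or three
#' sets the exclusive region cardinalities are also reported; with more
#' than three sets only the pairwise table is produced.
#'
#' @param gene_sets named list of >= 2 character vectors.
#' @return list with `sizes` (per-set), `pairwise` (matrix of intersection
#'   counts) and `regions` (named exclusive-region counts, or NULL for > 3
#'   sets).
#' @export
set_overlaps <- function(gene_sets) {
  stopifnot(is.list(gene_sets), length(gene_sets) >= 2,
            !is.null(names(gene_sets)))
  sets <- lapply(gene_sets, unique)
  k <- length(sets)
  nm <- names(sets)
  pw <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k))
    pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  regions <- NULL
  if (k <= 3) {
    all_ids <- unique(unlist(sets))
    member <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
    if (length(all_ids) == 1L) member <- matrix(member, nrow = 1)
    pattern <- apply(member, 1, function(b) paste(nm[b], collapse = "&"))
    regions <- table(factor(pattern, levels = {
      combos <- unlist(lapply(seq_len(k), function(m)
        utils::combn(nm, m, paste, collapse = "&", simplify = TRUE)))
      combos
    }))
    regions <- stats::setNames(as.integer(regions), names(regions))
  }
  list(sizes = vapply(sets, length, integer(1)), pairwise = pw,
       regions = regions)
}
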