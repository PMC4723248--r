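#' Read / write peptide identification tables
#'
#' Tab-separated text with a one-line header and columns protein_id,
#' peptide, sample_id, timepoint, replicate, probability, spectral_count.
#'
#' @param path file path.
#' @return data.frame of peptide records.
#' @export
read_peptides <- function(path) {
  req <- c("protein_id", "peptide", "sample_id", "timepoint", "replicate",
           "probability", "spectral_count")
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(req, names(x))
  if (length(missing))
    stop("peptide table lacks column(s): ", paste(missing, collapse = ", "))
  x
}

#' @rdname read_peptides
#' @param records data.frame of peptide records.
#' @export
write_peptides <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write an expression set as TSV
#'
#' Rows are genes with gene_id, chrom, start, end columns followed by one
#' column per array named `strain_timepoint_replicate`; chromosome lengths
#' travel in `# chrom_lengths:` header comments.
#'
#' @param expr an `expr_set`.
#' @param path file path.
#' @export
write_expr_set <- function(expr, path) {
  stopifnot(inherits(expr, "expr_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(expr$chrom_lengths))
    writeLines(sprintf("# chrom_lengths: %s %d", ch,
                       expr$chrom_lengths[[ch]]), con)
  writeLines(sprintf("# wild_type: %s", expr$wild_type), con)
  df <- cbind(expr$genes, as.data.frame(expr$ratios, check.names = FALSE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expr_set
#' @export
read_expr_set <- function(path) {
  hdr <- readLines(path, n = 50)
  cl_lines <- grep("^# chrom_lengths:", hdr, value = TRUE)
  wt_line <- grep("^# wild_type:", hdr, value = TRUE)
  cl <- NULL
  if (length(cl_lines)) {
    parts <- strsplit(sub("^# chrom_lengths: ", "", cl_lines), " ")
    cl <- stats::setNames(as.integer(vapply(parts, `[`, "", 2)),
                          vapply(parts, `[`, "", 1))
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta_cols <- c("gene_id", "chrom", "start", "end")
  stopifnot(all(meta_cols %in% names(df)))
  acols <- setdiff(names(df), meta_cols)
  ratios <- as.matrix(df[, acols, drop = FALSE])
  rownames(ratios) <- df$gene_id
  parts <- strsplit(acols, "_")
  arrays <- data.frame(array_id = acols,
                       strain = vapply(parts, function(p)
                         paste(p[seq_len(length(p) - 2)], collapse = "_"), ""),
                       timepoint = as.numeric(vapply(parts, function(p)
                         p[length(p) - 1], "")),
                       replicate = as.integer(vapply(parts, function(p)
                         p[length(p)], "")),
                       stringsAsFactors = FALSE)
  structure(list(ratios = ratios, arrays = arrays,
                 genes = df[, meta_cols],
                 chrom_lengths = cl,
                 wild_type = if (length(wt_line))
                   sub("^# wild_type: ", "", wt_line[1]) else "wt",
                 truth = NULL),
            class = "expr_set")
}

#' Write a clustering as TreeView-compatible CDT + GTR files
#'
#' The CDT lists genes in dendrogram leaf order with their values; the GTR
#' lists merges with the similarity (1 - merge height) at each node.
#'
#' @param hc `hclust` result from [hcluster_average()].
#' @param mat the clustered matrix (rows in original order).
#' @param basename path prefix; writes `<basename>.cdt` and
#'   `<basename>.gtr`.
#' @export
write_cdt_gtr <- function(hc, mat, basename) {
  stopifnot(inherits(hc, "hclust"), is.matrix(mat))
  n <- length(hc$order)
  gid <- sprintf("GENE%dX", seq_len(n))
  node_name <- function(v) if (v < 0) gid[-v] else sprintf("NODE%dX", v)
  sim <- if (!is.null(hc$merge_similarity)) hc$merge_similarity else
    1 - hc$height
  gtr <- data.frame(node = sprintf("NODE%dX", seq_len(n - 1)),
                    left = vapply(hc$merge[, 1], node_name, ""),
                    right = vapply(hc$merge[, 2], node_name, ""),
                    similarity = sim)
  utils::write.table(gtr, paste0(basename, ".gtr"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  cdt <- data.frame(GID = gid[hc$order],
                    UNIQID = hc$labels[hc$order],
                    NAME = hc$labels[hc$order],
                    GWEIGHT = 1,
                    mat[hc$order, , drop = FALSE],
                    check.names = FALSE)
  utils::write.table(cdt, paste0(basename, ".cdt"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(basename)
}

#' Write genomic regions as BED
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param regions data.frame with chrom plus either start/end (1-based
#'   inclusive gene coordinates) or the region columns of
#'   [detect_aneuploid_region()].
#' @param genes gene annotation (needed when regions reference gene ids).
#' @param path output path.
#' @export
write_bed <- function(regions, path, genes = NULL) {
  if (all(c("first_gene", "last_gene") %in% names(regions))) {
    stopifnot(!is.null(genes))
    start1 <- genes$start[match(regions$first_gene, genes$gene_id)]
    end1 <- genes$end[match(regions$last_gene, genes$gene_id)]
    name <- paste0(regions$first_gene, "-", regions$last_gene)
  } else {
    start1 <- regions$start; end1 <- regions$end
    name <- if ("name" %in% names(regions)) regions$name else "."
  }
  bed <- data.frame(chrom = regions$chrom, start = start1 - 1L, end = end1,
                    name = name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read an image field as TIFF + sidecar
#'
#' Channels go to 32-bit float single- or multi-page TIFF, masks to 16-bit
#' label TIFFs, metadata and ground truth (when present) to a YAML
#' sidecar.
#'
#' @param field an `image_field`.
#' @param basename path prefix; writes `<basename>_ch<i>.tif`,
#'   `<basename>_cells.tif`, `<basename>_nuclei.tif`, `<basename>.yaml`.
#' @export
write_image_field <- function(field, basename) {
  stopifnot(inherits(field, "image_field"))
  for (i in seq_along(field$channels))
    tiff::writeTIFF(field$channels[[i]] / max(field$channels[[i]], 1),
                    sprintf("%s_ch%d.tif", basename, i),
                    bits.per.sample = 32L)
  tiff::writeTIFF(field$cell_mask / 65535,
                  paste0(basename, "_cells.tif"), bits.per.sample = 16L)
  tiff::writeTIFF(field$nuclear_mask / 65535,
                  paste0(basename, "_nuclei.tif"), bits.per.sample = 16L)
  side <- list(metadata = field$metadata,
               intensity_scale = vapply(field$channels, function(ch)
                 max(ch, 1), numeric(1)))
  if (!is.null(field$truth))
    side$truth <- list(
      n_cells = field$truth$n_cells,
      inclusion_fraction = field$truth$inclusion_fraction,
      positive_cells = which(field$truth$positive),
      n_spots = nrow(field$truth$spots))
  yaml::write_yaml(side, paste0(basename, ".yaml"))
  invisible(basename)
}

#' @rdname write_image_field
#' @export
read_image_field <- function(basename) {
  side <- yaml::read_yaml(paste0(basename, ".yaml"))
  chans <- list()
  i <- 1L
  repeat {
    f <- sprintf("%s_ch%d.tif", basename, i)
    if (!file.exists(f)) break
    chans[[i]] <- tiff::readTIFF(f) * side$intensity_scale[[i]]
    i <- i + 1L
  }
  cm <- round(tiff::readTIFF(paste0(basename, "_cells.tif")) * 65535)
  nm <- round(tiff::readTIFF(paste0(basename, "_nuclei.tif")) * 65535)
  structure(list(channels = chans, cell_mask = matrix(as.integer(cm),
                                                      nrow(cm), ncol(cm)),
                 nuclear_mask = matrix(as.integer(nm), nrow(nm), ncol(nm)),
                 metadata = side$metadata, truth = NULL),
            class = "image_field")
}

#' Write enrichment calls as TSV
#'
#' @param calls data.frame from [call_enriched()].
#' @param path output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
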