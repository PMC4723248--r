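#' Segment cells from a single fluorescence channel
#'
#' Otsu threshold on the normalized image, hole filling, distance-map
#' watershed to split touching objects, then an area filter. Surviving
#' objects are relabeled 1..n in raster order of their centroids so labels
#' are deterministic.
#'
#' When ground-truth masks accompany a synthetic field, pass them directly
#' to the measurement functions instead; segmentation is for images that
#' arrive without masks.
#'
#' @param image numeric matrix (single channel).
#' @param expected_cell_area_range c(min, max) object area in pixels;
#'   objects outside it are discarded.
#' @return integer label matrix (0 = background). A field with no objects
#'   returns an all-zero mask with a warning.
#' @export
segment_cells <- function(image, expected_cell_area_range = c(30, 2000)) {
  stopifnot(is.matrix(image), length(expected_cell_area_range) == 2)
  rng <- range(image)
  if (diff(rng) == 0) {
    warning("segment_cells: blank image, no objects found")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  norm <- (image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm))
  bw <- norm > thr
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::watershed(EBImage::distmap(bw), tolerance = 1)
  lab <- EBImage::imageData(lab)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= expected_cell_area_range[1] &
                  areas <= expected_cell_area_range[2])
  if (!length(keep)) {
    warning("segment_cells: no objects within the expected area range")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  # relabel in raster order of centroids
  cent <- t(vapply(keep, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    colMeans(idx)
  }, numeric(2)))
  ord <- order(round(cent[, 1]), round(cent[, 2]))
  out <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_along(ord)) out[lab == keep[ord[i]]] <- i
  out
}

# scale-normalized Laplacian-of-Gaussian kernel; sign flipped so bright
# blobs give positive response
log_kernel <- function(sigma) {
  w <- ceiling(3 * sigma)
  ax <- -w:w
  g <- exp(-outer(ax^2, ax^2, `+`) / (2 * sigma^2))
  g <- g / sum(g)
  r2 <- outer(ax^2, ax^2, `+`)
  k <- -g * (r2 - 2 * sigma^2) / sigma^4   # -LoG
  sigma^2 * (k - mean(k))                   # scale-normalized, zero-sum
}

#' Detect inclusions (bright puncta) per cell
#'
#' Multiscale Laplacian-of-Gaussian blob detection: the image is convolved
#' with scale-normalized LoG kernels at `n_scales` sigmas between
#' `min_sigma` and `max_sigma`; candidate spots are local maxima (3x3) of
#' the across-scale maximum response with positive response. A candidate is
#' kept iff its pixel intensity exceeds the cell's median intensity by
#' `min_prominence` times the cell's robust intensity scale (MAD). Both
#' median and MAD — and the candidate search — use the cytoplasm (cell
#' minus nucleus) when a nuclear mask is present, since the inclusions
#' being scored are cytoplasmic and nuclear enrichment would otherwise
#' masquerade as a blob; with no nuclear mask the whole cell is used.
#'
#' The criterion is invariant to multiplicative intensity gain: peak,
#' median and MAD all scale together.
#'
#' @param field an `image_field` (channels + cell/nuclear masks).
#' @param channel channel index (default 1).
#' @param min_prominence required prominence in robust-scale units; > 0
#'   (default 4).
#' @param min_sigma,max_sigma blob scale range in pixels.
#' @param n_scales number of LoG scales.
#' @return named list, one element per cell label, each a data.frame
#'   (y, x, sigma, peak) of detected spots (0-based pixel coordinates).
#' @export
detect_inclusions <- function(field, channel = 1L, min_prominence = 4,
                              min_sigma = 1, max_sigma = 4, n_scales = 4L) {
  stopifnot(inherits(field, "image_field"))
  if (min_prominence <= 0) stop("min_prominence must be > 0")
  img <- field$channels[[channel]]
  cmask <- field$cell_mask
  nmask <- field$nuclear_mask
  stopifnot(is.matrix(img), identical(dim(img), dim(cmask)))

  # flatten the nucleus to the cell's cytoplasmic median before blob
  # filtering: the inclusions being scored are cytoplasmic, and an enriched
  # nucleus is itself a bright blob whose large-scale LoG response would
  # otherwise drown out puncta in the perinuclear cytoplasm
  filt_img <- img
  has_nuc <- any(nmask > 0)
  if (has_nuc) {
    for (l in unique(nmask[nmask > 0])) {
      cyt <- img[cmask == l & nmask == 0]
      if (length(cyt))
        filt_img[nmask == l] <- stats::median(cyt)
    }
  }

  sigmas <- exp(seq(log(min_sigma), log(max_sigma), length.out = n_scales))
  best <- matrix(-Inf, nrow(img), ncol(img))
  best_s <- matrix(sigmas[1], nrow(img), ncol(img))
  for (s in seq_along(sigmas)) {
    r <- as.matrix(EBImage::filter2(filt_img, log_kernel(sigmas[s])))
    upd <- r > best
    best[upd] <- r[upd]
    best_s[upd] <- sigmas[s]
  }

  # strict 3x3 local maxima with positive response
  h <- nrow(img); w <- ncol(img)
  is_max <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    shifted <- matrix(-Inf, h, w)
    ys <- max(1, 1 + dy):min(h, h + dy)
    xs <- max(1, 1 + dx):min(w, w + dx)
    shifted[ys, xs] <- best[ys - dy, xs - dx]
    is_max <- is_max & (best >= shifted)
  }
  domain <- if (has_nuc) cmask > 0 & nmask == 0 else cmask > 0
  cand <- which(is_max & best > 0 & domain, arr.ind = TRUE)

  labels <- sort(unique(cmask[cmask > 0]))
  out <- stats::setNames(
    replicate(length(labels),
              data.frame(y = integer(0), x = integer(0),
                         sigma = numeric(0), peak = numeric(0)),
              simplify = FALSE),
    as.character(labels))
  if (!nrow(cand)) return(out)
  for (l in labels) {
    px <- img[domain & cmask == l]
    med <- stats::median(px)
    scale <- stats::mad(px)
    in_cell <- cand[cmask[cand] == l, , drop = FALSE]
    if (!nrow(in_cell)) next
    peaks <- img[in_cell]
    keep <- if (scale > 0) peaks > med + min_prominence * scale
            else peaks > med
    if (any(keep))
      out[[as.character(l)]] <- data.frame(
        y = in_cell[keep, 1] - 1L, x = in_cell[keep, 2] - 1L,
        sigma = best_s[in_cell[keep, , drop = FALSE]],
        peak = peaks[keep])
  }
  out
}

#' Summarize inclusion fractions across fields
#'
#' Per field: the fraction of cells with at least one detected inclusion.
#' Per (condition, timepoint) group: mean and sample SD of the per-field
#' fractions (across fields, not pooled cells), the number of fields and
#' total cells. Groups with fewer than `min_fields` fields or any field
#' under `min_cells_per_field` cells are computed but flagged
#' `underpowered`. Fields with zero cells are excluded with a warning.
#'
#' @param fields list of `image_field` objects with metadata (condition,
#'   timepoint, field_id).
#' @param min_fields minimum fields per group for full power (default 6).
#' @param min_cells_per_field minimum cells per field (default 40).
#' @param spots optional precomputed list of [detect_inclusions()] results
#'   (one per field); when NULL detection is run with `...`.
#' @param ... passed to [detect_inclusions()].
#' @return list with `per_field` (data.frame: condition, timepoint,
#'   field_id, n_cells, n_positive, fraction) and `per_condition`
#'   (data.frame: condition, timepoint, mean_fraction, sd_fraction,
#'   n_fields, total_cells, underpowered).
#' @export
summarize_inclusion_fractions <- function(fields, min_fields = 6L,
                                          min_cells_per_field = 40L,
                                          spots = NULL, ...) {
  stopifnot(is.list(fields), length(fields) >= 1)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    n_cells <- length(unique(f$cell_mask[f$cell_mask > 0]))
    if (n_cells == 0) {
      warning("field ", i, " has zero cells; excluded")
      return(NULL)
    }
    sp <- if (is.null(spots)) detect_inclusions(f, ...) else spots[[i]]
    n_pos <- sum(vapply(sp, nrow, integer(1)) > 0)
    data.frame(condition = f$metadata$condition %||% "all",
               timepoint = f$metadata$timepoint %||% NA_real_,
               field_id = f$metadata$field_id %||% i,
               n_cells = n_cells, n_positive = n_pos,
               fraction = n_pos / n_cells, stringsAsFactors = FALSE)
  })
  per_field <- do.call(rbind, rows)
  if (is.null(per_field)) stop("no usable fields")
  key <- interaction(per_field$condition, per_field$timepoint, drop = TRUE)
  per_condition <- do.call(rbind, lapply(split(per_field, key), function(g) {
    data.frame(condition = g$condition[1], timepoint = g$timepoint[1],
               mean_fraction = mean(g$fraction),
               sd_fraction = if (nrow(g) > 1) stats::sd(g$fraction) else NA_real_,
               n_fields = nrow(g), total_cells = sum(g$n_cells),
               underpowered = nrow(g) < min_fields ||
                 any(g$n_cells < min_cells_per_field),
               stringsAsFactors = FALSE)
  }))
  per_condition <- per_condition[order(per_condition$condition,
                                       per_condition$timepoint), ]
  rownames(per_condition) <- NULL
  list(per_field = per_field, per_condition = per_condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare per-field fractions between two conditions
#'
#' Two-tailed heteroscedastic (Welch) t test on the per-field values, the
#' comparison used for inclusion-fraction differences between strains or
#' treatments. Identical constant groups give p = 1; constant groups with
#' different means give p = 0.
#'
#' @param fractions_a,fractions_b numeric vectors of per-field values,
#'   each length >= 2.
#' @return two-tailed p value.
#' @export
compare_conditions <- function(fractions_a, fractions_b) {
  if (length(fractions_a) < 2 || length(fractions_b) < 2)
    stop("need >= 2 fields per condition")
  if (stats::sd(fractions_a) == 0 && stats::sd(fractions_b) == 0)
    return(if (mean(fractions_a) == mean(fractions_b)) 1 else 0)
  stats::t.test(fractions_a, fractions_b, var.equal = FALSE)$p.value
}

#' Nuclear / cytoplasmic intensity per cell
#'
#' Per cell label: mean intensity over nuclear pixels, mean over
#' cytoplasmic pixels (cell minus nucleus), and their ratio. A cell whose
#' cytoplasmic mean is 0 gets an NA ratio and `defined = FALSE` rather
#' than an error.
#'
#' @param field an `image_field` with both masks.
#' @param channel channel index.
#' @return data.frame: cell, nuclear_mean, cytoplasmic_mean, ratio,
#'   defined.
#' @export
nc_ratio <- function(field, channel = 1L) {
  stopifnot(inherits(field, "image_field"))
  img <- field$channels[[channel]]
  cm <- field$cell_mask; nm <- field$nuclear_mask
  nlab <- sort(unique(nm[nm > 0]))
  clab <- sort(unique(cm[cm > 0]))
  if (!all(nlab %in% clab))
    stop("nuclear labels without matching cell labels: ",
         paste(setdiff(nlab, clab), collapse = ", "))
  out <- do.call(rbind, lapply(clab, function(l) {
    nuc <- img[nm == l]
    cyt <- img[cm == l & nm != l]
    nmn <- if (length(nuc)) mean(nuc) else NA_real_
    cmn <- if (length(cyt)) mean(cyt) else NA_real_
    ok <- is.finite(nmn) && is.finite(cmn) && cmn > 0
    data.frame(cell = l, nuclear_mean = nmn, cytoplasmic_mean = cmn,
               ratio = if (ok) nmn / cmn else NA_real_, defined = ok)
  }))
  rownames(out) <- NULL
  out
}

#' Manders overlap coefficient
#'
#' r = sum(R * G) / sqrt(sum(R^2) * sum(G^2)) over the masked pixels of two
#' channels — the overlap coefficient of two-channel colocalization
#' analysis. Invariant to multiplying either channel by a positive
#' constant.
#'
#' @param ch1,ch2 numeric matrices, same shape, non-negative.
#' @param mask logical or 0/1 matrix selecting the pixels to use (default:
#'   all pixels).
#' @return list with `overlap` (in \[0, 1\]) and `n_pixels`.
#' @export
manders_overlap <- function(ch1, ch2, mask = NULL) {
  stopifnot(is.matrix(ch1), identical(dim(ch1), dim(ch2)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ch1), ncol(ch1))
  stopifnot(identical(dim(mask), dim(ch1)))
  sel <- mask > 0
  if (!any(sel)) stop("mask selects no pixels")
  r <- ch1[sel]; g <- ch2[sel]
  if (any(r < 0) || any(g < 0)) stop("intensities must be non-negative")
  nr <- sum(r^2); ng <- sum(g^2)
  if (nr == 0 || ng == 0)
    stop("Manders overlap undefined: a channel is all-zero within the mask")
  list(overlap = sum(r * g) / sqrt(nr * ng), n_pixels = sum(sel))
}

#' Intensity profile along a line
#'
#' Bilinear interpolation of the image at `n_samples` evenly spaced points
#' from `p0` to `p1` inclusive. Coordinates are (row, col), 0-based, and
#' must lie inside the image.
#'
#' @param image numeric matrix.
#' @param p0,p1 numeric length-2 endpoints (row, col), 0-based.
#' @param n_samples number of samples >= 2.
#' @return numeric vector of length `n_samples`.
#' @export
line_profile <- function(image, p0, p1, n_samples = 100L) {
  stopifnot(is.matrix(image), length(p0) == 2, length(p1) == 2,
            n_samples >= 2)
  h <- nrow(image); w <- ncol(image)
  for (p in list(p0, p1))
    if (p[1] < 0 || p[1] > h - 1 || p[2] < 0 || p[2] > w - 1)
      stop("line endpoints must lie inside the image")
  t <- seq(0, 1, length.out = n_samples)
  ys <- p0[1] + t * (p1[1] - p0[1])
  xs <- p0[2] + t * (p1[2] - p0[2])
  y0 <- pmin(floor(ys), h - 2); x0 <- pmin(floor(xs), w - 2)
  fy <- ys - y0; fx <- xs - x0
  i00 <- image[cbind(y0 + 1, x0 + 1)]
  i01 <- image[cbind(y0 + 1, x0 + 2)]
  i10 <- image[cbind(y0 + 2, x0 + 1)]
  i11 <- image[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}
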