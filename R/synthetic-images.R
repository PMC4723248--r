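#' Describe the ground truth of a synthetic fluorescence field
#'
#' Emulates a fixed-cell epifluorescence field: elliptical cells with an
#' interior nuclear ellipse, a cytoplasmic baseline intensity, optional
#' nuclear enrichment, bright Gaussian puncta (cytoplasmic inclusions) in a
#' Bernoulli-chosen subset of cells, and additive Gaussian acquisition
#' noise (intensities clipped at 0).
#'
#' @param n_cells number of cells to place.
#' @param inclusion_fraction probability that a cell carries inclusions.
#' @param spots_per_positive_cell inclusions per positive cell; >= 1.
#' @param spot_amplitude peak intensity of an inclusion above the local
#'   cytoplasmic baseline; > 0.
#' @param spot_sigma Gaussian radius of an inclusion in pixels; > 0.
#' @param nuclear_enrichment ratio of nuclear to cytoplasmic mean
#'   intensity; >= 1 (1 = no nuclear signal).
#' @param noise_sd additive Gaussian noise SD.
#' @param baseline cytoplasmic baseline intensity.
#' @param cell_radius_range min/max semi-axis of the cell ellipses (pixels).
#' @param seed integer seed.
#' @return an object of class `field_truth`.
#' @export
field_truth <- function(n_cells = 40L, inclusion_fraction = 0.5,
                        spots_per_positive_cell = 2L, spot_amplitude = 150,
                        spot_sigma = 1.6, nuclear_enrichment = 2,
                        noise_sd = 10, baseline = 100,
                        cell_radius_range = c(6, 9), seed = 1L) {
  stopifnot(n_cells >= 1, inclusion_fraction >= 0, inclusion_fraction <= 1,
            spots_per_positive_cell >= 1, spot_amplitude > 0, spot_sigma > 0,
            nuclear_enrichment >= 1, noise_sd >= 0, baseline > 0,
            length(cell_radius_range) == 2, diff(cell_radius_range) >= 0)
  structure(list(n_cells = as.integer(n_cells),
                 inclusion_fraction = inclusion_fraction,
                 spots_per_positive_cell = as.integer(spots_per_positive_cell),
                 spot_amplitude = spot_amplitude, spot_sigma = spot_sigma,
                 nuclear_enrichment = nuclear_enrichment, noise_sd = noise_sd,
                 baseline = baseline, cell_radius_range = cell_radius_range,
                 seed = as.integer(seed)),
            class = "field_truth")
}

# Place n non-overlapping axis-aligned ellipses by rejection sampling.
# Fails loudly when the field cannot accommodate them: silent overlap would
# corrupt every downstream per-cell statistic.
place_cells <- function(n, shape, radius_range, max_tries = 500L) {
  rmax <- radius_range[2]
  centers <- matrix(NA_real_, n, 2)
  radii <- matrix(NA_real_, n, 2)
  bound <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      ry <- stats::runif(1, radius_range[1], rmax)
      rx <- stats::runif(1, radius_range[1], rmax)
      cy <- stats::runif(1, rmax + 2, shape[1] - rmax - 2)
      cx <- stats::runif(1, rmax + 2, shape[2] - rmax - 2)
      b <- max(rx, ry)
      if (i == 1L || all(sqrt((centers[seq_len(i - 1), 1] - cy)^2 +
                              (centers[seq_len(i - 1), 2] - cx)^2) >
                           bound[seq_len(i - 1)] + b + 1)) {
        centers[i, ] <- c(cy, cx); radii[i, ] <- c(ry, rx); bound[i] <- b
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", n, " non-overlapping cells in a ",
           shape[1], "x", shape[2], " field after ", max_tries,
           " tries per cell; enlarge the field or reduce n_cells")
  }
  list(centers = centers, radii = radii)
}

ellipse_pixels <- function(shape, cy, cx, ry, rx) {
  rows <- max(1L, floor(cy - ry)):min(shape[1], ceiling(cy + ry))
  cols <- max(1L, floor(cx - rx)):min(shape[2], ceiling(cx + rx))
  inside <- outer(((rows - cy) / ry)^2, ((cols - cx) / rx)^2, `+`) <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(rows[idx[, 1]], cols[idx[, 2]])
}

#' Generate a synthetic fluorescence field with known inclusions
#'
#' Renders one or two channels plus labeled cell and nuclear masks
#' (integer labels, 0 = background; nuclear labels match cell labels).
#' Inclusions are Gaussian puncta centered at cytoplasmic pixels of their
#' cell. For two channels, each spot appears in channel 2 with probability
#' `overlap_prob`; with `share_noise = TRUE` both channels reuse one noise
#' draw, so `overlap_prob = 1` makes the channels identical.
#'
#' Arrays are row-major with origin at the top-left; pixel coordinates in
#' the returned truth are (row, col), 0-based.
#'
#' @param truth a [field_truth()] object.
#' @param shape c(rows, cols) of the field in pixels.
#' @param channels 1 or 2.
#' @param overlap_prob probability a spot is present in channel 2.
#' @param share_noise reuse the same noise realization in both channels.
#' @param metadata optional list (condition, timepoint, field_id) attached
#'   to the field.
#' @return an `image_field`: list with `channels` (list of matrices),
#'   `cell_mask`, `nuclear_mask`, `metadata`, and `truth` (the input truth
#'   plus `spots` data.frame (cell, y, x, amplitude, sigma, in_ch2; y/x
#'   0-based) and `positive` logical per cell).
#' @export
gen_image_field <- function(truth, shape = c(256L, 256L), channels = 1L,
                            overlap_prob = 1, share_noise = FALSE,
                            metadata = list()) {
  stopifnot(inherits(truth, "field_truth"), length(shape) == 2,
            channels %in% c(1L, 2L), overlap_prob >= 0, overlap_prob <= 1)
  set.seed(truth$seed)
  n <- truth$n_cells
  pl <- place_cells(n, shape, truth$cell_radius_range)

  cell_mask <- matrix(0L, shape[1], shape[2])
  nuc_mask <- matrix(0L, shape[1], shape[2])
  structure_img <- matrix(0, shape[1], shape[2])
  cyto_px <- vector("list", n)
  for (i in seq_len(n)) {
    cy <- pl$centers[i, 1]; cx <- pl$centers[i, 2]
    ry <- pl$radii[i, 1]; rx <- pl$radii[i, 2]
    cp <- ellipse_pixels(shape, cy, cx, ry, rx)
    np_ <- ellipse_pixels(shape, cy, cx, ry / 2, rx / 2)
    cell_mask[cp] <- i
    nuc_mask[np_] <- i
    structure_img[cp] <- truth$baseline
    structure_img[np_] <- truth$baseline * truth$nuclear_enrichment
    in_nuc <- paste(cp[, 1], cp[, 2]) %in% paste(np_[, 1], np_[, 2])
    cyto_px[[i]] <- cp[!in_nuc, , drop = FALSE]
  }

  positive <- stats::runif(n) < truth$inclusion_fraction
  spots <- NULL
  if (any(positive)) {
    spots <- do.call(rbind, lapply(which(positive), function(i) {
      px <- cyto_px[[i]]
      pick <- px[sample.int(nrow(px), truth$spots_per_positive_cell,
                            replace = nrow(px) < truth$spots_per_positive_cell), ,
                 drop = FALSE]
      data.frame(cell = i, y = pick[, 1] - 1L, x = pick[, 2] - 1L,
                 amplitude = truth$spot_amplitude, sigma = truth$spot_sigma)
    }))
    spots$in_ch2 <- if (channels == 2L) stats::runif(nrow(spots)) < overlap_prob
                    else NA
  } else {
    spots <- data.frame(cell = integer(0), y = integer(0), x = integer(0),
                        amplitude = numeric(0), sigma = numeric(0),
                        in_ch2 = logical(0))
  }

  add_spots <- function(img, sp) {
    if (!nrow(sp)) return(img)
    for (j in seq_len(nrow(sp))) {
      cy <- sp$y[j] + 1L; cx <- sp$x[j] + 1L
      s <- sp$sigma[j]; w <- ceiling(3 * s)
      rows <- max(1L, cy - w):min(nrow(img), cy + w)
      cols <- max(1L, cx - w):min(ncol(img), cx + w)
      bump <- sp$amplitude[j] *
        exp(-outer((rows - cy)^2, (cols - cx)^2, `+`) / (2 * s^2))
      img[rows, cols] <- img[rows, cols] + bump
    }
    img
  }

  noise1 <- matrix(stats::rnorm(prod(shape), 0, truth$noise_sd),
                   shape[1], shape[2])
  ch1 <- pmax(add_spots(structure_img, spots) + noise1, 0)
  chans <- list(ch1)
  if (channels == 2L) {
    noise2 <- if (share_noise) noise1 else
      matrix(stats::rnorm(prod(shape), 0, truth$noise_sd), shape[1], shape[2])
    sp2 <- spots[which(spots$in_ch2), , drop = FALSE]
    chans[[2]] <- pmax(add_spots(structure_img, sp2) + noise2, 0)
  }

  out_truth <- truth
  out_truth$spots <- spots
  out_truth$positive <- positive
  structure(list(channels = chans, cell_mask = cell_mask,
                 nuclear_mask = nuc_mask, metadata = metadata,
                 truth = out_truth),
            class = "image_field")
}

#' Generate a time course of synthetic fields
#'
#' One batch of fields per timepoint, each with that timepoint's inclusion
#' fraction; per-field seeds are derived from the master seed so the whole
#' course is reproducible from one integer. Emulates a scoring protocol of
#' several fields of >= 40 cells per timepoint.
#'
#' @param trajectory named numeric vector: names are timepoints (minutes),
#'   values are inclusion fractions in \[0, 1\].
#' @param fields_per_timepoint fields per timepoint.
#' @param template a [field_truth()] whose parameters (other than
#'   `inclusion_fraction` and `seed`) every field shares.
#' @param master_seed integer master seed.
#' @param shape field dimensions, c(rows, cols).
#' @param condition condition label stored in each field's metadata.
#' @return list of `image_field` objects with metadata (condition,
#'   timepoint, field_id) set.
#' @export
gen_timecourse_fields <- function(trajectory, fields_per_timepoint = 6L,
                                  template = field_truth(),
                                  master_seed = 1L, shape = c(256L, 256L),
                                  condition = "stress") {
  if (!length(trajectory)) stop("trajectory must be non-empty")
  if (is.null(names(trajectory))) stop("trajectory must be named by timepoint")
  if (any(trajectory < 0 | trajectory > 1))
    stop("trajectory fractions must be in [0, 1]")
  n <- length(trajectory) * fields_per_timepoint
  seeds <- derive_seeds(master_seed, n)
  fields <- vector("list", n)
  k <- 0L
  for (tp in names(trajectory)) {
    for (f in seq_len(fields_per_timepoint)) {
      k <- k + 1L
      tr <- template
      tr$inclusion_fraction <- unname(trajectory[[tp]])
      tr$seed <- seeds[k]
      fields[[k]] <- gen_image_field(
        field_truth_from_list(tr), shape = shape,
        metadata = list(condition = condition,
                        timepoint = as.numeric(tp), field_id = f))
    }
  }
  fields
}

# rebuild a field_truth from a plain list (keeps constructor validation)
field_truth_from_list <- function(x) {
  field_truth(n_cells = x$n_cells, inclusion_fraction = x$inclusion_fraction,
              spots_per_positive_cell = x$spots_per_positive_cell,
              spot_amplitude = x$spot_amplitude, spot_sigma = x$spot_sigma,
              nuclear_enrichment = x$nuclear_enrichment,
              noise_sd = x$noise_sd, baseline = x$baseline,
              cell_radius_range = x$cell_radius_range, seed = x$seed)
}
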