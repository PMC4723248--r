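#' Final osmolyte concentration after mixing
#'
#' Volume-weighted mean of the culture and added-medium concentrations;
#' used to document the stress condition in run metadata (e.g. combining
#' equal volumes of culture and medium with 2.4 M sorbitol gives 1.2 M).
#'
#' @param initial_concentration concentration already in the culture.
#' @param added_concentration concentration of the added medium.
#' @param volume_ratio volume of added medium per volume of culture; > 0
#'   (1 = equal volumes).
#' @return the final concentration, same units as the inputs.
#' @export
stress_dilution <- function(initial_concentration, added_concentration,
                            volume_ratio = 1) {
  if (initial_concentration < 0 || added_concentration < 0)
    stop("concentrations must be non-negative")
  if (volume_ratio <= 0) stop("volume_ratio must be > 0")
  (initial_concentration + added_concentration * volume_ratio) /
    (1 + volume_ratio)
}

#' Default study-condition parameters for each pipeline stage
#'
#' These encode the synthetic reproduction's study conditions: an MS
#' experiment with 500 proteins of which two (the Tup1/Cyc8 analogues) are
#' planted at 10-fold stress enrichment over a baseline of 20 summed
#' counts with 3 replicates per timepoint; a 1500-gene expression study in
#' wild type and two sumoylation-deficient mutants at 0/30/60 min with
#' replicate noise SD 0.22 and a 20-gene aneuploid segment in one
#' biological sample; and an inclusion time course peaking at 15 min.
#'
#' @return named list of stage parameters.
#' @export
ms_defaults <- function() {
  list(n_proteins = 500L, planted_proteins = c(1L, 2L), planted_fold = 10,
       baseline_mean = 20, n_replicates = 3L, min_probability = 0.55,
       fold_min = 3, p_max = 0.01)
}

#' @rdname ms_defaults
#' @export
array_defaults <- function() {
  list(n_genes = 1500L, replicate_sd = 0.22, n_replicates = 2L,
       strains = c("wt", "tup1KR", "cyc8KR"), timepoints = c(0, 30, 60),
       wild_type = "wt", k = 3, n_self_self = 15000L,
       screen_fold = 2, telomere_bp = 25000, min_run = 5L,
       elevation_cutoff = 0.4,
       aneuploid = list(first = 701L, last = 720L, shift = 0.8,
                        strain = "tup1KR", replicate = 1L),
       n_up_tup1 = 16L, n_up_cyc8 = 21L, telomere_proximal_tup1 = 15L)
}

#' @rdname ms_defaults
#' @export
imaging_defaults <- function() {
  list(trajectory = c("0" = 0, "15" = 0.6, "60" = 0.05),
       fields_per_timepoint = 6L, n_cells = 40L, shape = c(256L, 256L),
       min_prominence = 4, nuclear_enrichment = 2)
}

#' Plant the mutant-effect screen's ground truth into an array experiment
#'
#' Builds the planted-effects table of the synthetic expression study:
#' `n_up_tup1` genes up >= `screen_fold`-fold in the tup1 mutant at 30 min
#' (of which `telomere_proximal_tup1` are placed within `telomere_bp` of a
#' chromosome end) and `n_up_cyc8` genes up in the cyc8 mutant, plus a
#' 20-gene aneuploid segment in one tup1 biological replicate.
#'
#' @param cfg list of array-stage parameters (see `array_defaults`).
#' @param seed integer seed for the experiment.
#' @return an `expr_set` with truth attached.
#' @export
simulate_array_study <- function(cfg = array_defaults(), seed = 1L) {
  ann <- synthetic_annotation(cfg$n_genes)
  prox <- which(telomere_proximity(ann$genes, ann$chrom_lengths,
                                   cfg$telomere_bp))
  interior <- setdiff(seq_len(cfg$n_genes), prox)
  # keep planted genes clear of the aneuploid segment
  seg_genes <- cfg$aneuploid$first:cfg$aneuploid$last
  prox <- setdiff(prox, seg_genes)
  interior <- setdiff(interior, seg_genes)
  n_prox <- cfg$telomere_proximal_tup1
  tup1_genes <- c(prox[seq_len(n_prox)],
                  interior[seq_len(cfg$n_up_tup1 - n_prox)])
  cyc8_genes <- interior[cfg$n_up_tup1 - n_prox + seq_len(cfg$n_up_cyc8)]
  lg2 <- log2(cfg$screen_fold)
  effects <- rbind(
    data.frame(gene = tup1_genes, strain = "tup1KR", timepoint = 30,
               shift = lg2 + 0.8),
    data.frame(gene = cyc8_genes, strain = "cyc8KR", timepoint = 30,
               shift = lg2 + 0.8))
  truth <- array_truth(n_genes = cfg$n_genes, replicate_sd = cfg$replicate_sd,
                       planted_effects = effects,
                       aneuploid_segment = cfg$aneuploid, seed = seed)
  gen_array_experiment(truth, strains = cfg$strains,
                       timepoints = cfg$timepoints,
                       n_replicates = cfg$n_replicates,
                       wild_type = cfg$wild_type)
}

#' Run one pipeline stage on synthetic inputs
#'
#' The stage runners behind [run_pipeline()], also usable directly from
#' analysis scripts: each generates its synthetic inputs from the stage
#' seed, runs the full analysis, writes its tables under `outdir` and
#' returns the in-memory results.
#'
#' @param cfg stage parameters (see [ms_defaults()] and friends).
#' @param seed integer seed for the stage.
#' @param outdir existing directory for output tables.
#' @return a list of stage results (see the pipeline manifest for files).
#' @export
run_ms_stage <- function(cfg = ms_defaults(), seed = 1L, outdir = ".") {
  truth <- spectral_truth(n_proteins = cfg$n_proteins,
                          planted_proteins = cfg$planted_proteins,
                          planted_fold = cfg$planted_fold,
                          baseline_mean = cfg$baseline_mean,
                          n_replicates = cfg$n_replicates, seed = seed)
  sim <- gen_spectral_counts(truth)
  kept <- filter_peptides(sim$peptides, cfg$min_probability)
  pcm <- sum_counts(kept, samples = sim$samples)
  calls <- call_enriched(test_enrichment(pcm), cfg$fold_min, cfg$p_max)
  write_peptides(sim$peptides, file.path(outdir, "peptides.tsv"))
  write_calls(calls, file.path(outdir, "ms_calls.tsv"))
  list(calls = calls, truth = truth,
       n_peptides = nrow(sim$peptides), n_kept = nrow(kept),
       n_passing = sum(calls$passes),
       planted_called = all(sprintf("P%04d", cfg$planted_proteins) %in%
                              calls$protein_id[calls$passes]))
}

#' @rdname run_ms_stage
#' @export
run_array_stage <- function(cfg = array_defaults(), seed = 1L, outdir = ".") {
  seeds <- derive_seeds(seed, 2)
  null_ratios <- gen_self_self(cfg$n_self_self, sd = cfg$replicate_sd,
                               seed = seeds[1])
  thr <- derive_threshold(null_ratios, k = cfg$k)
  expr <- simulate_array_study(cfg, seed = seeds[2])

  scan <- detect_aneuploid_region(
    expr, arrays_select = expr$arrays$strain == cfg$aneuploid$strain &
      expr$arrays$replicate == cfg$aneuploid$replicate,
    min_run = cfg$min_run, elevation_cutoff = cfg$elevation_cutoff)
  masked <- scan$masked

  avg <- average_replicates(masked)
  eff <- mutant_effect(avg, wild_type = cfg$wild_type)
  # unstressed (t = 0) changes read off the averaged ratios against the
  # common reference; stressed timepoints use mutant-effect ratios
  sig_input <- eff$effects
  t0 <- eff$strata$timepoint == 0
  sig_input[, t0] <- avg$means[, eff$strata$column[t0], drop = FALSE]
  sig_157 <- call_significant(sig_input, thr$log2_threshold, "both")
  eff30 <- eff$effects[, eff$strata$timepoint == 30, drop = FALSE]
  up2 <- call_significant(eff30, log2(cfg$screen_fold), "up")

  prox <- stats::setNames(
    lapply(up2, function(g) {
      sub <- masked$genes[masked$genes$gene_id %in% g, , drop = FALSE]
      sum(telomere_proximity(sub, masked$chrom_lengths, cfg$telomere_bp))
    }), names(up2))

  sig_genes <- unique(unlist(sig_157))
  hc <- NULL
  if (length(sig_genes) >= 2) {
    m <- eff$effects[sig_genes, , drop = FALSE]
    m <- m[rowSums(!is.finite(m)) == 0, , drop = FALSE]
    if (nrow(m) >= 2) {
      hc <- hcluster_average(m)
      write_cdt_gtr(hc, m, file.path(outdir, "clusters"))
    }
  }
  ov <- set_overlaps(up2)

  write_expr_set(expr, file.path(outdir, "expression.tsv"))
  if (nrow(scan$regions))
    write_bed(scan$regions, file.path(outdir, "aneuploid_regions.bed"),
              genes = expr$genes)
  utils::write.table(
    data.frame(mutant = rep(names(up2), lengths(up2)),
               gene_id = unlist(up2, use.names = FALSE),
               stringsAsFactors = FALSE),
    file.path(outdir, "genes_up2fold_30min.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)

  list(threshold = thr, regions = scan$regions, up2 = up2,
       telomere_proximal = prox, overlaps = ov, hc = hc,
       n_sig_157 = lengths(sig_157))
}

#' @rdname run_ms_stage
#' @export
run_imaging_stage <- function(cfg = imaging_defaults(), seed = 1L,
                              outdir = ".") {
  seeds <- derive_seeds(seed, 3)
  template <- field_truth(n_cells = cfg$n_cells,
                          nuclear_enrichment = cfg$nuclear_enrichment)
  fields <- gen_timecourse_fields(cfg$trajectory,
                                  fields_per_timepoint = cfg$fields_per_timepoint,
                                  template = template, master_seed = seeds[1],
                                  shape = cfg$shape)
  summ <- summarize_inclusion_fractions(fields,
                                        min_fields = cfg$fields_per_timepoint,
                                        min_prominence = cfg$min_prominence)
  pf <- summ$per_field
  p15_vs_0 <- compare_conditions(pf$fraction[pf$timepoint == 15],
                                 pf$fraction[pf$timepoint == 0])

  two_ch <- gen_image_field(field_truth(n_cells = 30L, inclusion_fraction = 1,
                                        nuclear_enrichment = 1,
                                        seed = seeds[2]),
                            shape = cfg$shape, channels = 2L,
                            overlap_prob = 1, share_noise = TRUE)
  mo <- manders_overlap(two_ch$channels[[1]], two_ch$channels[[2]],
                        two_ch$cell_mask > 0)
  nc_field <- gen_image_field(field_truth(n_cells = 40L,
                                          inclusion_fraction = 0,
                                          nuclear_enrichment = 3,
                                          noise_sd = 2, seed = seeds[3]),
                              shape = cfg$shape)
  nc <- nc_ratio(nc_field)

  utils::write.table(summ$per_field, file.path(outdir, "inclusions_per_field.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  utils::write.table(summ$per_condition,
                     file.path(outdir, "inclusions_per_condition.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  utils::write.table(nc, file.path(outdir, "nc_ratio_per_cell.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  write_image_field(fields[[1]], file.path(outdir, "field_t0_f1"))

  list(summary = summ, p_15_vs_0 = p15_vs_0, manders = mo,
       mean_nc_ratio = mean(nc$ratio[nc$defined]))
}

#' Run the full synthetic reproduction pipeline
#'
#' Executes the selected stages (MS enrichment calling, array analysis,
#' imaging quantification) on synthetic inputs with known ground truth,
#' writes every stage's tables under `outdir`, and records parameters,
#' seeds, package version and output checksums in a JSON manifest.
#' Identical (config, seed) yields byte-identical stage outputs.
#'
#' @param config list with elements `stages` (subset of
#'   c("ms", "arrays", "imaging") or "all"), `seed`, `outdir`, and optional
#'   per-stage parameter blocks `ms`, `arrays`, `imaging` overriding the
#'   documented defaults. Unknown top-level or stage keys are rejected
#'   before any computation.
#' @return the manifest (invisibly); also written to
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  allowed <- c("stages", "seed", "outdir", "ms", "arrays", "imaging")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  stages <- config$stages %||% "all"
  if (identical(stages, "all")) stages <- c("ms", "arrays", "imaging")
  if (!all(stages %in% c("ms", "arrays", "imaging")))
    stop("unknown stage(s): ",
         paste(setdiff(stages, c("ms", "arrays", "imaging")), collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  merge_cfg <- function(defaults, user) {
    if (is.null(user)) return(defaults)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop("unknown stage parameter(s): ", paste(unknown, collapse = ", "))
    utils::modifyList(defaults, user)
  }

  manifest <- list(package = "sumostress",
                   version = as.character(utils::packageVersion("sumostress")),
                   seed = seed, stages = list(), status = 0L,
                   stress_condition = list(
                     sorbitol_M = stress_dilution(0, 2.4, 1)))
  results <- list()
  stage_seeds <- derive_seeds(seed, 3)
  names(stage_seeds) <- c("ms", "arrays", "imaging")
  for (st in stages) {
    cfg <- switch(st,
                  ms = merge_cfg(ms_defaults(), config$ms),
                  arrays = merge_cfg(array_defaults(), config$arrays),
                  imaging = merge_cfg(imaging_defaults(), config$imaging))
    res <- tryCatch({
      r <- switch(st,
                  ms = run_ms_stage(cfg, stage_seeds[[st]], outdir),
                  arrays = run_array_stage(cfg, stage_seeds[[st]], outdir),
                  imaging = run_imaging_stage(cfg, stage_seeds[[st]], outdir))
      manifest$stages[[st]] <- list(status = "ok", seed = stage_seeds[[st]],
                                    parameters = cfg)
      r
    }, error = function(e) {
      manifest$stages[[st]] <<- list(status = "error",
                                     message = conditionMessage(e),
                                     seed = stage_seeds[[st]],
                                     parameters = cfg)
      manifest$status <<- 1L
      NULL
    })
    results[[st]] <- res
  }
  files <- setdiff(list.files(outdir, full.names = TRUE),
                   file.path(outdir, "manifest.json"))
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(manifest = manifest, results = results))
}
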