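#!/usr/bin/env Rscript

# Stage 2 — expression-array analysis of the sumoylation-deficient mutants.
#
# Derives the significance threshold from a simulated self-self (wt x wt)
# hybridization (SD 0.22 log2 -> 3 SD ~= 0.66 log2), simulates the mutant
# expression study (wild type + tup1KR + cyc8KR at 0/30/60 min, duplicate
# arrays, planted 30-min effects and a 20-gene aneuploid segment in one
# tup1KR biological sample), then: detects and masks the aneuploid
# segment, averages replicates, forms mutant-effect ratios, screens for
# >= 2-fold 30-min changes, flags telomere-proximal genes, clusters the
# changed genes (average linkage, uncentered correlation), and counts set
# overlaps.
#
# Outputs under results/arrays/: expression.tsv, aneuploid_regions.bed,
# genes_up2fold_30min.tsv, clusters.cdt / clusters.gtr.

suppressPackageStartupMessages(library(sumostress))

outdir <- "results/arrays"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

res <- run_array_stage(array_defaults(), seed = 202L, outdir = outdir)

print(res$threshold)
cat("\naneuploid regions detected and masked:\n")
print(res$regions[, c("chrom", "first_gene", "last_gene", "n_genes",
                      "span_bp", "mean_elevation")])
cat("\ngenes changed >= 2-fold at 30 min (mutant-effect ratios):\n")
print(lengths(res$up2))
cat("\nof which telomere-proximal (<= 25 kb from a chromosome end):\n")
print(unlist(res$telomere_proximal))
cat("\npairwise overlap of the 30-min gene sets:\n")
print(res$overlaps$pairwise)
cat(sprintf("\ngenes clustered (|mutant effect| >= %.2f log2): %d leaves\n",
            res$threshold$log2_threshold,
            if (is.null(res$hc)) 0L else length(res$hc$order)))
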