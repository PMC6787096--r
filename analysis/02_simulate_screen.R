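#!/usr/bin/env Rscript

## Simulate a pooled differential-growth screen with planted interactions and
## emit the paired FASTQ files plus truth tables under results/screen/.

suppressPackageStartupMessages(library(tcgi))

outdir <- "results/screen"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

planted <- data.frame(gene = c("GENE0007", "GENE0021", "GENE0033"),
                      effect = -2, single_effect = 0)
cfg <- screen_config(n_genes = 50L, n_controls_pos2 = 15L, depth = 1e5,
                     effect_sd = 0.05, seed = 42L, interaction_set = planted)
sl <- simulate_library(cfg)
sim <- simulate_screen(sl$library, cfg)

cat(sprintf("simulated %d constructs x %d samples at depth %g\n",
            nrow(sim$counts), ncol(sim$counts), sim$truth$depth))
cat("replicate concordance (pearson on log10 counts):\n")
cat(sprintf("  T0:  %.3f   T14: %.3f\n",
            replicate_correlation(sim$counts[, "T0_rep1"], sim$counts[, "T0_rep2"]),
            replicate_correlation(sim$counts[, "T14_rep1"], sim$counts[, "T14_rep2"])))
cat(sprintf("  plasmid vs T0 (spearman): %.3f\n",
            replicate_correlation(sim$counts[, "plasmid"], sim$counts[, "T0_rep1"],
                                  method = "spearman")))

write_counts(sim$counts, file.path(outdir, "true_counts.tsv"))
write_library_manifest(sl$library, file.path(outdir, "library_manifest.tsv"))
utils::write.table(sim$truth$gene_effects,
                   file.path(outdir, "truth_gene_effects.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sim$sample_info, file.path(outdir, "sample_info.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

## FASTQ files are bulky scratch artifacts; only the sample sheet that points
## at them lands under results/
sheet <- emit_fastq(sim$counts, sl$library, default_components(),
                    "scratch/screen_fastq", read_len = 40,
                    error_rate = 0.001, seed = 7L)
sheet$sample <- colnames(sim$counts)
utils::write.table(sheet, file.path(outdir, "sample_sheet.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", outdir, "\n")
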