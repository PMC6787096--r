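#!/usr/bin/env Rscript

## Design a desk-scale anchored dual-guide library: scrambled controls checked
## against a toy reference, the anchor x genome cross product, half-oligo
## pools and assembled cassettes. Writes manifests and FASTA pools under
## results/design/.

suppressPackageStartupMessages(library(tcgi))

outdir <- "results/design"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
set.seed(1)

comp <- default_components()

## a toy reference standing in for the genome when screening scrambled
## controls for absence
reference <- random_dna(20, 2000)
excl <- build_exclusion_index(reference, k = 20)

n_genes <- 50L
genes <- sprintf("GENE%04d", seq_len(n_genes))
pos1 <- guide_manifest(
  id = c("gTAZ_1", "gTAZ_2", "gTAZ_3", "gCtrl_1"),
  target = c("TAZ", "TAZ", "TAZ", "CONTROL"),
  protospacer = random_dna(4, 20), slot = 1L)
gene_guides <- guide_manifest(
  id = sprintf("g%s_%d", rep(genes, each = 3), rep(1:3, n_genes)),
  target = rep(genes, each = 3),
  protospacer = random_dna(3L * n_genes, 20), slot = 2L)
controls <- generate_scrambled_controls(15, 20, excl, seed = 2, prefix = "Ctrl2_")
pos2 <- rbind(gene_guides, controls)

lib <- build_cross_library(pos1, pos2, components = comp)
cat(sprintf("library: %d x %d = %d constructs\n",
            nrow(pos1), nrow(pos2), nrow(lib)))
print(table(lib$category))
cat(sprintf("cassette length: %d nt; internal BsmBI sites flagged: %d\n",
            unique(nchar(lib$cassette)), sum(lib$internal_bsmbi)))

oligo_a <- design_half_oligos(pos1, comp)
oligo_b <- design_half_oligos(pos2, comp)
cat(sprintf("half-oligo pools: %d + %d oligos, all %d nt\n",
            length(oligo_a), length(oligo_b),
            unique(nchar(c(oligo_a, oligo_b)))))

## spot-check the overlap assembly against the direct concatenation
cass <- assemble_full_cassette(oligo_a[["gTAZ_1"]], oligo_b[[pos2$id[1]]])
stopifnot(identical(cass,
                    lib$cassette[lib$construct_id ==
                                 paste0("gTAZ_1__", pos2$id[1])]))

write_guide_manifest(pos1, file.path(outdir, "pos1_manifest.tsv"))
write_guide_manifest(pos2, file.path(outdir, "pos2_manifest.tsv"))
write_library_manifest(lib[, setdiff(names(lib), "cassette")],
                       file.path(outdir, "library_manifest.tsv"))
write_half_oligos_fasta(oligo_a, file.path(outdir, "pool_A_oligos.fasta"))
write_half_oligos_fasta(oligo_b, file.path(outdir, "pool_B_oligos.fasta"))
cat("wrote", outdir, "\n")
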