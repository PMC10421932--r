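#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system.
#
# Builds the seven-group LY6/3FTX protein family (anchored LY6 majority,
# secreted LY6, pre-3FTX-like, and the four toxin categories), derives a
# diverged "species" copy of every protein, and implants them as 3-exon
# genes in a marker-anchored genomic scaffold together with one pseudogene,
# one orphan exon set and one gene carrying a duplicated pseudogenized
# exon 3.  All ground truth is written alongside.

suppressMessages(library(ly6tools))

seed <- 42L
outdir <- "results/run"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- pipeline_config(seed = seed,
                       groups = default_groups(c(5, 1, 1, 1, 1, 1, 1)),
                       classify_n = 20L)
run_pipeline(cfg, outdir, stages = "simulate")

fam <- read.delim(file.path(outdir, "family.tsv"))
truth <- read_gff3(file.path(outdir, "genome", "truth.gff3"))
genes <- truth[truth$feature_type == "gene", ]

cat("Protein family:", nrow(fam), "proteins in",
    length(unique(fam$group)), "groups\n")
print(table(fam$group))
cat("\nGenome:", sum(genes$status == "intact"), "intact genes,",
    sum(genes$status == "pseudogene"), "pseudogene(s),",
    sum(genes$status == "orphan_exon_set"), "orphan exon set(s)\n")
cat("Marker TOP1MT implanted once:",
    sum(genes$orthogroup == "TOP1MT", na.rm = TRUE) == 1, "\n")
cat("Scaffold length:",
    nchar(read_fasta(file.path(outdir, "genome", "scaffold.fasta"))[[1]]),
    "bp\n")
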