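#!/usr/bin/env Rscript
# Stage 1: generate the desk-scale study fixture — a toy genome carrying a
# two-isoform gene (four isoform-1-specific 5' exons, one isoform-2-specific
# exon, shared common exons > 6 kb downstream) plus six housekeeping genes,
# with biphasic developmental trajectories across 12 ages x 3 replicates.
# Writes the genome, annotation, expected-truth table and one example FASTQ.

suppressPackageStartupMessages(library(isoswitchr))

out <- "results/simulation"
cfg <- sim_config(seed = 1L)
fx <- make_study_fixture(cfg, out_dir = out)

cat("Ages:", paste(names(cfg$ages), collapse = " "), "\n")
cat("Samples:", nrow(fx$samples), " (", length(cfg$ages), "ages x",
    cfg$replicates, "replicates )\n")
cl <- classify_exons(fx$gene)
cat("Specific exons per isoform:",
    paste(names(cl$specific_counts), cl$specific_counts, sep = "=",
          collapse = ", "),
    "| common exons:", sum(cl$exons$label == "common"), "\n")
cat("Isoform cDNA ORFs:",
    translate_longest_orf(fx$transcripts[["tgene_iso1"]])$n_residues, "and",
    translate_longest_orf(fx$transcripts[["tgene_iso2"]])$n_residues,
    "residues\n")

write_feature_bed(fx$features, file.path(out, "features.bed"))
write_fasta(fx$transcripts, file.path(out, "transcripts.fa"))

# one example sample at full depth as FASTQ (the pipeline streams the rest
# in memory)
example_sample <- fx$samples$sample[1]
write_sample_fastq(fx, example_sample, out)
cat("Wrote example FASTQ for", example_sample, "under", out, "\n")
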