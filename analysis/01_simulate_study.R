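#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-omic study.
#
# Builds the base two-condition (CON vs IND), two-cell-line design: a toy
# genome with planted TF motif instances, ground-truth regulatory edges
# (a quarter of TFs rewired between conditions), RNA/ATAC count matrices
# with planted differential features, and Tn5 fragment files with
# protected footprints. All downstream stages read these files.

suppressMessages(library(grnrewire))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- scenario_config("default", seed = 1L)
print(cfg)
study <- simulate_study(cfg, fragments = TRUE)
print(study$truth)

write_genome_fasta(study$ref$genome, file.path(out, "genome.fa"))
write_peaks_bed(study$ref$peaks, file.path(out, "peaks.bed"))
write_gene_models(study$ref$genes, file.path(out, "genes.tsv"))
write_count_matrix(study$rna, file.path(out, "rna_counts.tsv"))
write_count_matrix(study$atac, file.path(out, "atac_counts.tsv"))
write_fragments_bed(study$fragments, file.path(out, "fragments.bed"))
write_truth_json(study$truth, file.path(out, "truth.json"))
write_jaspar(study$pwms, file.path(out, "motifs.jaspar"))

cat(sprintf(
  "wrote study to %s: %d genes, %d peaks, %d TFs (%d rewired), %d fragments\n",
  out, nrow(study$ref$genes), nrow(study$ref$peaks), cfg$n_tfs,
  length(study$truth$rewired_tfs), nrow(study$fragments)))
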