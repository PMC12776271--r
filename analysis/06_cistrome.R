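#!/usr/bin/env Rscript
# Stage 6: two-factor cistrome stratification.
#
# Two parts. First, a worked example on the published cardinalities of a
# two-factor ChIP comparison (factor A: 1228 CON / 2253 IND peaks with 881
# shared; factor B: 996 lost peaks of which 214 co-locate with factor A's
# gains, 83 at promoters), checking the summary arithmetic end to end.
# Second, the same stratification on synthetic cistromes derived from the
# simulated study, associated with DARs and DEGs.

suppressMessages(library(grnrewire))
dir.create("results", showWarnings = FALSE)

## worked example on published counts
slots <- function(n, origin, prefix, gap = 7000L, width = 100L) {
  s <- origin + (seq_len(n) - 1L) * gap
  data.frame(peak_id = sprintf("%s%05d", prefix, seq_len(n)),
             chrom = "chr1", start = s, end = s + width,
             summit = s + width %/% 2L, stringsAsFactors = FALSE)
}
shared_a <- slots(881, 0L, "as")
a_con <- rbind(shared_a, slots(347, 2e7, "ac"))
a_ind_sp <- slots(1372, 4e7, "ai")
a_ind <- rbind(transform(shared_a, peak_id = sub("as", "aj", peak_id)),
               a_ind_sp)
b_shared <- slots(1262, 6e7, "bs")
redis <- transform(a_ind_sp[1:214, ], peak_id = sprintf("br%05d", 1:214))
b_con <- rbind(b_shared, redis, slots(782, 8e7, "bl"))
b_ind <- transform(b_shared, peak_id = sub("bs", "bj", peak_id))
genes_we <- data.frame(gene_id = sprintf("g%03d", 1:83), chrom = "chr1",
                       strand = "+", tss = redis$summit[1:83],
                       tes = redis$summit[1:83] + 500L)

strat <- stratify_peak_groups(a_con, a_ind, b_con, b_ind, c("A", "B"))
print(strat$summary)
red <- redistribution(strat$groups$B_CON_specific,
                      strat$groups$A_IND_specific, genes_we)
cat(sprintf("factor B lost peaks redistributed to factor A gains: %d/%d (%.1f%%), %.1f%% promoter-proximal\n",
            red$n_redistributed, red$n_lost,
            100 * red$fraction_redistributed,
            100 * red$promoter_fraction))

## synthetic cistromes from the simulated study
genome_peaks <- read_peaks_bed("results/data/peaks.bed")
genes <- read_gene_models("results/data/genes.tsv")
truth <- read_truth_json("results/data/truth.json")
dars <- read.table("results/differential_peaks.tsv", header = TRUE,
                   sep = "\t")
degs <- read.table("results/differential_genes.tsv", header = TRUE,
                   sep = "\t")

# each factor's cistrome = peaks whose motif is bound in that condition
tf_peaks <- function(tf, cond) {
  bm <- truth$bound_motifs[[cond]]
  genome_peaks[genome_peaks$peak_id %in% bm$peak_id[bm$tf == tf], ]
}
tfs2 <- truth$tfs[1:2]
strat2 <- stratify_peak_groups(tf_peaks(tfs2[1], "CON"),
                               tf_peaks(tfs2[1], "IND"),
                               tf_peaks(tfs2[2], "CON"),
                               tf_peaks(tfs2[2], "IND"),
                               factor_names = tfs2)
print(strat2$summary)

p2g <- assign_peaks_to_genes(genome_peaks, genes)
groups <- strat2$groups[!grepl("merged", names(strat2$groups))]
assoc <- associate_dars_degs(groups, dars, genome_peaks, degs, p2g)
write.table(assoc, "results/cistrome_group_associations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(assoc)

ann <- annotate_context(genome_peaks, genes)
cat("genomic context of the peak universe:\n")
print(round(ann$fractions, 3))
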