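#' Write / read the toy genome as FASTA
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param path file path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write / read a peak set as BED6
#'
#' BED is 0-based half-open, matching the internal convention. The score
#' column carries the summit offset from the interval start so summits
#' round-trip.
#'
#' @param peaks peak data.frame (peak_id, chrom, start, end, summit).
#' @param path file path.
#' @export
write_peaks_bed <- function(peaks, path) {
  summit <- peak_summits(peaks)
  df <- data.frame(peaks$chrom, peaks$start, peaks$end,
                   peaks$peak_id %||% sprintf("peak%04d", seq_len(nrow(peaks))),
                   summit - peaks$start, ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  ids <- if (ncol(df) >= 4) as.character(df[[4]]) else
    sprintf("peak%04d", seq_len(nrow(df)))
  out <- data.frame(peak_id = ids,
                    chrom = df[[1]], start = df[[2]], end = df[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 5) out$summit <- df[[2]] + df[[5]]
  out
}

#' Write / read Tn5 fragment records as BED
#'
#' 0-based half-open; both ends are Tn5 insertions (shift convention is
#' applied by [insertion_profile], not stored). The name column carries the
#' sample id.
#'
#' @param frags data.frame (chrom, start, end, sample).
#' @param path file path.
#' @export
write_fragments_bed <- function(frags, path) {
  df <- data.frame(frags$chrom, frags$start, frags$end,
                   frags$sample %||% ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  out <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$sample <- as.character(df[[4]])
  out
}

#' Write / read gene models as a GTF-lite TSV
#'
#' On disk the table is 1-based inclusive (gene_id, chrom, strand, tss, tes);
#' internally coordinates are 0-based.
#'
#' @param genes gene data.frame (gene_id, chrom, strand, tss, tes).
#' @param path file path.
#' @export
write_gene_models <- function(genes, path) {
  df <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                   strand = genes$strand, tss = genes$tss + 1L,
                   tes = genes$tes + 1L, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  df$tss <- df$tss - 1L
  df$tes <- df$tes - 1L
  df
}

#' Write / read a count matrix with its sample sheet
#'
#' Counts go to `<path>` (features x samples TSV with a `feature` column);
#' the sample sheet (sample, condition, replicate, block) goes to
#' `<path>.samples.tsv` unless `sample_path` is given.
#'
#' @param cm a [count_matrix].
#' @param path counts TSV path.
#' @param sample_path sample sheet TSV path.
#' @export
write_count_matrix <- function(cm, path,
                               sample_path = paste0(path, ".samples.tsv")) {
  df <- data.frame(feature = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$samples, sample_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path,
                              sample_path = paste0(path, ".samples.tsv")) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  samples <- read.table(sample_path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
  count_matrix(counts, samples)
}

#' Write / read a truth set as JSON
#'
#' @param truth a `truth_set`.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, dataframe = "columns",
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("planted_sites", "de_genes", "dars")) {
    x[[nm]] <- as.data.frame(x[[nm]], stringsAsFactors = FALSE)
  }
  x$bound_motifs <- lapply(x$bound_motifs, as.data.frame,
                           stringsAsFactors = FALSE)
  x$true_edges <- lapply(x$true_edges, as.data.frame,
                         stringsAsFactors = FALSE)
  structure(x, class = "truth_set")
}
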