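#' Configuration for the synthetic multi-omic generator
#'
#' Bundles every knob of the simulator: the toy genome layout, the
#' negative-binomial (NB) count model, the planted differential signal, the
#' Tn5 footprint model, and the ground-truth network structure. A single
#' `seed` fixes every downstream draw bit-exactly.
#'
#' The defaults emulate the study design the package targets: two conditions
#' (CON vs IND) profiled in two cell-line blocks, with moderate NB dispersion,
#' ten percent planted differential features at |log2FC| = 2, and a quarter of
#' the TFs rewired (their regulatory edges exist in exactly one condition).
#'
#' @param n_chroms number of toy chromosomes.
#' @param chrom_len chromosome length in bp.
#' @param n_genes number of gene models (unique TSSs).
#' @param n_peaks number of non-overlapping accessible peaks.
#' @param n_tfs number of transcription factors (the first `n_tfs` genes);
#'   may be 0 for count-only scenarios.
#' @param n_samples_per_condition samples per condition (split across blocks).
#' @param n_blocks number of cell-line strata (blocks).
#' @param nb_mean_log_range range (log2) of baseline feature means.
#' @param nb_dispersion NB dispersion alpha (variance = mu + alpha * mu^2).
#' @param de_fraction fraction of genes with a planted expression effect.
#' @param de_lfc planted |log2FC| for differential genes.
#' @param dar_fraction fraction of peaks with a planted accessibility effect.
#' @param dar_lfc planted |log2FC| for differential peaks.
#' @param footprint_protection fractional depletion of Tn5 insertions over a
#'   bound motif, in [0, 1].
#' @param rewire_fraction fraction of TFs whose edges exist in exactly one
#'   condition (alternating IND-only, CON-only).
#' @param seed integer seed fixing all outputs.
#' @param prom_peak_fraction fraction of peaks placed promoter-proximal
#'   (within +/- 3 kb of a TSS); assignment is by construction, not sampling.
#' @param peak_width width of every peak in bp.
#' @param gene_length_range range of gene-body lengths in bp.
#' @param sites_per_tf planted motif instances per TF (each in its own peak).
#' @param tf_bound_fraction fraction of TFs whose planted motifs are actually
#'   bound (protected, wired); the rest contribute motif occurrences only,
#'   as unbound motifs do in real panels.
#' @param block_sd sd (log2) of per-feature block baseline offsets.
#' @param lib_size_range range of per-sample library-size multipliers.
#' @param tf_activity_sd sd (log2) of the shared per-sample TF-activity
#'   latent that couples a bound TF to its targets (sets the planted
#'   TF-target co-expression, about r = 0.8 at the default).
#' @param bound_peak_lfc extra accessibility (log2) of peaks that carry a
#'   bound motif, applied in the condition where the motif is bound.
#' @param frags_per_peak expected Tn5 fragments per peak per sample.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chroms = 2L,
                       chrom_len = 1e6,
                       n_genes = 160L,
                       n_peaks = 240L,
                       n_tfs = 8L,
                       n_samples_per_condition = 6L,
                       n_blocks = 2L,
                       nb_mean_log_range = c(2, 8),
                       nb_dispersion = 0.05,
                       de_fraction = 0.1,
                       de_lfc = 2,
                       dar_fraction = 0.1,
                       dar_lfc = 2,
                       footprint_protection = 0.8,
                       rewire_fraction = 0.25,
                       seed = 1L,
                       prom_peak_fraction = 0.5,
                       peak_width = 300L,
                       gene_length_range = c(2000L, 8000L),
                       sites_per_tf = 12L,
                       tf_bound_fraction = 1,
                       block_sd = 0.5,
                       lib_size_range = c(0.7, 1.4),
                       tf_activity_sd = 1.45,
                       bound_peak_lfc = 1,
                       frags_per_peak = 150) {
  for (nm in c("n_chroms", "chrom_len", "n_genes", "n_peaks",
               "n_samples_per_condition", "n_blocks", "peak_width")) {
    stopifnot_scalar(get(nm), nm)
  }
  if (n_tfs < 0) stop("'n_tfs' must be >= 0", call. = FALSE)
  for (nm in c("de_fraction", "dar_fraction", "footprint_protection",
               "rewire_fraction", "prom_peak_fraction", "tf_bound_fraction")) {
    check_fraction(get(nm), nm)
  }
  stopifnot_scalar(nb_dispersion + 1, "nb_dispersion")  # >= 0 allowed
  if (nb_dispersion < 0) stop("'nb_dispersion' must be >= 0", call. = FALSE)
  if (length(nb_mean_log_range) != 2L || diff(nb_mean_log_range) < 0) {
    stop("'nb_mean_log_range' must be an increasing pair", call. = FALSE)
  }
  if (n_samples_per_condition < n_blocks) {
    stop("need at least one sample per block per condition", call. = FALSE)
  }
  if (seed != as.integer(seed)) stop("'seed' must be an integer", call. = FALSE)
  cfg <- list(
    n_chroms = as.integer(n_chroms), chrom_len = as.integer(chrom_len),
    n_genes = as.integer(n_genes), n_peaks = as.integer(n_peaks),
    n_tfs = as.integer(n_tfs),
    n_samples_per_condition = as.integer(n_samples_per_condition),
    n_blocks = as.integer(n_blocks),
    nb_mean_log_range = as.numeric(nb_mean_log_range),
    nb_dispersion = nb_dispersion,
    de_fraction = de_fraction, de_lfc = de_lfc,
    dar_fraction = dar_fraction, dar_lfc = dar_lfc,
    footprint_protection = footprint_protection,
    rewire_fraction = rewire_fraction,
    seed = as.integer(seed),
    prom_peak_fraction = prom_peak_fraction,
    peak_width = as.integer(peak_width),
    gene_length_range = as.integer(gene_length_range),
    sites_per_tf = as.integer(sites_per_tf),
    tf_bound_fraction = tf_bound_fraction,
    block_sd = block_sd,
    lib_size_range = as.numeric(lib_size_range),
    tf_activity_sd = tf_activity_sd,
    bound_peak_lfc = bound_peak_lfc,
    frags_per_peak = frags_per_peak
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d chrom(s) x %d bp, %d genes, %d peaks, %d TFs, %dv%d samples in %d block(s), seed %d\n",
    x$n_chroms, x$chrom_len, x$n_genes, x$n_peaks, x$n_tfs,
    x$n_samples_per_condition, x$n_samples_per_condition, x$n_blocks, x$seed))
  invisible(x)
}
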