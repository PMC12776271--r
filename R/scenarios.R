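#' Pre-specified simulation scenarios
#'
#' Named [sim_config]s for the package's validation studies, so tests,
#' analysis scripts, and the acceptance checks all run the same study
#' conditions:
#'
#' * `default` - the base two-condition, two-cell-line design.
#' * `differential` - 2,000 genes, 6 vs 6 samples, 10% planted DE at
#'   |log2FC| = 2: differential-testing recovery.
#' * `null` - as `differential` but with no planted effects: type-I
#'   calibration.
#' * `network` - the base design with 10 samples per condition, the
#'   smallest size at which the |r| > 0.3 edge filter discriminates
#'   (null pass rate 40% at n = 10 vs 56% at n = 6).
#' * `rewiring` - 20 TFs, 2 rewired, 18 sites each, 12 vs 12 samples:
#'   degree-centrality rewiring recovery.
#' * `footprint` - 6 motifs x 200 sites, one TF bound in IND only at
#'   protection 0.8, one bound in both conditions, four never bound:
#'   differential footprint recovery.
#'
#' @param type scenario name.
#' @param seed integer seed.
#' @return a [sim_config].
#' @export
scenario_config <- function(type = c("default", "differential", "null",
                                     "network", "rewiring", "footprint"),
                            seed = 1L) {
  type <- match.arg(type)
  switch(type,
    default = sim_config(seed = seed),
    differential = sim_config(seed = seed, n_chroms = 2L, chrom_len = 3e6,
                              n_genes = 2000L, n_peaks = 40L,
                              prom_peak_fraction = 1, n_tfs = 0L,
                              de_fraction = 0.1, de_lfc = 2,
                              rewire_fraction = 0),
    null = sim_config(seed = seed, n_chroms = 2L, chrom_len = 3e6,
                      n_genes = 2000L, n_peaks = 40L,
                      prom_peak_fraction = 1, n_tfs = 0L,
                      de_fraction = 0, dar_fraction = 0,
                      rewire_fraction = 0),
    network = sim_config(seed = seed, n_samples_per_condition = 10L),
    rewiring = sim_config(seed = seed, n_chroms = 2L, chrom_len = 6e5,
                          n_genes = 400L, n_peaks = 400L,
                          prom_peak_fraction = 1, n_tfs = 20L,
                          rewire_fraction = 0.1, sites_per_tf = 18L,
                          n_samples_per_condition = 12L),
    footprint = sim_config(seed = seed, n_chroms = 2L, chrom_len = 2e6,
                           n_genes = 1300L, n_peaks = 1300L,
                           prom_peak_fraction = 1, n_tfs = 6L,
                           sites_per_tf = 200L, tf_bound_fraction = 1 / 3,
                           rewire_fraction = 1 / 6,
                           footprint_protection = 0.8,
                           n_samples_per_condition = 2L, n_blocks = 1L,
                           frags_per_peak = 60)
  )
}

#' Run the full synthetic study for a configuration
#'
#' Convenience wrapper chaining [make_reference], [random_pwms],
#' [plant_motifs_and_truth], [simulate_counts], and (optionally)
#' [simulate_fragments].
#'
#' @param cfg a [sim_config].
#' @param pwms PWM list (default: seeded [random_pwms] for `cfg$n_tfs`).
#' @param fragments also simulate Tn5 fragments (default FALSE).
#' @return list: cfg, ref, truth, rna, atac, pwms, and fragments when
#'   requested.
#' @export
simulate_study <- function(cfg, pwms = NULL, fragments = FALSE) {
  if (is.null(pwms) && cfg$n_tfs > 0) {
    pwms <- random_pwms(cfg$n_tfs, seed = cfg$seed)
  }
  ref <- make_reference(cfg)
  pt <- plant_motifs_and_truth(cfg, ref, pwms %||% list())
  cm <- simulate_counts(cfg, pt$ref, pt$truth)
  out <- list(cfg = cfg, ref = pt$ref, truth = pt$truth,
              rna = cm$rna, atac = cm$atac, pwms = pwms)
  if (fragments) out$fragments <- simulate_fragments(cfg, pt$ref, pt$truth)
  out
}

#' Build both condition networks from a simulated study
#'
#' Scans the peaks, assigns peaks to genes, and builds the CON and IND
#' networks with [build_grn].
#'
#' @param study a [simulate_study] result (needs TFs).
#' @param ... passed to [build_grn] (thresholds).
#' @return list: grn_con, grn_ind, hits, peak2gene.
#' @export
networks_from_study <- function(study, ...) {
  stopifnot(study$cfg$n_tfs > 0)
  hits <- scan_peaks(study$pwms, study$ref$genome, study$ref$peaks)
  p2g <- assign_peaks_to_genes(study$ref$peaks, study$ref$genes)
  list(
    grn_con = build_grn(study$rna, study$atac, hits, p2g,
                        study$truth$tf2motif, "CON", ...),
    grn_ind = build_grn(study$rna, study$atac, hits, p2g,
                        study$truth$tf2motif, "IND", ...),
    hits = hits, peak2gene = p2g)
}

#' Precision, recall, and F1 of recovered edges against the truth
#'
#' @param grn a `grn`.
#' @param truth a `truth_set`.
#' @return named numeric: precision, recall, f1, n_edges, n_true.
#' @export
edge_recovery <- function(grn, truth) {
  te <- truth$true_edges[[grn$condition]]
  ek <- unique(paste(grn$edges$tf, grn$edges$target))
  tk <- unique(paste(te$tf, te$target))
  precision <- if (length(ek)) mean(ek %in% tk) else NA_real_
  recall <- if (length(tk)) mean(tk %in% ek) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  c(precision = precision, recall = recall, f1 = f1,
    n_edges = length(ek), n_true = length(tk))
}
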