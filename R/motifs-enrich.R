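scan_window_fraction <- function(pwms, seqs, threshold) {
  codes <- lapply(seqs, encode_seq)
  vapply(pwms, function(m) {
    hit <- vapply(codes, function(cd) {
      h <- scan_one_seq(cd, m, threshold)
      !is.null(h) && nrow(h) > 0
    }, logical(1))
    c(frac = mean(hit), n_hit = sum(hit))
  }, numeric(2))
}

shuffle_seqs <- function(seqs, seed) {
  set.seed(seed)
  vapply(seqs, function(s) {
    paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Motif enrichment of a foreground peak set
#'
#' Compares, per motif, the fraction of foreground peaks with at least one
#' hit (70% match threshold by default, windows centered on summits)
#' against a background: either supplied peaks or, by default,
#' mononucleotide-shuffled copies of the foreground window sequences, which
#' preserve base composition while destroying motifs. Enrichment is
#' `log2((f_fg + eps) / (f_bg + eps))` with `eps = 1e-3`; a two-sided
#' Fisher exact test on the hit/miss 2x2 table gives the p-value and BH the
#' q-value.
#'
#' @param pwms named list of `pwm` objects.
#' @param fg_peaks foreground peak data.frame (>= 20 peaks).
#' @param genome a [Biostrings::DNAStringSet].
#' @param bg_peaks optional background peak data.frame; default NULL means
#'   shuffled-composition background.
#' @param window scan window in bp (default 500).
#' @param threshold match-fraction threshold (default 0.70).
#' @param eps shrinkage constant in the log ratio.
#' @param seed seed for the shuffled background.
#' @return data.frame: motif_id, f_fg, f_bg, n_fg, n_bg, log2_enrichment,
#'   pvalue, qvalue.
#' @export
enrich_peakset <- function(pwms, fg_peaks, genome, bg_peaks = NULL,
                           window = 500L, threshold = 0.70, eps = 1e-3,
                           seed = 1L) {
  if (inherits(pwms, "pwm")) pwms <- setNames(list(pwms), pwms$id)
  if (nrow(fg_peaks) < 20) {
    stop("need >= 20 foreground peaks", call. = FALSE)
  }
  fg_seqs <- peak_windows(genome, fg_peaks, window)$seqs
  if (is.null(bg_peaks)) {
    bg_seqs <- shuffle_seqs(fg_seqs, seed)
  } else {
    if (nrow(bg_peaks) == 0) stop("empty background peak set", call. = FALSE)
    bg_seqs <- peak_windows(genome, bg_peaks, window)$seqs
  }
  fg <- scan_window_fraction(pwms, fg_seqs, threshold)
  bg <- scan_window_fraction(pwms, bg_seqs, threshold)
  n_fg <- length(fg_seqs); n_bg <- length(bg_seqs)
  pv <- vapply(seq_along(pwms), function(i) {
    tab <- matrix(c(fg["n_hit", i], n_fg - fg["n_hit", i],
                    bg["n_hit", i], n_bg - bg["n_hit", i]), nrow = 2)
    fisher.test(tab)$p.value
  }, numeric(1))
  data.frame(
    motif_id = names(pwms),
    f_fg = fg["frac", ], f_bg = bg["frac", ],
    n_fg = n_fg, n_bg = n_bg,
    log2_enrichment = log2((fg["frac", ] + eps) / (bg["frac", ] + eps)),
    pvalue = pv, qvalue = p.adjust(pv, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL)
}
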