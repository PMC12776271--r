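code_lookup <- local({
  idx <- integer(128)
  idx[utf8ToInt("A")] <- 1L; idx[utf8ToInt("C")] <- 2L
  idx[utf8ToInt("G")] <- 3L; idx[utf8ToInt("T")] <- 4L
  idx
})

# encode a sequence string to 1..4 (0 = N / unknown, scores as background)
encode_seq <- function(s) {
  code_lookup[utf8ToInt(s)]
}

# log-odds score at every start position of an encoded sequence; N -> 0
score_positions <- function(codes, lo) {
  w <- ncol(lo)
  npos <- length(codes) - w + 1L
  if (npos < 1L) return(numeric(0))
  lo5 <- rbind(lo, 0)            # row 5 catches code 0 (N)
  idx0 <- codes
  idx0[idx0 == 0L] <- 5L
  sc <- numeric(npos)
  for (j in seq_len(w)) {
    sc <- sc + lo5[idx0[j:(j + npos - 1L)], j]
  }
  sc
}

scan_one_seq <- function(codes, pwm, threshold) {
  w <- ncol(pwm$lo)
  min_s <- sum(apply(pwm$lo, 2, min))
  max_s <- sum(apply(pwm$lo, 2, max))
  rng <- max_s - min_s
  rc <- pwm_revcomp(pwm)
  res <- lapply(c("+", "-"), function(std) {
    m <- if (std == "+") pwm$lo else rc$lo
    sc <- score_positions(codes, m)
    mf <- (sc - min_s) / rng
    keep <- which(mf >= threshold)
    if (!length(keep)) return(NULL)
    data.frame(pos = keep - 1L, strand = std, score = sc[keep],
               match_fraction = mf[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# extract scan windows around summits, truncating at chromosome ends
peak_windows <- function(genome, peaks, window) {
  summit <- peak_summits(peaks)
  clen <- Biostrings::width(genome)[match(peaks$chrom, names(genome))]
  ws <- summit - window %/% 2L
  we <- ws + window
  trunc <- ws < 0 | we > clen
  if (any(trunc)) {
    warning(sum(trunc), " peak window(s) truncated at a chromosome end")
  }
  ws_c <- pmax(ws, 0L)
  we_c <- pmin(we, clen)
  seqs <- as.character(Biostrings::subseq(genome[peaks$chrom],
                                          start = ws_c + 1L, end = we_c))
  list(seqs = seqs, wstart = ws_c, summit = summit)
}

#' Scan peak windows with PWMs
#'
#' Resizes each peak to a fixed window around its summit (midpoint
#' fallback), extracts the sequence, and scores every start position on
#' both strands. The match fraction rescales the log2-odds score between
#' the minimum and maximum attainable scores of the motif; hits at or above
#' `threshold` are kept. With `mode = "best_central"` only the hit closest
#' to the window center is kept per peak x motif (ties: higher score, then
#' the + strand).
#'
#' @param pwms a `pwm` or named list of them.
#' @param genome a [Biostrings::DNAStringSet] covering the peaks.
#' @param peaks peak data.frame (peak_id, chrom, start, end, summit).
#' @param window even scan-window width in bp (default 400).
#' @param threshold minimum match fraction (default 0.70).
#' @param mode `"all"` or `"best_central"`.
#' @return data.frame: peak_id, motif_id, strand, offset (bp of the motif
#'   center relative to the window center), score, match_fraction.
#' @export
scan_peaks <- function(pwms, genome, peaks, window = 400L, threshold = 0.70,
                       mode = c("best_central", "all")) {
  mode <- match.arg(mode)
  if (inherits(pwms, "pwm")) pwms <- setNames(list(pwms), pwms$id)
  if (window %% 2L != 0L) stop("'window' must be even", call. = FALSE)
  pw <- peak_windows(genome, peaks, window)
  codes <- lapply(pw$seqs, encode_seq)
  out <- vector("list", length(codes) * length(pwms))
  k <- 0L
  for (i in seq_along(codes)) {
    for (m in pwms) {
      hits <- scan_one_seq(codes[[i]], m, threshold)
      if (is.null(hits)) next
      w <- ncol(m$lo)
      center <- pw$wstart[i] + hits$pos + w %/% 2L
      k <- k + 1L
      out[[k]] <- data.frame(
        peak_id = peaks$peak_id[i], motif_id = m$id, strand = hits$strand,
        offset = center - pw$summit[i], score = hits$score,
        match_fraction = hits$match_fraction, stringsAsFactors = FALSE)
    }
  }
  hits <- if (k) do.call(rbind, out[seq_len(k)]) else
    data.frame(peak_id = character(0), motif_id = character(0),
               strand = character(0), offset = integer(0),
               score = numeric(0), match_fraction = numeric(0),
               stringsAsFactors = FALSE)
  if (mode == "best_central" && nrow(hits)) {
    ord <- order(hits$peak_id, hits$motif_id, abs(hits$offset),
                 -hits$score, hits$strand)
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(hits[, c("peak_id", "motif_id")]), ,
                 drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

#' Positional density of motif hits around peak centers
#'
#' Bins hit offsets in fixed intervals tiling `[-span, span)` (half-open
#' bins) and normalizes counts by the number of peaks in the set, so
#' densities are comparable across peak sets of different size.
#'
#' @param hits a [scan_peaks] result.
#' @param n_peaks number of peaks in the scanned set.
#' @param bin bin width in bp (default 20).
#' @param span half-range in bp (default 200).
#' @return data.frame: motif_id, bin_start, bin_end, count, density.
#' @export
positional_density <- function(hits, n_peaks, bin = 20L, span = 200L) {
  stopifnot_scalar(n_peaks, "n_peaks")
  edges <- seq(-span, span, by = bin)
  nb <- length(edges) - 1L
  motifs <- unique(hits$motif_id)
  out <- lapply(motifs, function(m) {
    off <- hits$offset[hits$motif_id == m]
    off <- off[off >= -span & off < span]
    bi <- floor((off + span) / bin) + 1L
    cnt <- tabulate(bi, nbins = nb)
    data.frame(motif_id = m, bin_start = edges[-length(edges)],
               bin_end = edges[-1], count = cnt, density = cnt / n_peaks,
               stringsAsFactors = FALSE)
  })
  if (!length(out)) {
    return(data.frame(motif_id = character(0), bin_start = integer(0),
                      bin_end = integer(0), count = integer(0),
                      density = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
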