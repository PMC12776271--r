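#' Per-base Tn5 insertion profile around motif sites
#'
#' Each fragment contributes two strandless insertion points: its 5' end
#' shifted +4 and its 3' end shifted -5 (the standard Tn5 dyad offset).
#' Insertions are accumulated per site-relative base over a fixed window
#' centered on each motif midpoint.
#'
#' @param fragments data.frame (chrom, start, end), 0-based half-open.
#' @param sites motif site data.frame (chrom, start, end), e.g. the spans of
#'   planted or scanned motif instances; all sites should share one motif.
#' @param window profile width in bp (default 200).
#' @param shift Tn5 shifts applied to the (5', 3') fragment ends.
#' @return integer matrix, n_sites x window, with attributes `window` and
#'   `motif_width`; class `insertion_profile`.
#' @export
insertion_profile <- function(fragments, sites, window = 200L,
                              shift = c(4L, 5L)) {
  if (nrow(sites) == 0) stop("zero sites", call. = FALSE)
  half <- window %/% 2L
  centers <- as.integer(floor((sites$start + sites$end) / 2))
  mat <- matrix(0L, nrow = nrow(sites), ncol = window)
  if (nrow(fragments)) {
    ins_pos <- c(fragments$start + shift[1], fragments$end - shift[2])
    ins_chr <- rep(fragments$chrom, 2L)
    by_chr <- lapply(split(ins_pos, ins_chr), sort)
    for (i in seq_len(nrow(sites))) {
      p <- by_chr[[sites$chrom[i]]]
      if (is.null(p)) next
      lo <- centers[i] - half
      span <- findInterval(c(lo - 1L, lo + window - 1L), p)
      if (span[2] <= span[1]) next
      rel <- p[(span[1] + 1L):span[2]] - lo + 1L
      mat[i, ] <- tabulate(rel, nbins = window)
    }
  }
  structure(mat, window = window,
            motif_width = as.integer(round(mean(sites$end - sites$start))),
            class = c("insertion_profile", "matrix", "array"))
}

site_scores <- function(profile, flank = 30L, eps = 0.1) {
  window <- attr(profile, "window")
  w <- attr(profile, "motif_width")
  if (window < w + 2L * flank) {
    stop("window must be >= motif span + 2 * flank", call. = FALSE)
  }
  half <- window %/% 2L
  c_from <- half - w %/% 2L + 1L
  c_to <- c_from + w - 1L
  f_idx <- c(seq(c_from - flank, c_from - 1L), seq(c_to + 1L, c_to + flank))
  if (min(f_idx) < 1L || max(f_idx) > window) {
    stop("flank and center regions overlap the window edge", call. = FALSE)
  }
  center_mean <- rowMeans(profile[, c_from:c_to, drop = FALSE])
  flank_mean <- rowMeans(profile[, f_idx, drop = FALSE])
  log2((flank_mean + eps) / (center_mean + eps))
}

#' Raw footprint score of an insertion profile
#'
#' Per site, the log2 ratio of mean flank insertions to mean center
#' (motif-span) insertions with a small `eps`; deeper protection gives a
#' higher score. The returned value is the mean over sites.
#'
#' @param profile an [insertion_profile].
#' @param flank flank width in bp on each side of the motif span.
#' @param eps continuity constant.
#' @return single raw footprint score.
#' @export
footprint_score <- function(profile, flank = 30L, eps = 0.1) {
  mean(site_scores(profile, flank = flank, eps = eps))
}

#' Differential footprint calls between two conditions
#'
#' For every motif shared by the two profile panels, computes raw footprint
#' scores per condition, min-max normalizes them across the motif panel
#' within each condition (onto \[0, 1\]), and tests the condition difference
#' by permuting per-site raw scores between condition labels (two-sided,
#' add-one corrected). A motif is significant when `|delta| >= 0.2` and
#' `p < 0.05`; motifs with fewer than 20 sites in either condition are
#' skipped with a warning.
#'
#' @param profiles_con,profiles_ind named lists of [insertion_profile]
#'   objects (same motif panel).
#' @param n_perm number of label permutations (default 1000).
#' @param seed permutation seed.
#' @param flank,eps passed to the score.
#' @param delta_threshold,p_threshold significance rule thresholds.
#' @return data.frame: motif_id, raw_con, raw_ind, score_con, score_ind,
#'   delta, pvalue, significant.
#' @export
differential_binding <- function(profiles_con, profiles_ind, n_perm = 1000L,
                                 seed = 1L, flank = 30L, eps = 0.1,
                                 delta_threshold = 0.2, p_threshold = 0.05) {
  motifs <- intersect(names(profiles_con), names(profiles_ind))
  if (!length(motifs)) stop("no shared motifs between panels", call. = FALSE)
  if (!setequal(names(profiles_con), names(profiles_ind))) {
    stop("the two panels must cover the same motifs", call. = FALSE)
  }
  set.seed(seed)
  keep <- vapply(motifs, function(m) {
    ok <- nrow(profiles_con[[m]]) >= 20L && nrow(profiles_ind[[m]]) >= 20L
    if (!ok) warning("motif ", m, " has < 20 sites; skipped")
    ok
  }, logical(1))
  motifs <- motifs[keep]
  if (!length(motifs)) stop("no motif has enough sites", call. = FALSE)

  per_site <- lapply(motifs, function(m) {
    list(con = site_scores(profiles_con[[m]], flank, eps),
         ind = site_scores(profiles_ind[[m]], flank, eps))
  })
  names(per_site) <- motifs
  raw_con <- vapply(per_site, function(x) mean(x$con), numeric(1))
  raw_ind <- vapply(per_site, function(x) mean(x$ind), numeric(1))

  minmax <- function(x) {
    r <- max(x) - min(x)
    if (r == 0) return(rep(0.5, length(x)))
    (x - min(x)) / r
  }
  score_con <- minmax(raw_con)
  score_ind <- minmax(raw_ind)
  delta <- score_ind - score_con

  pvalue <- vapply(motifs, function(m) {
    x <- per_site[[m]]$con
    y <- per_site[[m]]$ind
    obs <- mean(y) - mean(x)
    pool <- c(x, y)
    n_x <- length(x)
    n_tot <- length(pool)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n_tot, n_x)
      stat <- mean(pool[-idx]) - mean(pool[idx])
      if (abs(stat) >= abs(obs)) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  }, numeric(1))

  data.frame(
    motif_id = motifs, raw_con = raw_con, raw_ind = raw_ind,
    score_con = score_con, score_ind = score_ind, delta = delta,
    pvalue = pvalue,
    significant = abs(delta) >= delta_threshold & pvalue < p_threshold,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Build per-motif insertion-profile panels
#'
#' Splits a site table by motif and computes one [insertion_profile] per
#' motif from the given fragments.
#'
#' @param fragments fragment data.frame (chrom, start, end).
#' @param sites site data.frame (motif_id, chrom, start, end).
#' @param window profile width in bp.
#' @return named list of [insertion_profile] objects.
#' @export
profile_panel <- function(fragments, sites, window = 200L) {
  lapply(split(sites, sites$motif_id), function(s) {
    insertion_profile(fragments, s, window = window)
  })
}
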