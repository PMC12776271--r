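#' Simulate Tn5 fragment records with planted footprints
#'
#' For every sample, each peak receives a Poisson number of fragments; both
#' fragment ends are Tn5 insertions drawn uniformly over the peak, except
#' over bound-motif spans, where insertion density is multiplied by
#' `(1 - footprint_protection)` in the condition where the motif is bound.
#' Records use the BED dialect (0-based half-open) with the standard Tn5
#' offset baked in, so that shifting the 5' end by +4 and the 3' end by -5
#' recovers the sampled insertion positions exactly.
#'
#' @param cfg a [sim_config].
#' @param ref a [make_reference] result.
#' @param truth a `truth_set` from [plant_motifs_and_truth].
#' @return data.frame with columns chrom, start, end, sample, condition.
#' @export
simulate_fragments <- function(cfg, ref, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "truth_set"))
  set.seed(cfg$seed + 3L)
  samples <- sim_sample_sheet(cfg)
  peaks <- ref$peaks

  ch_acc <- st_acc <- en_acc <- sm_acc <- cd_acc <- vector("list", 0L)
  for (s in seq_len(nrow(samples))) {
    cond <- samples$condition[s]
    bm <- truth$bound_motifs[[cond]]
    for (p in seq_len(nrow(peaks))) {
      pk <- peaks[p, ]
      pos <- seq.int(pk$start, pk$end - 1L)
      wgt <- rep(1, length(pos))
      if (nrow(bm)) {
        spans <- bm[bm$peak_id == pk$peak_id, , drop = FALSE]
        for (b in seq_len(nrow(spans))) {
          inside <- pos >= spans$start[b] & pos < spans$end[b]
          wgt[inside] <- wgt[inside] * (1 - cfg$footprint_protection)
        }
      }
      nf <- rpois(1L, cfg$frags_per_peak)
      if (nf == 0L) next
      draw <- function(n) sample(pos, n, replace = TRUE,
                                 prob = if (all(wgt == 1)) NULL else wgt)
      p1 <- draw(nf); p2 <- draw(nf)
      tie <- p1 == p2
      while (any(tie)) {
        p2[tie] <- draw(sum(tie))
        tie <- p1 == p2
      }
      lo <- pmin(p1, p2); hi <- pmax(p1, p2)
      i <- length(st_acc) + 1L
      ch_acc[[i]] <- rep(pk$chrom, nf)
      st_acc[[i]] <- lo - 4L
      en_acc[[i]] <- hi + 5L
      sm_acc[[i]] <- rep(samples$sample[s], nf)
      cd_acc[[i]] <- rep(cond, nf)
    }
  }
  frags <- data.frame(chrom = unlist(ch_acc), start = unlist(st_acc),
                      end = unlist(en_acc), sample = unlist(sm_acc),
                      condition = unlist(cd_acc), stringsAsFactors = FALSE)
  if (any(frags$start < 0) || any(frags$end > cfg$chrom_len)) {
    stop("fragment runs off the chromosome; peaks too close to the edge",
         call. = FALSE)
  }
  rownames(frags) <- NULL
  frags
}
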