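#' Generate a toy genome, gene models, and a non-overlapping peak set
#'
#' Lays genes out on an even grid along each chromosome (unique TSSs,
#' alternating-ish strands, gene bodies capped by the grid spacing), then
#' places peaks deterministically: the first `ceiling(prom_peak_fraction *
#' n_peaks)` peaks promoter-proximal (summit within +/- 3 kb of a TSS, at
#' most two per gene) and the remainder distal (well outside every promoter
#' window, at most two per inter-gene gap). All coordinates are 0-based
#' half-open; peaks are pairwise non-overlapping and lie fully inside their
#' chromosome.
#'
#' @param cfg a [sim_config].
#' @return A list of class `sim_reference` with elements `genome`
#'   (a [Biostrings::DNAStringSet]), `genes` (gene_id, chrom, strand, tss,
#'   tes), and `peaks` (peak_id, chrom, start, end, summit, placement).
#' @export
make_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE),
          collapse = "")
  }, character(1)))
  names(genome) <- chroms

  # genes: contiguous chunks per chromosome on an even grid
  per_chrom <- diff(floor(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  gene_chrom <- rep(chroms, per_chrom)
  spacing <- cfg$chrom_len / pmax(per_chrom, 1L)
  idx_in_chrom <- unlist(lapply(per_chrom, seq_len), use.names = FALSE)
  sp <- spacing[match(gene_chrom, chroms)]
  tss <- as.integer(round((idx_in_chrom - 0.5) * sp))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  max_len <- pmin(cfg$gene_length_range[2], as.integer(floor(sp * 0.4)))
  if (any(max_len < cfg$gene_length_range[1])) {
    glen <- pmax(pmin(max_len, cfg$gene_length_range[2]), 200L)
  } else {
    glen <- as.integer(round(runif(cfg$n_genes, cfg$gene_length_range[1],
                                   max_len)))
  }
  tes <- ifelse(strand == "+", tss + glen, tss - glen)
  tes <- pmin(pmax(tes, 0L), cfg$chrom_len - 1L)
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
    chrom = gene_chrom, strand = strand,
    tss = as.integer(tss), tes = as.integer(tes),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes[, c("chrom", "tss")])) {
    stop("chromosome too short: duplicate TSS positions", call. = FALSE)
  }

  # peaks
  n_prom <- as.integer(ceiling(cfg$prom_peak_fraction * cfg$n_peaks))
  n_dist <- cfg$n_peaks - n_prom
  w <- cfg$peak_width
  min_sp <- min(sp)
  if (n_prom > 0 && min_sp < 2400 + w) {
    stop("chromosome too short to host promoter peaks at this gene density",
         call. = FALSE)
  }
  if (n_dist > 0 && min_sp < (3000 + 200 + w / 2) / 0.38) {
    stop("chromosome too short to host distal peaks outside promoter windows",
         call. = FALSE)
  }
  if (n_prom > 2L * cfg$n_genes || n_dist > 2L * cfg$n_genes) {
    stop("not enough genes/gaps to host the requested peaks", call. = FALSE)
  }

  centers <- character(0)
  mk <- function(center, chrom, placement) {
    data.frame(chrom = chrom,
               start = as.integer(center - w %/% 2),
               end = as.integer(center - w %/% 2 + w),
               summit = as.integer(center),
               placement = placement, stringsAsFactors = FALSE)
  }
  peak_list <- vector("list", cfg$n_peaks)
  if (n_prom > 0) {
    g_idx <- rep(seq_len(cfg$n_genes), length.out = n_prom)
    side <- ifelse(seq_len(n_prom) <= cfg$n_genes, 1, -1)
    off <- side * as.integer(round(runif(n_prom, 450, 950)))
    for (j in seq_len(n_prom)) {
      peak_list[[j]] <- mk(genes$tss[g_idx[j]] + off[j],
                           genes$chrom[g_idx[j]], "promoter")
    }
  }
  if (n_dist > 0) {
    g_idx <- rep(seq_len(cfg$n_genes), length.out = n_dist)
    frac <- ifelse(seq_len(n_dist) <= cfg$n_genes, 0.38, 0.62)
    jit <- as.integer(round(runif(n_dist, -200, 200)))
    for (j in seq_len(n_dist)) {
      gi <- g_idx[j]
      center <- as.integer(round(genes$tss[gi] +
                                 frac[j] * sp[gi])) + jit[j]
      center <- min(max(center, w), cfg$chrom_len - w)
      peak_list[[n_prom + j]] <- mk(center, genes$chrom[gi], "distal")
    }
  }
  peaks <- do.call(rbind, peak_list)
  peaks <- peaks[order(match(peaks$chrom, chroms), peaks$start), , drop = FALSE]
  peaks$peak_id <- sprintf("peak%04d", seq_len(nrow(peaks)))
  peaks <- peaks[, c("peak_id", "chrom", "start", "end", "summit", "placement")]
  rownames(peaks) <- NULL

  if (any(peaks$start < 0) || any(peaks$end > cfg$chrom_len)) {
    stop("chromosome too short: peak runs off the end", call. = FALSE)
  }
  by_chrom <- split(peaks, peaks$chrom)
  for (pc in by_chrom) {
    if (nrow(pc) > 1 && any(pc$start[-1] < pc$end[-nrow(pc)])) {
      stop("internal error: overlapping peaks generated", call. = FALSE)
    }
  }
  structure(list(genome = genome, genes = genes, peaks = peaks),
            class = "sim_reference")
}

#' @export
print.sim_reference <- function(x, ...) {
  cat(sprintf("sim_reference: %d chrom(s), %d genes, %d peaks\n",
              length(x$genome), nrow(x$genes), nrow(x$peaks)))
  invisible(x)
}
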