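overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  hits <- GenomicRanges::findOverlaps(peaks_to_granges(query),
                                      peaks_to_granges(subject))
  out <- rep(FALSE, nrow(query))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Stratify two factors' condition peak sets into six occupancy groups
#'
#' For each factor, a CON peak is `shared` when it overlaps (>= 1 bp) any
#' IND peak of the same factor, else CON-specific; symmetric for IND. The
#' six groups (factor A CON-specific / IND-specific / shared, likewise for
#' factor B) partition the inputs: per factor and condition,
#' specific + shared-side = all peaks. Shared counts are reported from the
#' CON side together with both percentages, and the shared region list is
#' the union-merge of overlapping CON/IND pairs.
#'
#' @param a_con,a_ind,b_con,b_ind peak data.frames for factors A and B in
#'   the two conditions.
#' @param factor_names names of the two factors (for group labels).
#' @return list with `groups` (named list of peak data.frames:
#'   A_CON_specific, A_IND_specific, A_shared, B_CON_specific,
#'   B_IND_specific, B_shared; shared given per side and merged), and
#'   `summary` (data.frame per factor: n_con, n_ind, n_shared,
#'   pct_of_con, pct_of_ind, n_shared_merged).
#' @export
stratify_peak_groups <- function(a_con, a_ind, b_con, b_ind,
                                 factor_names = c("A", "B")) {
  one_factor <- function(con, ind, fac) {
    if (nrow(con) == 0 || nrow(ind) == 0) {
      warning("empty input peak set for factor ", fac)
    }
    con_shared <- overlaps_any(con, ind)
    ind_shared <- overlaps_any(ind, con)
    shared_pairs <- rbind(con[con_shared, intersect(names(con),
                              c("peak_id", "chrom", "start", "end", "summit")),
                              drop = FALSE],
                          ind[ind_shared, intersect(names(ind),
                              c("peak_id", "chrom", "start", "end", "summit")),
                              drop = FALSE])
    merged <- if (nrow(shared_pairs)) {
      gr <- GenomicRanges::reduce(peaks_to_granges(shared_pairs))
      data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = character(0), start = integer(0), end = integer(0))
    }
    list(groups = setNames(list(con[!con_shared, , drop = FALSE],
                                ind[!ind_shared, , drop = FALSE],
                                con[con_shared, , drop = FALSE],
                                ind[ind_shared, , drop = FALSE],
                                merged),
                           paste0(fac, c("_CON_specific", "_IND_specific",
                                         "_shared_CON", "_shared_IND",
                                         "_shared_merged"))),
         summary = data.frame(
           factor = fac, n_con = nrow(con), n_ind = nrow(ind),
           n_shared = sum(con_shared),
           pct_of_con = if (nrow(con)) 100 * sum(con_shared) / nrow(con)
                        else NA_real_,
           pct_of_ind = if (nrow(ind)) 100 * sum(ind_shared) / nrow(ind)
                        else NA_real_,
           n_shared_merged = nrow(merged), stringsAsFactors = FALSE))
  }
  a <- one_factor(a_con, a_ind, factor_names[1])
  b <- one_factor(b_con, b_ind, factor_names[2])
  list(groups = c(a$groups, b$groups),
       summary = rbind(a$summary, b$summary))
}

#' Genomic-context annotation of peaks
#'
#' Labels each peak by its summit position (midpoint fallback) with
#' priority promoter > intragenic > distal_intergenic: `promoter` when the
#' summit lies in `[TSS - promoter, TSS + promoter)` of any gene,
#' `intragenic` when it lies in a gene body (TSS..TES, either strand), else
#' `distal_intergenic`.
#'
#' @param peaks peak data.frame.
#' @param genes gene data.frame (gene_id, chrom, strand, tss, tes).
#' @param promoter promoter half-width in bp (default 3000).
#' @return list with `labels` (per-peak data.frame peak_id, context) and
#'   `fractions` (named fractions over the three labels).
#' @export
annotate_context <- function(peaks, genes, promoter = 3000L) {
  summit <- peak_summits(peaks)
  n <- nrow(peaks)
  context <- rep("distal_intergenic", n)
  for (ch in unique(peaks$chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (!length(gi) || !length(pi)) next
    tss <- genes$tss[gi]
    body_lo <- pmin(genes$tss[gi], genes$tes[gi])
    body_hi <- pmax(genes$tss[gi], genes$tes[gi])
    for (k in seq_along(pi)) {
      s <- summit[pi[k]]
      rel <- s - tss
      if (any(rel >= -promoter & rel < promoter)) {
        context[pi[k]] <- "promoter"
      } else if (any(s >= body_lo & s < body_hi)) {
        context[pi[k]] <- "intragenic"
      }
    }
  }
  labels <- data.frame(peak_id = peaks$peak_id %||%
                         sprintf("peak%04d", seq_len(n)),
                       context = context, stringsAsFactors = FALSE)
  lev <- c("promoter", "intragenic", "distal_intergenic")
  fractions <- table(factor(context, levels = lev)) / max(n, 1)
  list(labels = labels, fractions = setNames(as.numeric(fractions), lev))
}

#' DAR and DEG associations per peak group
#'
#' For each peak group, counts differentially accessible regions (DARs,
#' from a differential test on the ATAC peak universe) overlapping any
#' group peak by >= 1 bp, split into opening (`up`) and closing (`down`),
#' and the unique differential genes among the gene assignments of the
#' group peaks, split into up- and down-regulated. Peaks without a gene
#' assignment are excluded from DEG counting only.
#'
#' @param groups named list of peak data.frames (e.g. from
#'   [stratify_peak_groups]).
#' @param dars [diff_test] result on the ATAC universe.
#' @param atac_peaks the ATAC peak universe (peak_id, chrom, start, end).
#' @param diff_rna [diff_test] result on genes.
#' @param peak2gene an [assign_peaks_to_genes] result mapping *group*
#'   peaks to genes.
#' @return data.frame per group: group, n_peaks, n_open_dar, n_closed_dar,
#'   n_up_deg, n_down_deg.
#' @export
associate_dars_degs <- function(groups, dars, atac_peaks, diff_rna,
                                peak2gene) {
  dar_up <- atac_peaks[atac_peaks$peak_id %in%
                         dars$feature[dars$status == "up"], , drop = FALSE]
  dar_down <- atac_peaks[atac_peaks$peak_id %in%
                           dars$feature[dars$status == "down"], ,
                         drop = FALSE]
  rows <- lapply(names(groups), function(g) {
    pk <- groups[[g]]
    if (!nrow(pk)) {
      return(data.frame(group = g, n_peaks = 0L, n_open_dar = 0L,
                        n_closed_dar = 0L, n_up_deg = 0L, n_down_deg = 0L,
                        stringsAsFactors = FALSE))
    }
    n_open <- sum(overlaps_any(dar_up, pk))
    n_closed <- sum(overlaps_any(dar_down, pk))
    gid <- peak2gene$gene_id[match(pk$peak_id, peak2gene$peak_id)]
    gid <- unique(gid[!is.na(gid)])
    st <- diff_rna$status[match(gid, diff_rna$feature)]
    data.frame(group = g, n_peaks = nrow(pk),
               n_open_dar = n_open, n_closed_dar = n_closed,
               n_up_deg = sum(st == "up", na.rm = TRUE),
               n_down_deg = sum(st == "down", na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Redistribution of one factor's lost peaks to another factor's gains
#'
#' The redistributed set is the lost peaks (factor B CON-specific) that
#' overlap (>= 1 bp) the other factor's gained peaks (factor A
#' IND-specific). Reports the redistributed fraction and, via
#' [annotate_context], the promoter-proximal fraction of the redistributed
#' subset.
#'
#' @param lost_b peak data.frame of lost peaks.
#' @param gained_a peak data.frame of gained peaks.
#' @param genes gene models for context annotation.
#' @param promoter promoter half-width in bp.
#' @return list: n_lost, n_redistributed, fraction_redistributed,
#'   promoter_fraction (of the redistributed subset), redistributed
#'   (the peak subset).
#' @export
redistribution <- function(lost_b, gained_a, genes, promoter = 3000L) {
  if (nrow(lost_b) == 0) {
    warning("no lost peaks; redistribution undefined")
    return(list(n_lost = 0L, n_redistributed = 0L,
                fraction_redistributed = NA_real_,
                promoter_fraction = NA_real_,
                redistributed = lost_b))
  }
  hit <- overlaps_any(lost_b, gained_a)
  redis <- lost_b[hit, , drop = FALSE]
  promoter_fraction <- if (nrow(redis)) {
    unname(annotate_context(redis, genes, promoter)$fractions["promoter"])
  } else NA_real_
  list(n_lost = nrow(lost_b), n_redistributed = nrow(redis),
       fraction_redistributed = nrow(redis) / nrow(lost_b),
       promoter_fraction = promoter_fraction,
       redistributed = redis)
}
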