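#' Assign peaks to genes by promoter overlap, then nearest TSS
#'
#' A peak whose summit (midpoint fallback) lies inside a gene's promoter
#' window `[TSS - promoter, TSS + promoter)` is assigned to that gene
#' (nearest TSS when several promoters overlap); otherwise to the nearest
#' TSS within `max_distal`; otherwise unassigned (NA).
#'
#' @param peaks peak data.frame (peak_id, chrom, start, end, summit).
#' @param genes gene data.frame (gene_id, chrom, tss).
#' @param promoter promoter half-width in bp (default 3000).
#' @param max_distal maximum distance for distal assignment (default 1e5).
#' @return data.frame: peak_id, gene_id (NA when unassigned), distance
#'   (summit to TSS, bp), type ("promoter"/"distal"/NA).
#' @export
assign_peaks_to_genes <- function(peaks, genes, promoter = 3000L,
                                  max_distal = 100000L) {
  summit <- peak_summits(peaks)
  n <- nrow(peaks)
  gene_id <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  type <- rep(NA_character_, n)
  for (ch in unique(peaks$chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (!length(gi) || !length(pi)) next
    tss <- genes$tss[gi]
    d <- abs(outer(summit[pi], tss, "-"))
    # promoter window is half-open on the right: [tss - promoter, tss + promoter)
    rel <- outer(summit[pi], tss, "-")
    in_prom <- rel >= -promoter & rel < promoter
    for (k in seq_along(pi)) {
      p <- pi[k]
      cand <- which(in_prom[k, ])
      if (length(cand)) {
        j <- cand[which.min(d[k, cand])]
        gene_id[p] <- genes$gene_id[gi[j]]
        distance[p] <- rel[k, j]
        type[p] <- "promoter"
      } else {
        j <- which.min(d[k, ])
        if (d[k, j] <= max_distal) {
          gene_id[p] <- genes$gene_id[gi[j]]
          distance[p] <- rel[k, j]
          type[p] <- "distal"
        }
      }
    }
  }
  data.frame(peak_id = peaks$peak_id, gene_id = gene_id,
             distance = distance, type = type,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a condition-specific gene regulatory network
#'
#' A candidate edge TF -> target exists when a peak assigned to the target
#' gene carries a motif hit mapped to the TF. The edge keeps, over its
#' candidate linking peaks, the one maximizing the edge score: the
#' geometric mean of (i) the best hit's match fraction, (ii) the linking
#' peak's accessibility quantile rank within the condition's mean
#' normalized ATAC signal, and (iii) the absolute TF-target expression
#' correlation (Pearson, log2 normalized counts, all samples of the
#' condition pooled across blocks). Edges are retained when
#' `score > score_threshold` and `|corr| > corr_threshold`.
#'
#' @param rna RNA [count_matrix] (TF ids must be features).
#' @param atac ATAC [count_matrix] over peaks.
#' @param hits motif hits from [scan_peaks].
#' @param peak2gene a [assign_peaks_to_genes] result.
#' @param tf2motif data.frame (tf, motif_id).
#' @param condition condition label to build for.
#' @param score_threshold edge-score cutoff (default 0.5).
#' @param corr_threshold absolute-correlation cutoff (default 0.3).
#' @return list of class `grn`: condition, edges (tf, target, peak, score,
#'   corr, condition), nodes.
#' @export
build_grn <- function(rna, atac, hits, peak2gene, tf2motif, condition,
                      score_threshold = 0.5, corr_threshold = 0.3) {
  rna_c <- subset_condition(rna, condition)
  atac_c <- subset_condition(atac, condition)
  if (ncol(rna_c$counts) < 3) {
    stop("need >= 3 samples in condition ", condition, call. = FALSE)
  }
  missing_tf <- setdiff(tf2motif$tf, rownames(rna$counts))
  if (length(missing_tf)) {
    warning("TF(s) not in the RNA features, excluded: ",
            paste(missing_tf, collapse = ", "))
    tf2motif <- tf2motif[!tf2motif$tf %in% missing_tf, , drop = FALSE]
  }

  # accessibility quantile rank of each peak (mean normalized signal)
  sf_a <- size_factors(atac)
  acc <- rowMeans(sweep(atac_c$counts, 2,
                        sf_a[colnames(atac_c$counts)], "/"))
  acc_rank <- rank(acc, ties.method = "average") / length(acc)

  # log2 normalized expression for correlations
  sf_r <- size_factors(rna)
  expr <- log2(sweep(rna_c$counts, 2, sf_r[colnames(rna_c$counts)], "/") + 1)

  cand <- merge(hits, tf2motif, by = "motif_id")
  cand <- merge(cand, peak2gene[!is.na(peak2gene$gene_id),
                                c("peak_id", "gene_id")], by = "peak_id")
  cand <- cand[cand$gene_id %in% rownames(rna$counts), , drop = FALSE]
  if (!nrow(cand)) {
    return(structure(list(condition = condition,
                          edges = data.frame(tf = character(0),
                                             target = character(0),
                                             peak = character(0),
                                             score = numeric(0),
                                             corr = numeric(0),
                                             condition = character(0)),
                          nodes = character(0)), class = "grn"))
  }
  # best hit per peak x motif
  cand <- cand[order(cand$peak_id, cand$motif_id,
                     -cand$match_fraction), , drop = FALSE]
  cand <- cand[!duplicated(cand[, c("peak_id", "motif_id")]), , drop = FALSE]

  pair_key <- paste(cand$tf, cand$gene_id, sep = "\r")
  corr_cache <- new.env(parent = emptyenv())
  corr_of <- function(tf, tg, key) {
    if (!is.null(corr_cache[[key]])) return(corr_cache[[key]])
    v <- suppressWarnings(cor(expr[tf, ], expr[tg, ]))
    if (is.na(v)) v <- 0
    corr_cache[[key]] <- v
    v
  }
  corr <- vapply(seq_len(nrow(cand)), function(i) {
    corr_of(cand$tf[i], cand$gene_id[i], pair_key[i])
  }, numeric(1))
  rank_i <- acc_rank[match(cand$peak_id, rownames(atac$counts))]
  score <- (cand$match_fraction * rank_i * abs(corr))^(1 / 3)

  edges <- data.frame(tf = cand$tf, target = cand$gene_id,
                      peak = cand$peak_id, score = score, corr = corr,
                      condition = condition, stringsAsFactors = FALSE)
  edges <- edges[edges$score > score_threshold &
                   abs(edges$corr) > corr_threshold, , drop = FALSE]
  # several linking peaks: keep the max-score one
  edges <- edges[order(edges$tf, edges$target, -edges$score), , drop = FALSE]
  edges <- edges[!duplicated(edges[, c("tf", "target")]), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(condition = condition, edges = edges,
                 nodes = union(edges$tf, edges$target)), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("grn[%s]: %d edges, %d nodes, %d TFs\n", x$condition,
              nrow(x$edges), length(x$nodes), length(unique(x$edges$tf))))
  invisible(x)
}

normalized_out_degree <- function(grn, tfs) {
  n_nodes <- length(grn$nodes)
  deg <- vapply(tfs, function(tf) {
    if (n_nodes < 2) return(0)
    sum(grn$edges$tf == tf) / (n_nodes - 1)
  }, numeric(1))
  deg
}

#' Normalized TF degree and condition difference
#'
#' Per TF, normalized out-degree (targets / (N - 1), N = nodes of that
#' network; 0 for TFs absent from a network), optionally averaged over
#' replicate networks, and `delta_degree = degree_ind - degree_con`.
#'
#' @param grn_con,grn_ind `grn` objects (or lists of replicate `grn`s).
#' @param tfs TF universe; default: TFs seen in any input network.
#' @return data.frame: tf, degree_con, degree_ind, delta_degree.
#' @export
degree_and_delta <- function(grn_con, grn_ind, tfs = NULL) {
  as_list <- function(g) if (inherits(g, "grn")) list(g) else g
  lc <- as_list(grn_con); li <- as_list(grn_ind)
  if (any(vapply(c(lc, li), function(g) nrow(g$edges), integer(1)) == 0)) {
    warning("empty network: degrees are 0")
  }
  if (is.null(tfs)) {
    tfs <- unique(unlist(lapply(c(lc, li), function(g) g$edges$tf)))
  }
  deg_mat <- function(gl) {
    matrix(vapply(gl, normalized_out_degree, numeric(length(tfs)),
                  tfs = tfs), nrow = length(tfs))
  }
  dc <- rowMeans(deg_mat(lc))
  di <- rowMeans(deg_mat(li))
  data.frame(tf = tfs, degree_con = dc, degree_ind = di,
             delta_degree = di - dc, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' TF-TF projection of a GRN by shared targets
#'
#' @param grn a `grn`.
#' @return data.frame (tf_a, tf_b, weight = shared target count);
#'   zero-weight pairs are omitted, each unordered pair appears once.
#' @export
tf_tf_projection <- function(grn) {
  tfs <- sort(unique(grn$edges$tf))
  out <- list()
  k <- 0L
  targets <- split(grn$edges$target, grn$edges$tf)
  if (length(tfs) >= 2) {
    for (i in seq_len(length(tfs) - 1)) {
      for (j in (i + 1):length(tfs)) {
        w <- length(intersect(targets[[tfs[i]]], targets[[tfs[j]]]))
        if (w > 0) {
          k <- k + 1L
          out[[k]] <- data.frame(tf_a = tfs[i], tf_b = tfs[j], weight = w,
                                 stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!k) {
    return(data.frame(tf_a = character(0), tf_b = character(0),
                      weight = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Edge overlap between two networks
#'
#' Edges are compared as (tf, target) pairs. Reports the Jaccard-style
#' shared fraction `|A intersect B| / |A union B|` plus the shared fraction
#' of each network.
#'
#' @param grn_a,grn_b `grn` objects.
#' @return list: n_shared, n_a, n_b, shared_union_fraction,
#'   shared_fraction_a, shared_fraction_b. All NA with a warning when both
#'   edge sets are empty.
#' @export
network_overlap <- function(grn_a, grn_b) {
  ea <- unique(paste(grn_a$edges$tf, grn_a$edges$target, sep = "\r"))
  eb <- unique(paste(grn_b$edges$tf, grn_b$edges$target, sep = "\r"))
  if (!length(ea) && !length(eb)) {
    warning("both networks are empty; overlap undefined")
    return(list(n_shared = NA_integer_, n_a = 0L, n_b = 0L,
                shared_union_fraction = NA_real_,
                shared_fraction_a = NA_real_, shared_fraction_b = NA_real_))
  }
  ns <- length(intersect(ea, eb))
  list(n_shared = ns, n_a = length(ea), n_b = length(eb),
       shared_union_fraction = ns / length(union(ea, eb)),
       shared_fraction_a = if (length(ea)) ns / length(ea) else NA_real_,
       shared_fraction_b = if (length(eb)) ns / length(eb) else NA_real_)
}

#' Join connectivity, expression, and footprint evidence per TF
#'
#' Combines degree differences, differential-expression status, and
#' differential footprint calls into one table. TFs are grouped by their
#' expression response: `Activated` (up), `Repressed` (down), `Unchanged`
#' (ns or missing). TFs missing a modality keep NA values rather than being
#' dropped.
#'
#' @param degrees a [degree_and_delta] result.
#' @param diff a [diff_test] result on RNA (features = genes).
#' @param footcalls a [differential_binding] result.
#' @param tf2motif data.frame (tf, motif_id) linking TFs to footprint motifs.
#' @return data.frame: tf, degree_con, degree_ind, delta_degree, log2fc,
#'   padj, de_status, footprint_delta, group.
#' @export
summarize_tfs <- function(degrees, diff, footcalls, tf2motif) {
  out <- degrees
  i <- match(out$tf, diff$feature)
  out$log2fc <- diff$log2fc[i]
  out$padj <- diff$padj[i]
  out$de_status <- diff$status[i]
  mid <- tf2motif$motif_id[match(out$tf, tf2motif$tf)]
  j <- match(mid, footcalls$motif_id)
  out$footprint_delta <- footcalls$delta[j]
  out$group <- ifelse(is.na(out$de_status), "Unchanged",
                      c(up = "Activated", down = "Repressed",
                        ns = "Unchanged")[out$de_status])
  out$group <- unname(out$group)
  out
}
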