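#' Plant motif instances and build the ground-truth set
#'
#' Writes the consensus (maximum-probability) sequence of each TF's PWM into
#' seeded-random peaks of the toy genome and records the full ground truth:
#' planted sites, which motifs are bound in which condition, the implied
#' TF -> target-gene edges (the target is the gene the host peak is assigned
#' to), the rewired TFs, and the planted differential genes/peaks.
#'
#' Truth cardinalities are deterministic: differential features are the first
#' `ceiling(fraction * n)` after a seeded shuffle; rewired TFs are the first
#' `ceiling(rewire_fraction * n_tfs)` of the bound TFs, assigned alternately
#' to IND-only and CON-only binding. Unbound TFs (when `tf_bound_fraction <
#' 1`) still get planted motif instances but carry no edges or protection.
#'
#' @param cfg a [sim_config].
#' @param ref a [make_reference] result.
#' @param pwms named list of `pwm` objects, at least `n_tfs` of them
#'   (may be empty when `cfg$n_tfs == 0`).
#' @return list with `ref` (the reference with motifs written into the
#'   genome) and `truth` (class `truth_set`).
#' @export
plant_motifs_and_truth <- function(cfg, ref, pwms = list()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ref, "sim_reference"))
  set.seed(cfg$seed + 1L)
  genes <- ref$genes
  peaks <- ref$peaks

  if (cfg$n_tfs > 0 && length(pwms) < cfg$n_tfs) {
    stop("need at least n_tfs PWMs", call. = FALSE)
  }
  tfs <- head(genes$gene_id, cfg$n_tfs)
  motif_ids <- head(names(pwms), cfg$n_tfs)
  tf2motif <- data.frame(tf = tfs, motif_id = motif_ids,
                         stringsAsFactors = FALSE)

  n_bound <- as.integer(ceiling(cfg$tf_bound_fraction * cfg$n_tfs))
  n_rewired <- as.integer(ceiling(cfg$rewire_fraction * cfg$n_tfs))
  if (n_rewired > n_bound) {
    stop("rewired TFs must be bound: increase tf_bound_fraction", call. = FALSE)
  }
  tf_order <- if (cfg$n_tfs > 0) sample(tfs) else character(0)
  bound <- head(tf_order, n_bound)
  rewired <- head(bound, n_rewired)
  rewired_cond <- rep(c("IND", "CON"), length.out = n_rewired)
  bound_tfs <- list(
    CON = c(setdiff(bound, rewired), rewired[rewired_cond == "CON"]),
    IND = c(setdiff(bound, rewired), rewired[rewired_cond == "IND"])
  )

  # site allocation: disjoint peaks per TF, each assigned to a distinct
  # non-TF gene, so every planted edge carries exactly one activity latent
  # and the planted TF-target co-expression is what the config states
  sites <- NULL
  genome <- ref$genome
  p2g_pre <- assign_peaks_to_genes(peaks, genes)
  if (cfg$n_tfs > 0) {
    need <- cfg$n_tfs * cfg$sites_per_tf
    eligible <- which(!is.na(p2g_pre$gene_id) & !(p2g_pre$gene_id %in% tfs))
    pool <- sample(eligible)
    pool <- pool[!duplicated(p2g_pre$gene_id[pool])]
    if (need > length(pool)) {
      stop("not enough peaks mapping to distinct non-TF genes to host ",
           need, " motif sites", call. = FALSE)
    }
    host <- pool[seq_len(need)]
    site_rows <- vector("list", need)
    k <- 0L
    for (i in seq_len(cfg$n_tfs)) {
      p <- pwms[[motif_ids[i]]]
      w <- ncol(p$ppm)
      cons <- pwm_consensus(p)
      for (j in seq_len(cfg$sites_per_tf)) {
        k <- k + 1L
        pk <- peaks[host[k], ]
        half_room <- floor((pk$end - pk$start - w) / 2)
        if (half_room < 0) {
          stop("motif ", p$id, " is longer than peak ", pk$peak_id,
               call. = FALSE)
        }
        off <- sample(seq(-min(30L, half_room), min(30L, half_room)), 1L)
        mstart <- pk$summit - w %/% 2L + off
        mstart <- min(max(mstart, pk$start), pk$end - w)
        Biostrings::subseq(genome[[pk$chrom]], mstart + 1L,
                           mstart + w) <- Biostrings::DNAString(cons)
        site_rows[[k]] <- data.frame(
          peak_id = pk$peak_id, motif_id = p$id, tf = tfs[i],
          chrom = pk$chrom, start = mstart, end = mstart + w,
          offset = mstart + w %/% 2L - pk$summit, strand = "+",
          stringsAsFactors = FALSE)
      }
    }
    sites <- do.call(rbind, site_rows)
  } else {
    sites <- data.frame(peak_id = character(0), motif_id = character(0),
                        tf = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        offset = integer(0), strand = character(0),
                        stringsAsFactors = FALSE)
  }

  # edges: target gene = gene the host peak is assigned to
  sites$target <- p2g_pre$gene_id[match(sites$peak_id, p2g_pre$peak_id)]
  bound_motifs <- lapply(bound_tfs, function(bt) {
    sites[sites$tf %in% bt, , drop = FALSE]
  })
  true_edges <- lapply(bound_motifs, function(bm) {
    keep <- !is.na(bm$target)
    unique(data.frame(tf = bm$tf[keep], target = bm$target[keep],
                      stringsAsFactors = FALSE))
  })

  n_de <- as.integer(ceiling(cfg$de_fraction * cfg$n_genes))
  de_idx <- sample.int(cfg$n_genes)[seq_len(n_de)]
  de_genes <- data.frame(
    gene_id = genes$gene_id[de_idx],
    lfc = rep(c(1, -1), length.out = n_de) * cfg$de_lfc,
    stringsAsFactors = FALSE)

  n_dar <- as.integer(ceiling(cfg$dar_fraction * cfg$n_peaks))
  dar_idx <- sample.int(cfg$n_peaks)[seq_len(n_dar)]
  dars <- data.frame(
    peak_id = peaks$peak_id[dar_idx],
    lfc = rep(c(1, -1), length.out = n_dar) * cfg$dar_lfc,
    stringsAsFactors = FALSE)

  truth <- structure(list(
    tfs = tfs, tf2motif = tf2motif,
    bound_tfs = bound_tfs, rewired_tfs = rewired,
    planted_sites = sites, bound_motifs = bound_motifs,
    true_edges = true_edges,
    de_genes = de_genes, dars = dars
  ), class = "truth_set")

  ref$genome <- genome
  list(ref = ref, truth = truth)
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf(
    "truth_set: %d TFs (%d rewired), %d planted sites, %d DE genes, %d DARs, edges CON=%d IND=%d\n",
    length(x$tfs), length(x$rewired_tfs), nrow(x$planted_sites),
    nrow(x$de_genes), nrow(x$dars),
    nrow(x$true_edges$CON), nrow(x$true_edges$IND)))
  invisible(x)
}
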