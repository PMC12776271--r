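ppm_revcomp <- function(ppm) {
  m <- ppm[4:1, rev(seq_len(ncol(ppm))), drop = FALSE]
  rownames(m) <- DNA_BASES
  m
}

# best Pearson correlation of flattened aligned columns over all ungapped
# offsets of b (and its reverse complement) against a
align_cor <- function(a, b, min_overlap = 4L) {
  wa <- ncol(a); wb <- ncol(b)
  best <- -1
  for (bm in list(b, ppm_revcomp(b))) {
    for (off in seq(-(wb - min_overlap), wa - min_overlap)) {
      ia <- max(1L, 1L + off):min(wa, wb + off)
      ib <- ia - off
      if (length(ia) < min_overlap) next
      va <- as.vector(a[, ia, drop = FALSE])
      vb <- as.vector(bm[, ib, drop = FALSE])
      if (sd(va) == 0 || sd(vb) == 0) next
      r <- cor(va, vb)
      if (r > best) best <- r
    }
  }
  best
}

#' Pairwise PFM similarity of a motif panel
#'
#' Pearson correlation of the flattened position probability matrices,
#' maximized over all ungapped alignment offsets and the reverse
#' complement (minimum overlap 4 columns).
#'
#' @param pwms named list of `pwm` objects.
#' @return symmetric similarity matrix with unit diagonal.
#' @export
motif_similarity <- function(pwms) {
  n <- length(pwms)
  ids <- names(pwms)
  sim <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n < 2) return(sim)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- align_cor(pwms[[i]]$ppm, pwms[[j]]$ppm)
      sim[i, j] <- sim[j, i] <- s
    }
  }
  sim
}

#' Cluster motifs into families by PFM similarity
#'
#' Average-linkage hierarchical clustering on `1 - similarity`, cut at
#' `1 - similarity_threshold`. Each family is labelled by the member motif
#' with the highest mean similarity to the rest of its family.
#'
#' @param pwms named list of at least two `pwm` objects.
#' @param similarity_threshold similarity at which motifs join a family
#'   (default 0.8).
#' @return list with `families` (data.frame motif_id, family, label),
#'   `order` (dendrogram leaf order), `similarity`, and the `hclust` tree.
#' @export
cluster_motifs <- function(pwms, similarity_threshold = 0.8) {
  if (length(pwms) < 2) stop("need >= 2 motifs", call. = FALSE)
  if (any(vapply(pwms, function(p) ncol(p$ppm), integer(1)) < 2)) {
    stop("motifs of width < 2 cannot be aligned", call. = FALSE)
  }
  sim <- motif_similarity(pwms)
  d <- as.dist(1 - sim)
  hc <- hclust(d, method = "average")
  fam <- cutree(hc, h = 1 - similarity_threshold)
  labels <- vapply(split(names(fam), fam), function(members) {
    if (length(members) == 1) return(members)
    sub <- sim[members, members, drop = FALSE]
    members[which.max((rowSums(sub) - 1) / (length(members) - 1))]
  }, character(1))
  families <- data.frame(
    motif_id = names(fam),
    family = as.integer(fam),
    label = labels[as.character(fam)],
    stringsAsFactors = FALSE, row.names = NULL)
  list(families = families, order = hc$order, similarity = sim, hclust = hc)
}
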