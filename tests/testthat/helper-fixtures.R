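# shared fixtures, built once per test run
.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# a compact end-to-end study: 5 TFs x 8 sites, 2 rewired
small_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_chroms = 1L, chrom_len = 1e6, n_genes = 80L,
             n_peaks = 120L, n_tfs = 5L, sites_per_tf = 8L, ...
             )
}

small_study <- function() {
  fixture("small_study", function() simulate_study(small_cfg()))
}

small_networks <- function() {
  fixture("small_networks", function() networks_from_study(small_study()))
}

# random interval sets for overlap property tests (may overlap each other)
rand_peaks <- function(n, chrom_len = 1e5, seed = 1L, chroms = c("c1", "c2"),
                       prefix = "p") {
  set.seed(seed)
  start <- sample.int(chrom_len - 600L, n, replace = TRUE)
  width <- sample(50:500, n, replace = TRUE)
  data.frame(peak_id = sprintf("%s%04d", prefix, seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             summit = start + width %/% 2L,
             stringsAsFactors = FALSE)
}

rand_genes <- function(n, chrom_len = 1e5, seed = 1L, chroms = c("c1", "c2")) {
  set.seed(seed)
  tss <- sample.int(chrom_len, n)
  len <- sample(500:5000, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  data.frame(gene_id = sprintf("g%04d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             strand = strand, tss = tss,
             tes = ifelse(strand == "+", tss + len, pmax(tss - len, 0L)),
             stringsAsFactors = FALSE)
}

# ---- independent brute-force oracles ----

bf_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(query$chrom[i] == subject$chrom &
          query$start[i] < subject$end &
          subject$start < query$end[i])
  }, logical(1))
}

bf_assign <- function(peaks, genes, promoter = 3000L, max_distal = 100000L) {
  s <- peak_summits(peaks)
  vapply(seq_len(nrow(peaks)), function(i) {
    j <- which(genes$chrom == peaks$chrom[i])
    if (!length(j)) return(NA_character_)
    rel <- s[i] - genes$tss[j]
    prom <- which(rel >= -promoter & rel < promoter)
    if (length(prom)) {
      k <- prom[which.min(abs(rel[prom]))]
      return(genes$gene_id[j[k]])
    }
    k <- which.min(abs(rel))
    if (abs(rel[k]) <= max_distal) genes$gene_id[j[k]] else NA_character_
  }, character(1))
}

bf_projection <- function(edges) {
  tfs <- sort(unique(edges$tf))
  out <- list()
  for (i in seq_along(tfs)) {
    for (j in seq_along(tfs)) {
      if (j <= i) next
      a <- unique(edges$target[edges$tf == tfs[i]])
      b <- unique(edges$target[edges$tf == tfs[j]])
      w <- length(intersect(a, b))
      if (w > 0) out[[length(out) + 1L]] <-
          data.frame(tf_a = tfs[i], tf_b = tfs[j], weight = w)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# step-up BH oracle, independent of stats::p.adjust
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# two-sided Fisher p by hypergeometric enumeration
bf_fisher2 <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
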