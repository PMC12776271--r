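mk_grn <- function(edges, condition = "CON") {
  structure(list(condition = condition, edges = edges,
                 nodes = union(edges$tf, edges$target)), class = "grn")
}

test_that("peak-to-gene assignment respects the promoter boundary", {
  genes <- data.frame(gene_id = "g1", chrom = "c1", strand = "+",
                      tss = 50000L, tes = 55000L)
  pk <- function(summit) data.frame(peak_id = "p", chrom = "c1",
                                    start = summit - 50L,
                                    end = summit + 50L, summit = summit)
  at_tss <- assign_peaks_to_genes(pk(50000L), genes)
  expect_equal(at_tss$gene_id, "g1")
  expect_equal(at_tss$distance, 0L)
  expect_equal(at_tss$type, "promoter")
  expect_equal(assign_peaks_to_genes(pk(50000L - 2999L), genes)$type,
               "promoter")
  expect_equal(assign_peaks_to_genes(pk(50000L + 3001L), genes)$type,
               "distal")
  # the window is half-open: -3000 is promoter, +3000 is not
  expect_equal(assign_peaks_to_genes(pk(50000L - 3000L), genes)$type,
               "promoter")
  expect_equal(assign_peaks_to_genes(pk(50000L + 3000L), genes)$type,
               "distal")
  far <- pk(50000L + 200000L)
  expect_true(is.na(assign_peaks_to_genes(far, genes)$gene_id))
})

test_that("assignment matches a brute-force all-pairs scan", {
  for (seed in 1:20) {
    pks <- rand_peaks(60, seed = seed)
    gns <- rand_genes(25, seed = seed + 1000)
    got <- assign_peaks_to_genes(pks, gns)
    expect_equal(got$gene_id, bf_assign(pks, gns))
  }
})

test_that("edge scores combine evidence and thresholds drop weak edges", {
  # two conditions x 3 samples; tf row == target row -> correlation 1
  counts <- rbind(tf1 = c(10, 20, 40, 12, 24, 48),
                  tgA = c(10, 20, 40, 12, 24, 48),
                  tgB = c(30, 30, 30, 30, 30, 30))
  samples <- data.frame(sample = paste0("s", 1:6),
                        condition = rep(c("CON", "IND"), each = 3),
                        replicate = rep(1:3, 2), block = 1L)
  rna <- count_matrix(counts, samples)
  atac <- count_matrix(matrix(c(100, 5)[c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2, 1, 2)],
                              nrow = 2, dimnames = list(c("pk1", "pk2"), NULL)),
                       samples)
  hits <- data.frame(peak_id = c("pk1", "pk1"), motif_id = "m1",
                     strand = "+", offset = 0L, score = 5,
                     match_fraction = c(1, 1))
  p2g <- data.frame(peak_id = c("pk1", "pk2"), gene_id = c("tgA", "tgB"),
                    distance = 0L, type = "promoter")
  t2m <- data.frame(tf = "tf1", motif_id = "m1")
  g <- build_grn(rna, atac, hits, p2g, t2m, "CON")
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$target, "tgA")
  expect_equal(g$edges$corr, 1)
  # pk1 is the most accessible peak -> rank 1; perfect match; corr 1
  expect_equal(g$edges$score, 1)

  # constant target: correlation undefined -> treated as 0 -> dropped
  hits2 <- data.frame(peak_id = "pk2", motif_id = "m1", strand = "+",
                      offset = 0L, score = 5, match_fraction = 1)
  g2 <- build_grn(rna, atac, hits2, p2g, t2m, "CON")
  expect_equal(nrow(g2$edges), 0L)

  expect_error(build_grn(rna, atac, hits, p2g, t2m, "MISSING"),
               "no samples")
  expect_warning(
    build_grn(rna, atac, hits, p2g,
              data.frame(tf = c("tf1", "ghost"), motif_id = c("m1", "m2")),
              "CON"),
    "not in the RNA")
})

test_that("raising thresholds never adds edges", {
  nets <- small_networks()
  study <- small_study()
  base <- nets$grn_con$edges
  for (st in c(0.6, 0.7)) {
    for (ct in c(0.4, 0.5)) {
      g <- build_grn(study$rna, study$atac, nets$hits, nets$peak2gene,
                     study$truth$tf2motif, "CON",
                     score_threshold = st, corr_threshold = ct)
      key <- paste(g$edges$tf, g$edges$target)
      expect_true(all(key %in% paste(base$tf, base$target)))
    }
  }
})

test_that("degrees are normalized out-degrees with absent TFs at zero", {
  edges <- data.frame(tf = c("A", "A", "A", "A", "B"),
                      target = c("B", "C", "D", "E", "C"),
                      peak = "p", score = 1, corr = 1, condition = "CON")
  g <- mk_grn(edges)  # nodes: A..E -> N = 5
  dd <- degree_and_delta(g, g, tfs = c("A", "B", "Z"))
  expect_equal(dd$degree_con[dd$tf == "A"], 1)       # connected to all
  expect_equal(dd$degree_con[dd$tf == "B"], 1 / 4)
  expect_equal(dd$degree_con[dd$tf == "Z"], 0)
  expect_equal(dd$delta_degree, rep(0, 3))

  # replicate averaging
  e2 <- edges[1:2, ]
  dd2 <- degree_and_delta(list(g, mk_grn(e2)), g, tfs = "A")
  expect_equal(dd2$degree_con, mean(c(1, 2 / 2)))
  expect_warning(degree_and_delta(mk_grn(edges[0, ]), g), "empty")
})

test_that("degree computation is label-invariant", {
  set.seed(17)
  tfs <- paste0("T", 1:6)
  edges <- data.frame(tf = sample(tfs, 30, TRUE),
                      target = sample(paste0("G", 1:15), 30, TRUE),
                      peak = "p", score = 1, corr = 1, condition = "CON")
  edges <- edges[!duplicated(edges[, 1:2]), ]
  g <- mk_grn(edges)
  relab <- edges
  u <- unique(c(edges$tf, edges$target))
  map <- setNames(paste0("x", seq_along(u)), u)
  relab$tf <- unname(map[edges$tf]); relab$target <- unname(map[edges$target])
  g2 <- mk_grn(relab)
  d1 <- degree_and_delta(g, g, tfs = unique(edges$tf))$degree_con
  d2 <- degree_and_delta(g2, g2, tfs = unname(map[unique(edges$tf)]))$degree_con
  expect_equal(sort(d1), sort(d2))
})

test_that("TF-TF projection equals brute-force shared-target counts", {
  e1 <- data.frame(tf = c("A", "A", "B", "B"), target = c("x", "y", "x", "y"),
                   peak = "p", score = 1, corr = 1, condition = "CON")
  proj <- tf_tf_projection(mk_grn(e1))
  expect_equal(proj$weight, 2L)
  e2 <- data.frame(tf = c("A", "B"), target = c("x", "y"),
                   peak = "p", score = 1, corr = 1, condition = "CON")
  expect_equal(nrow(tf_tf_projection(mk_grn(e2))), 0L)

  for (seed in 1:30) {
    set.seed(seed)
    e <- unique(data.frame(tf = sample(paste0("T", 1:8), 60, TRUE),
                           target = sample(paste0("G", 1:25), 60, TRUE)))
    e$peak <- "p"; e$score <- 1; e$corr <- 1; e$condition <- "CON"
    got <- tf_tf_projection(mk_grn(e))
    want <- bf_projection(e)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got[order(got$tf_a, got$tf_b), ],
                   want[order(want$tf_a, want$tf_b), ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("network overlap reports union and per-network fractions", {
  mk <- function(tfs, tgs) mk_grn(data.frame(tf = tfs, target = tgs,
                                             peak = "p", score = 1, corr = 1,
                                             condition = "CON"))
  a <- mk(rep("A", 10), paste0("g", 1:10))
  expect_equal(network_overlap(a, a)$shared_union_fraction, 1)
  b <- mk(rep("B", 10), paste0("g", 1:10))
  expect_equal(network_overlap(a, b)$shared_union_fraction, 0)
  c5 <- mk(rep("A", 10), paste0("g", c(1:5, 21:25)))
  ov <- network_overlap(a, c5)
  expect_equal(ov$shared_union_fraction, 5 / 15, tolerance = 1e-12)
  expect_equal(ov$shared_fraction_a, 0.5)
  expect_equal(ov$shared_fraction_b, 0.5)
  # symmetry of the union fraction
  expect_equal(network_overlap(c5, a)$shared_union_fraction,
               ov$shared_union_fraction)
  expect_warning(ov0 <- network_overlap(mk_grn(a$edges[0, ]),
                                        mk_grn(a$edges[0, ])), "empty")
  expect_true(is.na(ov0$shared_union_fraction))
})

test_that("TF summaries join modalities and group by expression response", {
  degrees <- data.frame(tf = c("t1", "t2", "t3"), degree_con = c(0.5, 0.1, 0),
                        degree_ind = c(0.1, 0.4, 0),
                        delta_degree = c(-0.4, 0.3, 0))
  diff <- data.frame(feature = c("t1", "t2"), log2fc = c(2.5, -3),
                     se = 0.1, pvalue = 1e-5, padj = 1e-4,
                     status = c("up", "down"))
  fc <- data.frame(motif_id = "m1", delta = 0.7, pvalue = 0.001,
                   significant = TRUE)
  t2m <- data.frame(tf = "t1", motif_id = "m1")
  s <- summarize_tfs(degrees, diff, fc, t2m)
  expect_equal(s$group, c("Activated", "Repressed", "Unchanged"))
  expect_equal(s$footprint_delta, c(0.7, NA, NA))
  expect_equal(nrow(s), 3L)  # t3 kept despite missing modalities
})

test_that("rewired TFs change degree more than stable TFs", {
  deltas <- lapply(1:10, function(seed) {
    study <- simulate_study(small_cfg(seed = seed,
                                      n_samples_per_condition = 10L))
    nets <- networks_from_study(study)
    dd <- degree_and_delta(nets$grn_con, nets$grn_ind, tfs = study$truth$tfs)
    split(abs(dd$delta_degree), dd$tf %in% study$truth$rewired_tfs)
  })
  rew <- unlist(lapply(deltas, `[[`, "TRUE"))
  stable <- unlist(lapply(deltas, `[[`, "FALSE"))
  expect_gt(mean(rew), mean(stable))
})
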