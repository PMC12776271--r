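test_that("reference generation is deterministic and satisfies the layout", {
  cfg <- sim_config(n_chroms = 1L, chrom_len = 1e6, n_genes = 80L,
                    n_peaks = 100L, seed = 1L)
  ref1 <- make_reference(cfg)
  ref2 <- make_reference(cfg)
  expect_identical(as.character(ref1$genome), as.character(ref2$genome))
  expect_identical(ref1$genes, ref2$genes)
  expect_identical(ref1$peaks, ref2$peaks)

  pk <- ref1$peaks
  expect_equal(nrow(pk), 100L)
  # brute-force pairwise overlap check
  n_olap <- sum(vapply(seq_len(nrow(pk)), function(i) {
    sum(pk$chrom == pk$chrom[i] & pk$start < pk$end[i] &
          pk$start[i] < pk$end) - 1L
  }, integer(1)))
  expect_equal(n_olap, 0L)
  expect_true(all(pk$start >= 0 & pk$end <= cfg$chrom_len))
  expect_false(anyDuplicated(ref1$genes[, c("chrom", "tss")]) > 0)

  # promoter-proximal fraction is exact by construction
  dist_to_tss <- vapply(seq_len(nrow(pk)), function(i) {
    min(abs(pk$summit[i] - ref1$genes$tss[ref1$genes$chrom == pk$chrom[i]]))
  }, numeric(1))
  n_prom_expected <- ceiling(cfg$prom_peak_fraction * cfg$n_peaks)
  expect_equal(sum(dist_to_tss < 3000), n_prom_expected)
  expect_identical(unname(table(pk$placement)["promoter"]),
                   as.integer(n_prom_expected))
})

test_that("undersized chromosomes are rejected", {
  expect_error(make_reference(sim_config(n_chroms = 1L, chrom_len = 5e4,
                                         n_genes = 100L, n_peaks = 100L)),
               "too short")
})

test_that("planting writes recoverable consensus sites with exact truth counts", {
  study <- small_study()
  truth <- study$truth
  cfg <- study$cfg

  expect_equal(length(truth$rewired_tfs),
               ceiling(cfg$rewire_fraction * cfg$n_tfs))
  expect_equal(nrow(truth$de_genes), ceiling(cfg$de_fraction * cfg$n_genes))
  expect_equal(nrow(truth$dars), ceiling(cfg$dar_fraction * cfg$n_peaks))
  expect_true(all(truth$rewired_tfs %in% truth$tfs))

  # every planted site lies inside its peak
  ps <- merge(truth$planted_sites, study$ref$peaks, by = "peak_id",
              suffixes = c("", ".pk"))
  expect_true(all(ps$start >= ps$start.pk & ps$end <= ps$end.pk))

  # each planted site rescans to a perfect hit at the recorded offset
  hits <- scan_peaks(study$pwms, study$ref$genome, study$ref$peaks,
                     mode = "all")
  hk <- paste(hits$peak_id, hits$motif_id, hits$offset)
  pk <- paste(truth$planted_sites$peak_id, truth$planted_sites$motif_id,
              truth$planted_sites$offset)
  expect_true(all(pk %in% hk))
  perfect <- hits[match(pk, hk), ]
  expect_true(all(perfect$match_fraction == 1))
})

test_that("rewiring controls the condition specificity of true edges", {
  cfg0 <- small_cfg(rewire_fraction = 0)
  t0 <- plant_motifs_and_truth(cfg0, make_reference(cfg0),
                               random_pwms(cfg0$n_tfs, seed = 1))$truth
  expect_identical(t0$true_edges$CON, t0$true_edges$IND)

  cfg5 <- sim_config(n_tfs = 10L, sites_per_tf = 4L, rewire_fraction = 0.5,
                     n_genes = 160L, n_peaks = 240L)
  t5 <- plant_motifs_and_truth(cfg5, make_reference(cfg5),
                               random_pwms(10, seed = 1))$truth
  expect_equal(length(t5$rewired_tfs), 5L)
  for (tf in t5$rewired_tfs) {
    in_con <- tf %in% t5$true_edges$CON$tf
    in_ind <- tf %in% t5$true_edges$IND$tf
    expect_true(xor(in_con, in_ind))
  }
})

test_that("a motif longer than its peak is rejected", {
  cfg <- small_cfg(peak_width = 16L)
  ref <- make_reference(cfg)
  expect_error(plant_motifs_and_truth(cfg, ref,
                                      random_pwms(5, width = 18L, seed = 1)),
               "longer than peak")
})

test_that("simulated counts are deterministic with planted fold changes", {
  study <- small_study()
  cm2 <- simulate_counts(study$cfg, study$ref, study$truth)
  expect_identical(study$rna$counts, cm2$rna$counts)
  expect_identical(study$atac$counts, cm2$atac$counts)
  expect_true(sd(colSums(study$rna$counts)) > 0)

  # de_fraction = 0 plants nothing
  cfg0 <- small_cfg(de_fraction = 0)
  t0 <- plant_motifs_and_truth(cfg0, make_reference(cfg0),
                               random_pwms(5, seed = 1))$truth
  expect_equal(nrow(t0$de_genes), 0L)

  # law of large numbers: planted log2 fold change at n = 200 replicates
  cfgN <- sim_config(n_chroms = 1L, chrom_len = 1e6, n_genes = 60L,
                     n_peaks = 80L, n_tfs = 0L, n_blocks = 1L,
                     n_samples_per_condition = 200L, de_fraction = 0.2,
                     de_lfc = 2, seed = 7L)
  refN <- make_reference(cfgN)
  ptN <- plant_motifs_and_truth(cfgN, refN)
  cmN <- simulate_counts(cfgN, ptN$ref, ptN$truth)
  is_ind <- cmN$rna$samples$condition == "IND"
  emp_lfc <- log2(rowMeans(cmN$rna$counts[, is_ind]) /
                    rowMeans(cmN$rna$counts[, !is_ind]))
  planted <- ptN$truth$de_genes
  expect_true(all(abs(emp_lfc[planted$gene_id] - planted$lfc) < 0.3))
  others <- setdiff(rownames(cmN$rna$counts), planted$gene_id)
  expect_true(all(abs(emp_lfc[others]) < 0.3))
})

test_that("fragments are valid, deterministic, and footprints deplete insertions", {
  cfg <- small_cfg(footprint_protection = 1)
  ref <- make_reference(cfg)
  pt <- plant_motifs_and_truth(cfg, ref, random_pwms(5, seed = 1))
  fr <- simulate_fragments(cfg, pt$ref, pt$truth)
  fr2 <- simulate_fragments(cfg, pt$ref, pt$truth)
  expect_identical(fr, fr2)
  expect_true(all(fr$start >= 0 & fr$start < fr$end &
                    fr$end <= cfg$chrom_len))

  # protection 1: no insertion strictly inside a bound motif span
  for (cond in c("CON", "IND")) {
    bm <- pt$truth$bound_motifs[[cond]]
    ins <- c(fr$start[fr$condition == cond] + 4L,
             fr$end[fr$condition == cond] - 5L)
    chr <- rep(fr$chrom[fr$condition == cond], 2L)
    for (b in seq_len(nrow(bm))) {
      inside <- chr == bm$chrom[b] & ins >= bm$start[b] & ins < bm$end[b]
      expect_equal(sum(inside), 0L)
    }
  }
})

test_that("unprotected insertion density is uniform across motif spans", {
  cfg <- small_cfg(footprint_protection = 0, frags_per_peak = 400,
                   n_samples_per_condition = 2L, n_blocks = 1L)
  ref <- make_reference(cfg)
  pt <- plant_motifs_and_truth(cfg, ref, random_pwms(5, seed = 1))
  fr <- simulate_fragments(cfg, pt$ref, pt$truth)
  ins <- data.frame(chrom = rep(fr$chrom, 2),
                    pos = c(fr$start + 4L, fr$end - 5L))
  # pool site-relative insertion positions over all planted motif spans
  ps <- pt$truth$planted_sites
  rel <- unlist(lapply(seq_len(nrow(ps)), function(i) {
    p <- ins$pos[ins$chrom == ps$chrom[i]]
    p <- p[p >= ps$start[i] & p < ps$end[i]]
    p - ps$start[i]
  }))
  counts <- tabulate(rel + 1L, nbins = 18L)
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("generated files round-trip through the package readers", {
  study <- small_study()
  dir <- withr::local_tempdir()

  fa <- file.path(dir, "genome.fa")
  write_genome_fasta(study$ref$genome, fa)
  expect_identical(as.character(read_genome_fasta(fa)),
                   as.character(study$ref$genome))

  bed <- file.path(dir, "peaks.bed")
  write_peaks_bed(study$ref$peaks, bed)
  back <- read_peaks_bed(bed)
  expect_identical(back[, c("peak_id", "chrom", "start", "end", "summit")],
                   study$ref$peaks[, c("peak_id", "chrom", "start", "end",
                                       "summit")])

  gm <- file.path(dir, "genes.tsv")
  write_gene_models(study$ref$genes, gm)
  expect_identical(read_gene_models(gm), study$ref$genes)

  cmp <- file.path(dir, "rna.tsv")
  write_count_matrix(study$rna, cmp)
  rt <- read_count_matrix(cmp)
  expect_identical(unname(rt$counts), unname(study$rna$counts))
  expect_identical(rt$samples$condition, study$rna$samples$condition)

  fr <- simulate_fragments(study$cfg, study$ref, study$truth)
  fb <- file.path(dir, "frags.bed")
  write_fragments_bed(fr, fb)
  fr_rt <- read_fragments_bed(fb)
  expect_identical(fr_rt[, c("chrom", "start", "end", "sample")],
                   fr[, c("chrom", "start", "end", "sample")])

  tj <- file.path(dir, "truth.json")
  write_truth_json(study$truth, tj)
  truth_rt <- read_truth_json(tj)
  expect_identical(truth_rt$planted_sites$offset,
                   study$truth$planted_sites$offset)
  expect_identical(sort(truth_rt$rewired_tfs), sort(study$truth$rewired_tfs))
})
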