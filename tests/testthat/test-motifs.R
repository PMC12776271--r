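toy_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

one_peak <- function(len, summit = len %/% 2L, chrom = "c1") {
  data.frame(peak_id = "pk1", chrom = chrom, start = 0L, end = len,
             summit = summit, stringsAsFactors = FALSE)
}

test_that("build_pwm converts counts to probabilities and log-odds", {
  uni <- matrix(25, 4, 6)
  p <- build_pwm(uni)
  expect_equal(unname(p$lo), matrix(0, 4, 6))
  expect_true(all(abs(colSums(p$ppm) - 1) < 1e-9))

  hot <- matrix(0, 4, 4); hot[1, ] <- 10
  p2 <- build_pwm(hot, pseudocount = 1e-9)
  expect_equal(unname(p2$lo[1, ]), rep(2, 4), tolerance = 1e-6)

  expect_error(build_pwm(matrix(0, 4, 5)), "zero-sum")
  expect_error(build_pwm(matrix(1, 4, 3)), "width")
})

test_that("JASPAR text round-trips exactly", {
  pwms <- random_pwms(3, width = 10, seed = 5)
  path <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(pwms, path)
  back <- read_jaspar(path)
  expect_identical(names(back), names(pwms))
  for (i in seq_along(pwms)) {
    expect_equal(attr(back[[i]], "pfm"), attr(pwms[[i]], "pfm"))
    expect_equal(back[[i]]$ppm, pwms[[i]]$ppm)
  }
  # write -> read -> build -> write -> read is stable
  path2 <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(back, path2)
  expect_equal(attr(read_jaspar(path2)[[1]], "pfm"), attr(pwms[[1]], "pfm"))
})

test_that("a centered consensus scans to a single perfect central hit", {
  set.seed(3)
  pwm <- random_pwms(1, width = 12, seed = 3)[[1]]
  bg <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  cons <- pwm_consensus(pwm)
  # place consensus so its center (start + w/2) sits at the summit (pos 500)
  s <- 500 - 6
  seq1 <- paste0(substr(bg, 1, s), cons, substr(bg, s + 13, 1000))
  g <- toy_genome(c(c1 = seq1))
  hits <- scan_peaks(pwm, g, one_peak(1000, summit = 500),
                     mode = "best_central")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 0L)
  expect_equal(hits$match_fraction, 1)
  expect_equal(hits$strand, "+")

  # threshold 1 on motif-free sequence: no hits
  g0 <- toy_genome(c(c1 = bg))
  expect_equal(nrow(scan_peaks(pwm, g0, one_peak(1000), threshold = 1)), 0L)
})

test_that("scanning mirrors under reverse complement", {
  pwm <- random_pwms(1, width = 12, seed = 11)[[1]]
  set.seed(12)
  seq1 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq1)))
  h_fwd <- scan_peaks(pwm, toy_genome(c(c1 = seq1)), one_peak(400),
                      threshold = 0.6, mode = "all")
  h_rc <- scan_peaks(pwm, toy_genome(c(c1 = rc)), one_peak(400),
                     threshold = 0.6, mode = "all")
  expect_equal(nrow(h_fwd), nrow(h_rc))
  flip <- data.frame(offset = -h_rc$offset,
                     strand = ifelse(h_rc$strand == "+", "-", "+"),
                     score = h_rc$score)
  o1 <- order(h_fwd$offset, h_fwd$strand)
  o2 <- order(flip$offset, flip$strand)
  expect_equal(h_fwd$offset[o1], flip$offset[o2])
  expect_equal(h_fwd$strand[o1], flip$strand[o2])
  expect_equal(h_fwd$score[o1], flip$score[o2])
})

test_that("match_fraction is invariant to shifting the log-odds", {
  pwm <- random_pwms(1, width = 10, seed = 21)[[1]]
  shifted <- pwm
  shifted$lo <- shifted$lo + 0.8
  set.seed(22)
  seq1 <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  g <- toy_genome(c(c1 = seq1))
  h1 <- scan_peaks(pwm, g, one_peak(600), threshold = 0.55, mode = "all")
  h2 <- scan_peaks(shifted, g, one_peak(600), threshold = 0.55, mode = "all")
  expect_equal(h1$offset, h2$offset)
  expect_equal(h1$match_fraction, h2$match_fraction)
})

test_that("best_central is a subset of all hits and prefers the center", {
  study <- small_study()
  all_h <- scan_peaks(study$pwms, study$ref$genome, study$ref$peaks,
                      mode = "all")
  bc <- scan_peaks(study$pwms, study$ref$genome, study$ref$peaks,
                   mode = "best_central")
  key_all <- paste(all_h$peak_id, all_h$motif_id, all_h$strand, all_h$offset)
  key_bc <- paste(bc$peak_id, bc$motif_id, bc$strand, bc$offset)
  expect_true(all(key_bc %in% key_all))
  expect_false(any(duplicated(bc[, c("peak_id", "motif_id")])))
  # per peak x motif, no hit in "all" is closer to the center
  min_abs <- tapply(abs(all_h$offset),
                    paste(all_h$peak_id, all_h$motif_id), min)
  expect_equal(as.numeric(min_abs[paste(bc$peak_id, bc$motif_id)]),
               as.numeric(abs(bc$offset)))
})

test_that("positional density bins offsets and conserves mass", {
  hits0 <- data.frame(peak_id = "p", motif_id = "m", strand = "+",
                      offset = rep(0L, 7), score = 1, match_fraction = 1)
  d0 <- positional_density(hits0, n_peaks = 10)
  expect_equal(d0$density[d0$bin_start == 0], 0.7)
  expect_equal(sum(d0$density), nrow(hits0) / 10)

  set.seed(31)
  hits_u <- data.frame(peak_id = "p", motif_id = "m", strand = "+",
                       offset = sample(-200:199, 4000, TRUE),
                       score = 1, match_fraction = 1)
  du <- positional_density(hits_u, n_peaks = 100)
  expect_equal(sum(du$count), 4000)
  # flat within a generous binomial envelope (expected 200/bin)
  expect_true(all(abs(du$count - 200) < 4 * sqrt(4000 * (1 / 20) * (19 / 20))))
})

test_that("enrichment separates planted foregrounds and matches Fisher", {
  study <- small_study()
  g <- study$ref$genome
  pk <- study$ref$peaks
  fg <- pk[seq_len(30), ]
  same <- enrich_peakset(study$pwms, fg, g, bg_peaks = fg)
  expect_equal(same$log2_enrichment, rep(0, length(study$pwms)))
  expect_equal(same$pvalue, rep(1, length(study$pwms)))

  # peaks hosting a TF's planted sites vs shuffled background
  st1 <- simulate_study(sim_config(seed = 6L, n_chroms = 1L, chrom_len = 1e6,
                                   n_genes = 80L, n_peaks = 120L,
                                   n_tfs = 1L, sites_per_tf = 25L))
  ps <- st1$truth$planted_sites
  m1 <- names(st1$pwms)[1]
  fg1 <- st1$ref$peaks[st1$ref$peaks$peak_id %in% ps$peak_id, ]
  enr <- enrich_peakset(st1$pwms[m1], fg1, st1$ref$genome, seed = 4)
  expect_gt(enr$log2_enrichment, 0)
  expect_lt(enr$pvalue, 1e-4)

  # package Fisher p equals an exact hypergeometric enumeration
  enr2 <- enrich_peakset(study$pwms, pk[1:40, ], g, bg_peaks = pk[41:120, ])
  for (i in seq_len(nrow(enr2))) {
    a <- round(enr2$f_fg[i] * enr2$n_fg[i])
    b <- enr2$n_fg[i] - a
    c <- round(enr2$f_bg[i] * enr2$n_bg[i])
    d <- enr2$n_bg[i] - c
    expect_equal(enr2$pvalue[i], bf_fisher2(a, b, c, d), tolerance = 1e-8)
  }
  expect_error(enrich_peakset(study$pwms, pk[1:10, ], g), ">= 20")
  expect_error(enrich_peakset(study$pwms, pk[1:40, ], g, bg_peaks = pk[0, ]),
               "empty")
})

test_that("motif similarity handles identity, reverse complement, and disjoint motifs", {
  pwms <- random_pwms(2, width = 10, seed = 41)
  m <- pwms[[1]]
  expect_equal(motif_similarity(list(a = m, b = m))["a", "b"], 1)
  rc <- pwm_revcomp(m)
  expect_equal(motif_similarity(list(a = m, b = rc))["a", "b"], 1,
               tolerance = 1e-12)

  polyA <- build_pwm(rbind(10, 0, 0, 0)[, rep(1, 6), drop = FALSE] *
                       matrix(rep(c(1, 0, 0, 0), 6), 4), id = "polyA")
  polyC <- build_pwm(matrix(rep(c(0, 10, 0, 0), 6), 4), id = "polyC")
  sim <- motif_similarity(list(polyA = polyA, polyC = polyC))
  expect_lt(sim["polyA", "polyC"], 0)
  cl <- cluster_motifs(list(polyA = polyA, polyC = polyC),
                       similarity_threshold = 0.8)
  expect_equal(length(unique(cl$families$family)), 2L)
})

test_that("motif families group near-duplicates and label by centrality", {
  base <- random_pwms(3, width = 10, seed = 51)
  near <- base[[1]]
  near$id <- "near"
  # perturb the PPM slightly: same family as base motif 1
  near$ppm <- (near$ppm + 0.05) / colSums(near$ppm + 0.05)[1]
  panel <- c(base, list(near = near))
  cl <- cluster_motifs(panel, similarity_threshold = 0.8)
  fam <- cl$families
  expect_equal(fam$family[fam$motif_id == "near"],
               fam$family[fam$motif_id == base[[1]]$id])
  expect_true(all(table(fam$family) >= 1))
  expect_error(cluster_motifs(panel["M001"]), ">= 2")
})
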