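sim_sample_sheet <- function(cfg) {
  one <- function(cond) {
    n <- cfg$n_samples_per_condition
    block <- ((seq_len(n) - 1L) %% cfg$n_blocks) + 1L
    rep_in_block <- stats::ave(block, block, FUN = seq_along)
    data.frame(
      sample = sprintf("%s_b%d_r%d", cond, block, rep_in_block),
      condition = cond, replicate = rep_in_block, block = block,
      stringsAsFactors = FALSE)
  }
  rbind(one("CON"), one("IND"))
}

rnb <- function(n, mu, alpha) {
  if (alpha <= 0) return(rpois(n, mu))
  rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate RNA and ATAC count matrices with planted structure
#'
#' Counts are negative binomial around `2^(baseline + block offset +
#' planted effects)` scaled by a per-sample library-size multiplier, so
#' column sums vary and size-factor estimation is non-trivial. Planted
#' effects:
#' * differential genes/peaks gain `+/- de_lfc` (`dar_lfc`) log2 units in
#'   the IND condition;
#' * each bound TF has a per-sample activity latent shared with its target
#'   genes (in the conditions where the edge is active), planting the
#'   TF-target co-expression the network stage relies on;
#' * peaks hosting planted motifs get accessible baselines, and peaks whose
#'   motif is bound gain `bound_peak_lfc` log2 units in the bound condition.
#'
#' @param cfg a [sim_config].
#' @param ref a [make_reference] result (gene/peak tables are used).
#' @param truth a `truth_set` from [plant_motifs_and_truth].
#' @return list with `rna` and `atac` [count_matrix] objects.
#' @export
simulate_counts <- function(cfg, ref, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "truth_set"))
  set.seed(cfg$seed + 2L)
  samples <- sim_sample_sheet(cfg)
  ns <- nrow(samples)
  genes <- ref$genes$gene_id
  peaks <- ref$peaks$peak_id
  rng <- cfg$nb_mean_log_range

  # --- RNA ---
  lmu <- runif(cfg$n_genes, rng[1], rng[2])
  # genes wired into the truth network sit in the expressed tail: planted
  # co-expression is only recoverable for quantifiable transcripts
  net_genes <- union(truth$tfs,
                     unlist(lapply(truth$true_edges, `[[`, "target")))
  ni <- match(intersect(net_genes, genes), genes)
  if (length(ni)) {
    lmu[ni] <- runif(length(ni), mean(rng), rng[2])
  }
  boff <- matrix(rnorm(cfg$n_genes * cfg$n_blocks, 0, cfg$block_sd),
                 nrow = cfg$n_genes)
  boff[, 1] <- 0  # block 1 is the reference cell line
  lib <- runif(ns, cfg$lib_size_range[1], cfg$lib_size_range[2])
  logmu <- matrix(lmu, cfg$n_genes, ns) + boff[, samples$block, drop = FALSE]
  is_ind <- samples$condition == "IND"
  de_i <- match(truth$de_genes$gene_id, genes)
  if (length(de_i)) {
    logmu[de_i, is_ind] <- logmu[de_i, is_ind] + truth$de_genes$lfc
  }
  all_bound <- union(truth$bound_tfs$CON, truth$bound_tfs$IND)
  z <- matrix(rnorm(length(all_bound) * ns), nrow = length(all_bound),
              ncol = ns, dimnames = list(all_bound, samples$sample))
  for (tf in all_bound) {
    act <- cfg$tf_activity_sd * z[tf, ]
    ti <- match(tf, genes)
    logmu[ti, ] <- logmu[ti, ] + act
    for (cond in c("CON", "IND")) {
      if (!(tf %in% truth$bound_tfs[[cond]])) next
      ed <- truth$true_edges[[cond]]
      tg <- setdiff(ed$target[ed$tf == tf], tf)
      gi <- match(tg, genes)
      jc <- which(samples$condition == cond)
      logmu[gi, jc] <- logmu[gi, jc] +
        rep(act[jc], each = length(gi))
    }
  }
  mu <- sweep(2^logmu, 2, lib, "*")
  rna <- matrix(rnb(length(mu), mu, cfg$nb_dispersion), nrow = cfg$n_genes,
                dimnames = list(genes, samples$sample))

  # --- ATAC ---
  lmu_p <- runif(cfg$n_peaks, rng[1], rng[2])
  hosted <- peaks %in% truth$planted_sites$peak_id
  span <- rng[2] - rng[1]
  lmu_p[hosted] <- rng[2] - 0.4 * span *
    runif(sum(hosted))  # motif-bearing peaks sit in the accessible tail
  boff_p <- matrix(rnorm(cfg$n_peaks * cfg$n_blocks, 0, cfg$block_sd),
                   nrow = cfg$n_peaks)
  boff_p[, 1] <- 0
  lib_p <- runif(ns, cfg$lib_size_range[1], cfg$lib_size_range[2])
  logmu_p <- matrix(lmu_p, cfg$n_peaks, ns) +
    boff_p[, samples$block, drop = FALSE]
  dar_i <- match(truth$dars$peak_id, peaks)
  if (length(dar_i)) {
    logmu_p[dar_i, is_ind] <- logmu_p[dar_i, is_ind] + truth$dars$lfc
  }
  for (cond in c("CON", "IND")) {
    bm <- truth$bound_motifs[[cond]]
    bi <- match(unique(bm$peak_id), peaks)
    jc <- which(samples$condition == cond)
    if (length(bi)) logmu_p[bi, jc] <- logmu_p[bi, jc] + cfg$bound_peak_lfc
  }
  mu_p <- sweep(2^logmu_p, 2, lib_p, "*")
  atac <- matrix(rnb(length(mu_p), mu_p, cfg$nb_dispersion),
                 nrow = cfg$n_peaks,
                 dimnames = list(peaks, samples$sample))
  storage.mode(rna) <- "integer"
  storage.mode(atac) <- "integer"

  list(rna = count_matrix(rna, samples),
       atac = count_matrix(atac, samples))
}
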