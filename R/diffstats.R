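#' Median-of-ratios size factors
#'
#' DESeq-style normalization: each sample's factor is the median, over
#' features whose geometric mean across samples is nonzero, of the ratio
#' count / geometric mean. Factors are rescaled to have geometric mean 1.
#' If no feature is expressed in every sample, falls back to library-size
#' ratios (column sum / geometric-mean column sum) with a warning.
#'
#' @param cm a [count_matrix] (or a plain counts matrix).
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (any(colSums(counts) == 0)) {
    stop("every sample needs at least one nonzero count", call. = FALSE)
  }
  loggeo <- rowMeans(log(counts))
  ok <- is.finite(loggeo)
  if (!any(ok)) {
    warning("no feature expressed in all samples; ",
            "falling back to library-size ratios")
    sf <- colSums(counts)
  } else {
    sf <- apply(counts, 2, function(x) {
      median(exp(log(x[ok]) - loggeo[ok]))
    })
  }
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Method-of-moments NB dispersion per feature
#'
#' On normalized counts, pools samples within each condition and estimates
#' `alpha = (s^2 - m) / m^2` per condition, then averages across conditions
#' and truncates at zero. Features with zero mean get dispersion 0.
#'
#' @param cm a [count_matrix].
#' @param sf size factors from [size_factors] (recomputed when missing).
#' @return numeric vector of dispersions (>= 0), one per feature.
#' @export
nb_dispersion <- function(cm, sf = size_factors(cm)) {
  stopifnot(inherits(cm, "count_matrix"))
  norm <- sweep(cm$counts, 2, sf, "/")
  conds <- unique(cm$samples$condition)
  per_cond <- vapply(conds, function(cc) {
    x <- norm[, cm$samples$condition == cc, drop = FALSE]
    m <- rowMeans(x)
    v <- apply(x, 1, var)
    a <- (v - m) / m^2
    a[!is.finite(a)] <- 0
    a
  }, numeric(nrow(norm)))
  alpha <- rowMeans(as.matrix(per_cond))
  pmax(alpha, 0)
}

#' Blocked NB Wald test for two-condition differential counts
#'
#' Within each block (cell-line stratum), computes the log2 ratio of
#' normalized condition means (IND vs CON) with a 0.5 pseudo-count, and a
#' delta-method standard error from the NB variance `mu + alpha * mu^2` of
#' the per-sample normalized counts. Blocks are combined by inverse-variance
#' weighting; the Wald statistic gets a two-sided normal p-value;
#' Benjamini-Hochberg adjusts across features. A feature is called `up` when
#' `log2fc > lfc_threshold` and `padj < alpha`, `down` symmetrically, else
#' `ns`. Features at zero in every usable sample get log2fc 0 and p 1.
#'
#' @param cm a [count_matrix] with two conditions.
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param lfc_threshold absolute log2FC threshold (default 1).
#' @param dispersion optional per-feature dispersions (default
#'   [nb_dispersion]).
#' @return data.frame with columns feature, log2fc, se, pvalue, padj, status.
#' @export
diff_test <- function(cm, alpha = 0.05, lfc_threshold = 1,
                      dispersion = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  conds <- unique(cm$samples$condition)
  if (!all(c("CON", "IND") %in% conds)) {
    stop("diff_test needs both CON and IND samples", call. = FALSE)
  }
  sf <- size_factors(cm)
  if (is.null(dispersion)) dispersion <- nb_dispersion(cm, sf)
  disp <- pmax(dispersion, 1e-8)
  norm <- sweep(cm$counts, 2, sf, "/")
  nfeat <- nrow(norm)

  blocks <- sort(unique(cm$samples$block))
  wsum <- num <- rep(0, nfeat)
  used <- 0L
  for (b in blocks) {
    jc <- which(cm$samples$block == b & cm$samples$condition == "CON")
    ji <- which(cm$samples$block == b & cm$samples$condition == "IND")
    if (!length(jc) || !length(ji)) {
      warning("block ", b, " is missing a condition; dropped")
      next
    }
    used <- used + 1L
    mc <- rowMeans(norm[, jc, drop = FALSE])
    mi <- rowMeans(norm[, ji, drop = FALSE])
    lfc_b <- log2((mi + 0.5) / (mc + 0.5))
    v_b <- (mc + disp * mc^2) / length(jc) / ((mc + 0.5)^2 * log(2)^2) +
      (mi + disp * mi^2) / length(ji) / ((mi + 0.5)^2 * log(2)^2)
    v_b <- pmax(v_b, 1e-12)
    w <- 1 / v_b
    num <- num + w * lfc_b
    wsum <- wsum + w
  }
  if (used == 0L) stop("no block contains both conditions", call. = FALSE)

  log2fc <- num / wsum
  se <- sqrt(1 / wsum)
  z <- log2fc / se
  pvalue <- 2 * pnorm(-abs(z))

  # features with no signal anywhere: defined, not NA
  allzero <- rowSums(cm$counts) == 0
  log2fc[allzero] <- 0
  pvalue[allzero] <- 1
  pvalue[!is.finite(pvalue)] <- 1

  padj <- p.adjust(pvalue, method = "BH")
  feat <- rownames(cm$counts)
  if (is.null(feat)) feat <- sprintf("f%05d", seq_len(nfeat))
  status <- rep("ns", nfeat)
  status[log2fc > lfc_threshold & padj < alpha] <- "up"
  status[log2fc < -lfc_threshold & padj < alpha] <- "down"
  data.frame(feature = feat, log2fc = log2fc, se = se,
             pvalue = pvalue, padj = padj, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tabulate differential-call status with percentages
#'
#' @param diff a [diff_test] result (or any table with a `status` column).
#' @return data.frame with status, n, pct (percentage of the called
#'   features, i.e. of up + down).
#' @export
diff_summary <- function(diff) {
  n_up <- sum(diff$status == "up")
  n_down <- sum(diff$status == "down")
  n_ns <- sum(diff$status == "ns")
  called <- n_up + n_down
  data.frame(
    status = c("up", "down", "ns"),
    n = c(n_up, n_down, n_ns),
    pct = c(if (called > 0) 100 * c(n_up, n_down) / called else c(NA, NA),
            NA),
    stringsAsFactors = FALSE)
}
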