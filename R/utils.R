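#' @importFrom stats rnbinom rpois rnorm runif median var cor p.adjust pnorm
#'   fisher.test hclust cutree as.dist setNames quantile sd ave
#' @importFrom utils read.table write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (positive && x <= 0)) {
    stop(sprintf("'%s' must be a single %s number", name,
                 if (positive) "positive" else "finite"), call. = FALSE)
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a fraction in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

#' Convert a 0-based half-open peak table to GRanges
#'
#' Peaks are carried as BED-dialect data frames (0-based, half-open).
#' Bioconductor ranges are 1-based inclusive, so start shifts by +1.
#'
#' @param peaks data.frame with columns chrom, start, end (and optionally
#'   peak_id, summit).
#' @return A [GenomicRanges::GRanges] with peak ids as names when present.
#' @export
peaks_to_granges <- function(peaks) {
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  if (!is.null(peaks$peak_id)) names(gr) <- peaks$peak_id
  gr
}

#' Summit position of each peak
#'
#' Returns the recorded summit, falling back to the interval midpoint
#' (0-based coordinate of the summit base).
#'
#' @param peaks peak data.frame (chrom, start, end, optional summit).
#' @return integer vector of 0-based summit positions.
#' @export
peak_summits <- function(peaks) {
  s <- peaks$summit
  mid <- as.integer(floor((peaks$start + peaks$end) / 2))
  if (is.null(s)) return(mid)
  s <- as.integer(s)
  s[is.na(s)] <- mid[is.na(s)]
  s
}

#' Counts-with-metadata container
#'
#' A minimal features-by-samples container: an integer count matrix plus a
#' sample sheet with the condition ("CON"/"IND"), replicate, and block
#' (cell-line stratum) of every column.
#'
#' @param counts numeric matrix, features x samples, non-negative.
#' @param samples data.frame with columns sample, condition, replicate, block;
#'   one row per column of `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  req <- c("sample", "condition", "replicate", "block")
  if (!all(req %in% names(samples))) {
    stop("sample sheet needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(samples) != ncol(counts)) {
    stop("sample sheet rows must match count columns", call. = FALSE)
  }
  if (anyNA(samples$condition) || anyNA(samples$block)) {
    stop("every sample needs condition and block labels", call. = FALSE)
  }
  tab <- table(samples$condition)
  if (any(tab < 2)) {
    stop("need >= 2 samples per condition", call. = FALSE)
  }
  colnames(counts) <- samples$sample
  structure(list(counts = counts, samples = as.data.frame(samples)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$samples$condition)),
                            table(x$samples$condition)), collapse = ", ")))
  invisible(x)
}

#' Subset a count matrix to one condition
#'
#' @param cm a [count_matrix].
#' @param condition condition label to keep.
#' @return a `count_matrix` restricted to the matching samples.
#' @export
subset_condition <- function(cm, condition) {
  keep <- cm$samples$condition == condition
  if (!any(keep)) stop("no samples in condition ", condition, call. = FALSE)
  structure(list(counts = cm$counts[, keep, drop = FALSE],
                 samples = cm$samples[keep, , drop = FALSE]),
            class = "count_matrix")
}
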