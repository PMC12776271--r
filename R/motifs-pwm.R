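DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from a count matrix
#'
#' Converts a 4 x w position frequency matrix (PFM, base counts per motif
#' position) into a probability matrix and a log2-odds scoring matrix.
#' Probabilities use a background-weighted pseudocount:
#' `p = (count + pseudocount * bg) / (colsum + pseudocount)`, and
#' `log_odds = log2(p / bg)`.
#'
#' @param pfm numeric 4 x w matrix of non-negative counts, rows A/C/G/T.
#' @param pseudocount total pseudocount spread over bases by `background`.
#' @param background length-4 base frequencies (default uniform).
#' @param id motif identifier.
#' @param name optional motif name (JASPAR second field).
#' @return An object of class `pwm`: list with `id`, `name`, `ppm`, `bg`,
#'   `lo` (log2-odds), `pseudocount`.
#' @export
build_pwm <- function(pfm, pseudocount = 0.8, background = rep(0.25, 4),
                      id = "motif", name = id) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4L) stop("PFM must have 4 rows (A, C, G, T)", call. = FALSE)
  if (ncol(pfm) < 4L) stop("motif width must be >= 4", call. = FALSE)
  if (any(pfm < 0)) stop("PFM counts must be >= 0", call. = FALSE)
  cs <- colSums(pfm)
  if (any(cs <= 0)) stop("PFM has a zero-sum column", call. = FALSE)
  bg <- background / sum(background)
  ppm <- sweep(pfm + pseudocount * bg, 2, cs + pseudocount, "/")
  rownames(ppm) <- DNA_BASES
  lo <- log2(ppm / bg)
  structure(list(id = id, name = name, ppm = ppm, bg = bg, lo = lo,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s), width %d, consensus %s\n",
              x$id, x$name, ncol(x$ppm), pwm_consensus(x)))
  invisible(x)
}

#' Maximum-probability (consensus) sequence of a PWM
#'
#' @param pwm a [build_pwm] object.
#' @return single consensus string.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$ppm, 2, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#'
#' @param pwm a [build_pwm] object.
#' @return a `pwm` scoring the reverse strand.
#' @export
pwm_revcomp <- function(pwm) {
  flip <- function(m) {
    m <- m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
    rownames(m) <- DNA_BASES
    m
  }
  structure(list(id = pwm$id, name = pwm$name, ppm = flip(pwm$ppm),
                 bg = rev(pwm$bg), lo = flip(pwm$lo),
                 pseudocount = pwm$pseudocount),
            class = "pwm")
}

#' Read position frequency matrices in JASPAR text format
#'
#' Parses the standard JASPAR layout: a `>ID NAME` header followed by four
#' lines `A [ 1 2 3 ]` (brackets optional).
#'
#' @param path file path.
#' @param pseudocount,background passed to [build_pwm].
#' @return named list of `pwm` objects (names = motif ids).
#' @export
read_jaspar <- function(path, pseudocount = 0.8, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no JASPAR records in ", path, call. = FALSE)
  out <- lapply(seq_along(hdr), function(i) {
    from <- hdr[i]
    to <- if (i < length(hdr)) hdr[i + 1] - 1L else length(lines)
    fields <- strsplit(sub("^>", "", lines[from]), "\\s+")[[1]]
    id <- fields[1]
    name <- if (length(fields) > 1) fields[2] else id
    body <- lines[(from + 1L):to]
    rows <- lapply(DNA_BASES, function(b) {
      ln <- body[grepl(paste0("^\\s*", b, "\\b"), body)]
      if (length(ln) != 1) stop("malformed JASPAR record ", id, call. = FALSE)
      nums <- regmatches(ln, gregexpr("[0-9]+\\.?[0-9]*", ln))[[1]]
      as.numeric(nums)
    })
    pfm <- do.call(rbind, rows)
    p <- build_pwm(pfm, pseudocount = pseudocount, background = background,
                   id = id, name = name)
    attr(p, "pfm") <- pfm
    p
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Write PWMs (their PFM counts) in JASPAR text format
#'
#' Writes the integer-rounded count matrix that [build_pwm] was given,
#' reconstructed as `ppm * 100` when counts are unavailable; for motifs made
#' by [random_pwms] and [read_jaspar] the stored counts round-trip exactly.
#'
#' @param pwms named list of `pwm` objects (or a single `pwm`).
#' @param path output file path.
#' @export
write_jaspar <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    counts <- attr(p, "pfm")
    if (is.null(counts)) {
      # undo the pseudocount so build_pwm(read(write(x))) == x
      counts <- sweep(p$ppm, 2, 100 + p$pseudocount, "*") -
        p$pseudocount * p$bg
    }
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in seq_len(4)) {
      writeLines(sprintf("%s [ %s ]", DNA_BASES[b],
                         paste(format(counts[b, ], trim = TRUE,
                                      scientific = FALSE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Generate sharp synthetic PFMs
#'
#' Each column puts `dominant` counts on one seeded random base and
#' `(total - dominant) / 3` on the others. Sharp columns make the 70%
#' match threshold selective, so planted consensus sites dominate scan hits.
#'
#' @param n number of motifs.
#' @param width motif width in bp.
#' @param dominant count of the preferred base per column.
#' @param total total count per column.
#' @param seed integer seed.
#' @param prefix id prefix.
#' @return named list of `pwm` objects with the PFM attached as attribute.
#' @export
random_pwms <- function(n, width = 18L, dominant = 94, total = 100,
                        seed = 1L, prefix = "M") {
  set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    dom <- sample.int(4, width, replace = TRUE)
    pfm <- matrix((total - dominant) / 3, nrow = 4, ncol = width)
    pfm[cbind(dom, seq_len(width))] <- dominant
    p <- build_pwm(pfm, id = sprintf("%s%03d", prefix, i))
    attr(p, "pfm") <- pfm
    p
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}
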