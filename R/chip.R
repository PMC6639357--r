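#' Binned, CPM-scaled coverage track from ChIP alignments
#'
#' Filters reads to MAPQ >= `mapq_min` with a unique best alignment
#' (NH tag = 1 when present), computes full-span per-base coverage, and
#' averages it in fixed-width bins, scaled to counts per million filtered
#' reads: each bin holds `mean per-base coverage in bin * 1e6 / n_reads`.
#'
#' @param sam_path SAM file (single-end or paired; records are used
#'   individually).
#' @param bin_bp Bin width in bp (default 10).
#' @param mapq_min Minimum MAPQ (default 10).
#' @return `signal_track` object: list `values` (per-chromosome numeric
#'   vectors of bin values), `bin_bp`, `normalization`, `n_reads`,
#'   `seqlengths`.
#' @export
coverage_track <- function(sam_path, bin_bp = 10L, mapq_min = 10L) {
  ga <- read_sam_alignments(sam_path)
  nh <- S4Vectors::mcols(ga)$NH
  keep <- S4Vectors::mcols(ga)$mapq >= mapq_min
  if (!is.null(nh)) keep <- keep & (is.na(nh) | nh == 1L)
  ga <- ga[keep]
  n_reads <- length(ga)
  sl <- GenomeInfoDb::seqlengths(ga)
  if (any(is.na(sl)))
    stop("SAM header must carry @SQ lengths")
  cov <- GenomicAlignments::coverage(ga)
  values <- lapply(names(sl), function(chr) {
    v <- as.numeric(cov[[chr]])
    length(v) <- sl[[chr]]                 # pad with NA then zero-fill
    v[is.na(v)] <- 0
    nb <- ceiling(sl[[chr]] / bin_bp)
    idx <- rep(seq_len(nb), each = bin_bp, length.out = sl[[chr]])
    bw <- tabulate(idx, nbins = nb)
    as.numeric(rowsum(v, idx) / bw) * (1e6 / max(n_reads, 1L))
  })
  names(values) <- names(sl)
  structure(list(values = values, bin_bp = as.integer(bin_bp),
                 normalization = "raw-coverage", n_reads = n_reads,
                 seqlengths = sl),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", length(x$values), "chromosomes, bin",
      x$bin_bp, "bp,", x$normalization, ",", x$n_reads, "reads\n")
  invisible(x)
}

#' Combine signal tracks
#'
#' `replicate-mean`: element-wise mean of any number of identically
#' binned tracks. `log2-ratio`: `log2((IP + eps) / (input + eps))` for
#' exactly two tracks (IP first), with pseudocount `eps` guarding zeros.
#'
#' @param tracks List of `signal_track` objects with identical binning.
#' @param mode `"replicate-mean"` or `"log2-ratio"`.
#' @param pseudocount Pseudocount for the log2 ratio (default 1, in
#'   CPM-scaled units).
#' @return A combined `signal_track`.
#' @export
combine_tracks <- function(tracks, mode = c("replicate-mean", "log2-ratio"),
                           pseudocount = 1) {
  mode <- match.arg(mode)
  stopifnot(length(tracks) >= 2)
  b <- vapply(tracks, function(t) t$bin_bp, integer(1))
  if (length(unique(b)) != 1)
    stop("tracks have mismatched bin widths")
  chroms <- names(tracks[[1]]$values)
  for (t in tracks)
    if (!identical(names(t$values), chroms) ||
        !identical(lengths(t$values), lengths(tracks[[1]]$values)))
      stop("tracks have mismatched binning")
  values <- lapply(chroms, function(chr) {
    mat <- do.call(cbind, lapply(tracks, function(t) t$values[[chr]]))
    if (mode == "replicate-mean") rowMeans(mat)
    else {
      stopifnot(ncol(mat) == 2)
      log2((mat[, 1] + pseudocount) / (mat[, 2] + pseudocount))
    }
  })
  names(values) <- chroms
  out <- tracks[[1]]
  out$values <- values
  out$normalization <- if (mode == "replicate-mean") "replicate-mean"
                       else "log2-ratio"
  out$n_reads <- NA_integer_
  out
}

#' Element-anchored scaled-body heatmap matrix
#'
#' Builds a matrix with one row per element: `flank_bins` fixed-width
#' bins over the 5' flank, `body_bins` bins over the element body
#' rescaled to constant length (proportional-window averaging), and
#' `flank_bins` bins over the 3' flank. Rows for minus-strand elements
#' are reversed so the element 5' end is always on the left. Elements
#' shorter than `body_bins` bases are flagged and their body profile
#' linearly interpolated.
#'
#' @param track A `signal_track`.
#' @param elements `GRanges` with strand and `element_id`.
#' @param body_bins Number of bins over the scaled body (default 60).
#' @param flank_bp Flank width in bp (default 1000).
#' @param flank_bins Number of bins per flank (default 10).
#' @return Numeric matrix (rows = elements, in input order; rownames =
#'   element ids) with attribute `short_rows` (logical vector flagging
#'   interpolated rows) and `column_type` (`"flank5"`, `"body"`,
#'   `"flank3"`).
#' @export
element_heatmap <- function(track, elements, body_bins = 60L,
                            flank_bp = 1000L, flank_bins = 10L) {
  stopifnot(inherits(track, "signal_track"))
  per_base <- lapply(names(track$values), function(chr) {
    rep(track$values[[chr]], each = track$bin_bp)[
      seq_len(track$seqlengths[[chr]])]
  })
  names(per_base) <- names(track$values)

  win_means <- function(v, breaks) {
    # breaks: numeric vector length nb+1 over [lo-1, hi] genome coords
    nb <- length(breaks) - 1L
    out <- numeric(nb)
    for (b in seq_len(nb)) {
      lo <- floor(breaks[b]) + 1L
      hi <- ceiling(breaks[b + 1L])
      lo2 <- max(lo, 1L); hi2 <- min(hi, length(v))
      out[b] <- if (lo2 > hi2) NA_real_ else mean(v[lo2:hi2])
    }
    out
  }

  n <- length(elements)
  ncols <- 2L * flank_bins + body_bins
  mat <- matrix(NA_real_, nrow = n, ncol = ncols)
  short <- logical(n)
  st <- GenomicRanges::start(elements)
  en <- GenomicRanges::end(elements)
  chr <- as.character(GenomicRanges::seqnames(elements))
  strand_el <- as.character(GenomicRanges::strand(elements))
  fw <- flank_bp / flank_bins
  for (i in seq_len(n)) {
    v <- per_base[[chr[i]]]
    if (is.null(v)) next
    left <- win_means(v, st[i] - 1L - flank_bp + fw * (0:flank_bins))
    width_i <- en[i] - st[i] + 1L
    if (width_i < body_bins) {
      short[i] <- TRUE
      body_raw <- v[max(st[i], 1L):min(en[i], length(v))]
      body <- stats::approx(seq_along(body_raw), body_raw,
                            xout = seq(1, length(body_raw),
                                       length.out = body_bins))$y
    } else {
      body <- win_means(v, seq(st[i] - 1L, en[i], length.out = body_bins + 1L))
    }
    right <- win_means(v, en[i] + fw * (0:flank_bins))
    row <- c(left, body, right)
    if (strand_el[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  rownames(mat) <- if (!is.null(elements$element_id)) elements$element_id
                   else as.character(seq_len(n))
  attr(mat, "short_rows") <- short
  attr(mat, "column_type") <- c(rep("flank5", flank_bins),
                                rep("body", body_bins),
                                rep("flank3", flank_bins))
  mat
}
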