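#' Load paired-end fragments from a SAM file
#'
#' Converts SAM to BAM in a temporary directory (via [Rsamtools::asBam])
#' and pairs primary alignment records by query name. One fragment is
#' produced per properly paired template; secondary and supplementary
#' records are ignored and orphan mates are counted and skipped. The
#' fragment strand is inferred from the library protocol: for a
#' dUTP/TruSeq reverse-stranded library the fragment (transcript) strand
#' is the opposite of mate 1's alignment strand.
#'
#' A fragment is flagged `unique` iff both mates are primary and carry
#' `NH:i:1` when the NH tag is present, falling back to `MAPQ >=
#' mapq_min` when it is not.
#'
#' @param sam_path Path to a SAM file with an `@SQ` header.
#' @param protocol `"reverse-stranded"` (default, dUTP), `"forward-stranded"`
#'   or `"unstranded"`.
#' @param mapq_min MAPQ fallback threshold for uniqueness (default 10).
#' @return An object of class `read_fragments`: list with `meta`
#'   (data.frame `qname`, `chrom`, `fragment_strand`, `unique`, `mapq`),
#'   `blocks` (GRangesList of the union of both mates' aligned blocks per
#'   fragment), `mate_blocks` (list of two GRangesLists, per-mate blocks,
#'   CIGAR-N-split), `protocol`, and `n_orphans`.
#' @export
load_fragments <- function(sam_path,
                           protocol = c("reverse-stranded",
                                        "forward-stranded", "unstranded"),
                           mapq_min = 10L) {
  protocol <- match.arg(protocol)
  ga <- read_sam_alignments(sam_path)
  fl <- S4Vectors::mcols(ga)$flag
  paired <- bitwAnd(fl, 1L) > 0L
  ga <- ga[paired]
  fl <- S4Vectors::mcols(ga)$flag
  is_first <- bitwAnd(fl, 64L) > 0L

  qn <- S4Vectors::mcols(ga)$qname
  ord1 <- which(is_first)[order(qn[is_first])]
  ord2 <- which(!is_first)[order(qn[!is_first])]
  q1 <- qn[ord1]; q2 <- qn[ord2]
  common <- intersect(q1, q2)
  n_orphans <- (length(q1) - length(common)) + (length(q2) - length(common))
  if (n_orphans > 0)
    message(n_orphans, " orphan mate records skipped")
  i1 <- ord1[match(common, q1)]
  i2 <- ord2[match(common, q2)]

  strand1 <- as.character(GenomicAlignments::strand(ga))[i1]
  frag_strand <- switch(protocol,
    "forward-stranded" = strand1,
    "reverse-stranded" = ifelse(strand1 == "+", "-", "+"),
    "unstranded" = rep("*", length(i1)))
  nh <- S4Vectors::mcols(ga)$NH
  mq <- S4Vectors::mcols(ga)$mapq
  uniq_rec <- if (is.null(nh)) rep(NA, length(ga)) else nh == 1L
  uniq_rec[is.na(uniq_rec)] <- (mq >= mapq_min)[is.na(uniq_rec)]
  unique_frag <- uniq_rec[i1] & uniq_rec[i2]

  b1 <- GenomicAlignments::grglist(ga[i1])
  b2 <- GenomicAlignments::grglist(ga[i2])
  names(b1) <- names(b2) <- NULL
  all_blocks <- GenomicRanges::reduce(S4Vectors::pc(b1, b2),
                                      ignore.strand = TRUE)
  meta <- data.frame(
    qname = common,
    chrom = as.character(GenomicAlignments::seqnames(ga))[i1],
    fragment_strand = frag_strand,
    unique = unique_frag,
    mapq = pmin(mq[i1], mq[i2]),
    stringsAsFactors = FALSE
  )
  structure(list(meta = meta, blocks = all_blocks,
                 mate_blocks = list(b1, b2),
                 protocol = protocol, n_orphans = n_orphans),
            class = "read_fragments")
}

#' @export
print.read_fragments <- function(x, ...) {
  cat("read_fragments:", nrow(x$meta), "fragments (",
      sum(x$meta$unique), "unique ),", x$n_orphans, "orphans, protocol",
      x$protocol, "\n")
  invisible(x)
}

# SAM -> GAlignments with qname/flag/mapq/NH, primary records only.
read_sam_alignments <- function(sam_path) {
  stopifnot(file.exists(sam_path))
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE))
  GenomicAlignments::readGAlignments(bam, param = param)
}

# Per-fragment feature assignment by largest block overlap.
# features: GRanges with feature_id metadata column. Returns a
# data.frame(frag = fragment index, feature_id) with one row per assigned
# fragment. mode "largest-overlap" breaks ties toward the
# lower-coordinate feature; "discard-ambiguous" drops fragments touching
# more than one feature (featureCounts-like).
assign_fragments <- function(blocks, features,
                             mode = c("largest-overlap", "discard-ambiguous")) {
  mode <- match.arg(mode)
  stopifnot(!is.null(features$feature_id))
  ub <- unlist(blocks, use.names = FALSE)
  frag_of_block <- rep(seq_along(blocks), lengths(blocks))
  hits <- GenomicRanges::findOverlaps(ub, features, ignore.strand = TRUE)
  if (length(hits) == 0)
    return(data.frame(frag = integer(), feature_id = character(),
                      stringsAsFactors = FALSE))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov_w <- IRanges::width(IRanges::pintersect(IRanges::ranges(ub)[q],
                                             IRanges::ranges(features)[s]))
  dt <- data.table::data.table(
    frag = frag_of_block[q],
    fid = features$feature_id[s],
    fstart = GenomicRanges::start(features)[s],
    w = ov_w)
  per <- dt[, list(w = sum(w), fstart = fstart[1]), by = c("frag", "fid")]
  if (mode == "discard-ambiguous") {
    nfeat <- per[, list(n = .N), by = "frag"]
    per <- per[per$frag %in% nfeat$frag[nfeat$n == 1L], ]
    return(data.frame(frag = per$frag, feature_id = per$fid,
                      stringsAsFactors = FALSE))
  }
  data.table::setorderv(per, c("frag", "w", "fstart"), order = c(1L, -1L, 1L))
  best <- per[!duplicated(per$frag), ]
  data.frame(frag = best$frag, feature_id = best$fid,
             stringsAsFactors = FALSE)
}
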