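#' Call indels across a CRISPR target site from amplicon alignments
#'
#' Scans each primary aligned read for CIGAR insertions/deletions
#' intersecting the flanked target window `cut_pos +/- flank_bp`
#' (1-based, closed). Reads whose aligned reference span does not cover
#' the whole window (i.e. fewer than `flank_bp` aligned bases on each
#' side of the cut) are uninformative and excluded from the denominator.
#' Multiple window-overlapping operations on one read are collapsed into
#' a single complex event keyed by the full local alternative haplotype.
#' Reads with no window-overlapping indel are unmodified (substitutions
#' do not count as modification).
#'
#' @param sam_path SAM of reads aligned to the amplicon reference.
#' @param cut_pos 1-based reference position of the expected cut site.
#' @param flank_bp Window half-width in bp (default 10).
#' @param reference Amplicon reference sequence (character or
#'   [Biostrings::DNAString]).
#' @return list: `events` (data.frame `query_id`, `kind`, `pos` 1-based,
#'   `ref_allele`, `alt_allele`, `net_length`; one row per modified
#'   read), `n_informative`, `n_unmodified`, `n_uninformative`.
#' @export
call_read_indels <- function(sam_path, cut_pos, flank_bp = 10L, reference) {
  reference <- as.character(reference)
  win_lo <- cut_pos - flank_bp
  win_hi <- cut_pos + flank_bp
  stopifnot(win_lo >= 1, win_hi <= nchar(reference))

  bam <- Rsamtools::asBam(sam_path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = TRUE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "pos", "cigar", "seq", "flag"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)))[[1]]
  n <- length(res$qname)
  ops_all <- GenomicAlignments::explodeCigarOps(res$cigar)
  len_all <- GenomicAlignments::explodeCigarOpLengths(res$cigar)
  seqs <- as.character(res$seq)

  rows <- vector("list", n)
  n_informative <- 0L
  n_unmodified <- 0L
  n_uninformative <- 0L
  for (i in seq_len(n)) {
    ops <- ops_all[[i]]; lens <- len_all[[i]]
    rpos <- res$pos[i]          # next reference base (1-based)
    qpos <- 1L                  # next read base
    ref_end <- rpos + sum(lens[ops %in% c("M", "D", "N", "=", "X")]) - 1L
    if (rpos > win_lo || ref_end < win_hi) {
      n_uninformative <- n_uninformative + 1L
      next
    }
    n_informative <- n_informative + 1L
    evs <- list()
    for (k in seq_along(ops)) {
      op <- ops[k]; L <- lens[k]
      if (op %in% c("M", "=", "X")) {
        rpos <- rpos + L; qpos <- qpos + L
      } else if (op == "D" || op == "N") {
        if (op == "D" && rpos <= win_hi && rpos + L - 1L >= win_lo)
          evs[[length(evs) + 1L]] <- list(kind = "deletion", pos = rpos,
                                          ref = substr(reference, rpos,
                                                       rpos + L - 1L),
                                          alt = "")
        rpos <- rpos + L
      } else if (op == "I") {
        anchor <- rpos - 1L      # inserted after this reference base
        if (anchor >= win_lo - 1L && anchor <= win_hi)
          evs[[length(evs) + 1L]] <- list(kind = "insertion", pos = rpos,
                                          ref = "",
                                          alt = substr(seqs[i], qpos,
                                                       qpos + L - 1L))
        qpos <- qpos + L
      } else if (op == "S") {
        qpos <- qpos + L
      } # H/P consume nothing relevant
    }
    if (length(evs) == 0) {
      n_unmodified <- n_unmodified + 1L
      next
    }
    if (length(evs) == 1) {
      e <- evs[[1]]
      rows[[i]] <- data.frame(query_id = res$qname[i], kind = e$kind,
                              pos = e$pos, ref_allele = e$ref,
                              alt_allele = e$alt,
                              net_length = nchar(e$alt) - nchar(e$ref),
                              stringsAsFactors = FALSE)
    } else {
      # complex: local haplotype from first to last affected ref base
      lo <- min(vapply(evs, function(e)
        if (e$kind == "insertion") e$pos - 1L else e$pos, integer(1)))
      hi <- max(vapply(evs, function(e)
        if (e$kind == "insertion") e$pos - 1L
        else e$pos + nchar(e$ref) - 1L, integer(1)))
      lo <- max(lo, 1L)
      alt <- read_local_haplotype(ops, lens, res$pos[i], seqs[i], lo, hi)
      ref <- substr(reference, lo, hi)
      rows[[i]] <- data.frame(query_id = res$qname[i], kind = "complex",
                              pos = lo, ref_allele = ref, alt_allele = alt,
                              net_length = nchar(alt) - nchar(ref),
                              stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(events))
    events <- data.frame(query_id = character(), kind = character(),
                         pos = integer(), ref_allele = character(),
                         alt_allele = character(), net_length = integer(),
                         stringsAsFactors = FALSE)
  list(events = events, n_informative = n_informative,
       n_unmodified = n_unmodified, n_uninformative = n_uninformative)
}

# Read bases aligned over reference interval [lo, hi], including
# insertions anchored strictly inside, excluding deleted bases.
read_local_haplotype <- function(ops, lens, aln_start, seq, lo, hi) {
  rpos <- aln_start; qpos <- 1L
  out <- character(0)
  for (k in seq_along(ops)) {
    op <- ops[k]; L <- lens[k]
    if (op %in% c("M", "=", "X")) {
      o_lo <- max(rpos, lo); o_hi <- min(rpos + L - 1L, hi)
      if (o_lo <= o_hi)
        out <- c(out, substr(seq, qpos + (o_lo - rpos),
                             qpos + (o_hi - rpos)))
      rpos <- rpos + L; qpos <- qpos + L
    } else if (op == "D" || op == "N") {
      rpos <- rpos + L
    } else if (op == "I") {
      if (rpos - 1L >= lo && rpos - 1L < hi + 1L && rpos > lo)
        out <- c(out, substr(seq, qpos, qpos + L - 1L))
      qpos <- qpos + L
    } else if (op == "S") {
      qpos <- qpos + L
    }
  }
  paste(out, collapse = "")
}

#' Left-align an indel event to its canonical representation
#'
#' Trims shared prefix/suffix bases and shifts pure insertions/deletions
#' left through repeat context until no equivalent representation with a
#' smaller position exists, so that identical variants compare equal.
#' Idempotent.
#'
#' @param pos 1-based reference position of the event (first deleted base
#'   for deletions; for insertions, the reference base before which the
#'   sequence is inserted).
#' @param ref_allele,alt_allele Event alleles (either may be `""`).
#' @param reference Amplicon reference sequence.
#' @return list `pos`, `ref_allele`, `alt_allele`, `kind`, `net_length`.
#' @export
canonicalize_indel <- function(pos, ref_allele, alt_allele, reference) {
  reference <- as.character(reference)
  ref <- ref_allele; alt <- alt_allele
  if (nchar(ref) > 0 &&
      substr(reference, pos, pos + nchar(ref) - 1L) != ref)
    stop("event inconsistent with reference at position ", pos)
  # trim common suffix
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # trim common prefix
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  # left-shift pure indels through repeat context
  if (xor(nchar(ref) == 0, nchar(alt) == 0)) {
    ins <- nchar(ref) == 0
    s <- if (ins) alt else ref
    while (pos > 1L) {
      prev <- substr(reference, pos - 1L, pos - 1L)
      if (prev != substr(s, nchar(s), nchar(s))) break
      s <- paste0(prev, substr(s, 1L, nchar(s) - 1L))
      pos <- pos - 1L
    }
    if (ins) alt <- s else ref <- s
  }
  net <- nchar(alt) - nchar(ref)
  kind <- if (nchar(ref) == 0 && nchar(alt) > 0) "insertion"
          else if (nchar(alt) == 0 && nchar(ref) > 0) "deletion"
          else "complex"
  list(pos = pos, ref_allele = ref, alt_allele = alt, kind = kind,
       net_length = net)
}

# Vectorised canonicalization over an events data.frame.
canonicalize_events <- function(events, reference) {
  if (nrow(events) == 0) return(events)
  for (i in seq_len(nrow(events))) {
    cn <- canonicalize_indel(events$pos[i], events$ref_allele[i],
                             events$alt_allele[i], reference)
    events$pos[i] <- cn$pos
    events$ref_allele[i] <- cn$ref_allele
    events$alt_allele[i] <- cn$alt_allele
    events$kind[i] <- cn$kind
    events$net_length[i] <- cn$net_length
  }
  events
}

#' Tally unique indels and summarise editing
#'
#' Canonicalizes per-read events, groups them by (position, ref, alt),
#' and reports each unique indel's read count, relative frequency (over
#' informative reads) and frame class: in-frame iff the net length change
#' is a multiple of 3, frameshift otherwise (complex events use the
#' summed net length).
#'
#' @param calls List from [call_read_indels()].
#' @param reference Amplicon reference sequence.
#' @return list: `tally` (data.frame `kind`, `pos`, `ref_allele`,
#'   `alt_allele`, `net_length`, `read_count`, `frequency`,
#'   `frame_class`, sorted by decreasing frequency) and `summary` (list
#'   `total_reads`, `modified_reads`, `pct_modified`,
#'   `n_unique_frameshift`, `n_unique_inframe`).
#' @export
tally_indels <- function(calls, reference) {
  if (calls$n_informative == 0)
    stop("no informative reads covering the target window")
  ev <- canonicalize_events(calls$events, reference)
  if (nrow(ev) > 0) {
    dt <- data.table::data.table(ev)
    tally <- dt[, list(kind = kind[1], net_length = net_length[1],
                       read_count = .N),
                by = c("pos", "ref_allele", "alt_allele")]
    tally$frequency <- tally$read_count / calls$n_informative
    tally$frame_class <- ifelse(tally$net_length %% 3L == 0L,
                                "in-frame", "frameshift")
    data.table::setorderv(tally, c("frequency", "pos"), order = c(-1L, 1L))
    tally <- as.data.frame(tally)[, c("kind", "pos", "ref_allele",
                                      "alt_allele", "net_length",
                                      "read_count", "frequency",
                                      "frame_class")]
  } else {
    tally <- data.frame(kind = character(), pos = integer(),
                        ref_allele = character(), alt_allele = character(),
                        net_length = integer(), read_count = integer(),
                        frequency = numeric(), frame_class = character(),
                        stringsAsFactors = FALSE)
  }
  modified <- calls$n_informative - calls$n_unmodified
  summary <- list(
    total_reads = calls$n_informative,
    modified_reads = modified,
    pct_modified = 100 * modified / calls$n_informative,
    n_unique_frameshift = sum(tally$frame_class == "frameshift"),
    n_unique_inframe = sum(tally$frame_class == "in-frame"))
  list(tally = tally, summary = summary)
}
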