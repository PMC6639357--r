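#' Parse a RepeatMasker-derived transposable-element table
#'
#' Reads a BED-like tab-separated table of TE loci with columns
#' `chrom, start, end, strand, subfamily, class, family, divergence`
#' (0-based half-open coordinates, no header) and returns a validated
#' [GenomicRanges::GRanges] of TE fragments. Rows whose repeat class is not
#' one of `LINE`, `SINE`, `LTR`, `SVA` (e.g. DNA transposons, simple
#' repeats) are dropped; the number of dropped rows is recorded in the
#' `n_excluded` attribute and reported via [message()].
#'
#' @param path Path to the TE table.
#' @return A `GRanges` with metadata columns `element_id`, `subfamily`,
#'   `class`, `family`, `divergence_pct`, and attribute `n_excluded`.
#'   Coordinates are 1-based closed (converted from the BED dialect).
#' @export
parse_te_annotation <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "character", "character",
                                         "character", "numeric"),
                          col.names = c("chrom", "start", "end", "strand",
                                        "subfamily", "class", "family",
                                        "divergence"))
  bad <- which(is.na(df$start) | is.na(df$end) | !(df$strand %in% c("+", "-")))
  if (length(bad) > 0)
    stop("malformed TE annotation row at line ", bad[1])
  rev_coord <- which(df$start >= df$end)
  if (length(rev_coord) > 0)
    stop("start >= end in TE annotation at line ", rev_coord[1])
  if (any(df$divergence < 0))
    stop("negative divergence at line ", which(df$divergence < 0)[1])

  keep <- df$class %in% te_classes()
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    message(n_excluded, " TE rows outside classes {",
            paste(te_classes(), collapse = ","), "} excluded")
  df <- df[keep, , drop = FALSE]

  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand,
    element_id = sprintf("%s|%s:%d-%d(%s)", df$subfamily, df$chrom,
                         df$start, df$end, df$strand),
    subfamily = df$subfamily,
    class = df$class,
    family = df$family,
    divergence_pct = df$divergence
  )
  if (anyDuplicated(gr$element_id))
    stop("duplicate element_id in TE annotation")
  attr(gr, "n_excluded") <- n_excluded
  gr
}

te_classes <- function() c("LINE", "SINE", "LTR", "SVA")

#' Parse gene models from a GTF file
#'
#' Imports exon records from a GTF (1-based closed, as emitted by
#' Gencode-style annotation) and assembles per-transcript models with a
#' strand-aware transcription start site.
#'
#' @param path Path to a GTF file with `exon` features carrying `gene_id`
#'   and `transcript_id` attributes; an optional `gene_type`/`gene_biotype`
#'   attribute marks protein-coding transcripts (absent, all transcripts
#'   are assumed coding).
#' @return A list with `transcripts` (data.frame: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `coding`, `tss` 1-based position of the
#'   first transcribed base) and `exons` (`GRanges` with `transcript_id`,
#'   `gene_id` metadata).
#' @export
parse_gene_annotation <- function(path) {
  gtf <- rtracklayer::import(path, format = "gtf")
  ex <- gtf[gtf$type == "exon"]
  if (length(ex) == 0) stop("no exon records in GTF")
  biotype <- if (!is.null(ex$gene_type)) ex$gene_type
             else if (!is.null(ex$gene_biotype)) ex$gene_biotype
             else rep("protein_coding", length(ex))
  exons <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(ex),
    ranges = IRanges::ranges(ex),
    strand = GenomicRanges::strand(ex),
    transcript_id = ex$transcript_id,
    gene_id = ex$gene_id,
    coding = biotype == "protein_coding"
  )
  first <- !duplicated(exons$transcript_id)
  dt <- data.table::data.table(
    transcript_id = exons$transcript_id,
    gene_id = exons$gene_id,
    chrom = as.character(GenomicRanges::seqnames(exons)),
    strand = as.character(GenomicRanges::strand(exons)),
    coding = exons$coding,
    start = GenomicRanges::start(exons),
    end = GenomicRanges::end(exons)
  )
  tx <- dt[, list(gene_id = gene_id[1], chrom = chrom[1], strand = strand[1],
                  coding = coding[1],
                  tss = if (strand[1] == "-") max(end) else min(start)),
           by = "transcript_id"]
  list(transcripts = as.data.frame(tx), exons = exons)
}

#' Classify full-length intact L1s (FLI-L1s)
#'
#' An L1 locus is called FLI-L1 when it is full length (> 6 kb) and its
#' ORF1, ORF2, 5'UTR internal promoter, and 3'UTR are all intact.
#' Intactness is supplied per element (e.g. from [scan_orf_intactness()]
#' or an external curation); elements without flags are treated as not
#' intact and skipped with a warning.
#'
#' @param fragments `GRanges` of TE fragments from [parse_te_annotation()].
#' @param feature_flags data.frame keyed by `element_id` with logical
#'   columns `orf1_intact`, `orf2_intact`, `utr5_intact`, `utr3_intact`.
#' @param min_length_bp Length threshold in bp (exclusive); default 6000.
#' @return data.frame of classified FLI-L1s: `element_id`, `length_bp`,
#'   the four intactness flags.
#' @export
classify_fli_l1 <- function(fragments, feature_flags, min_length_bp = 6000L) {
  flag_cols <- c("orf1_intact", "orf2_intact", "utr5_intact", "utr3_intact")
  stopifnot(all(c("element_id", flag_cols) %in% names(feature_flags)))
  idx <- match(fragments$element_id, feature_flags$element_id)
  missing <- is.na(idx)
  if (any(missing))
    warning(sum(missing), " fragments lack intactness flags; treated as not intact")
  len <- GenomicRanges::width(fragments)
  intact <- rep(FALSE, length(fragments))
  has <- which(!missing)
  if (length(has) > 0) {
    fl <- feature_flags[idx[has], flag_cols, drop = FALSE]
    intact[has] <- Reduce(`&`, lapply(fl, function(x) !is.na(x) & x))
  }
  keep <- len > min_length_bp & intact
  out <- data.frame(
    element_id = fragments$element_id[keep],
    length_bp = len[keep],
    stringsAsFactors = FALSE
  )
  cbind(out, feature_flags[idx[keep], flag_cols, drop = FALSE],
        row.names = NULL)
}

#' Scan element sequences for intact open reading frames
#'
#' Helper that scores ORF1/ORF2 intactness from sequence alone: an ORF is
#' "intact" when some forward reading frame of the element's sense
#' sequence contains a stop-codon-free stretch of at least the configured
#' length. UTR intactness is approximated by requiring the element to
#' retain its terminal sequence (full-length elements only); callers with
#' curated annotation should supply flags directly to [classify_fli_l1()].
#'
#' @param seqs A [Biostrings::DNAStringSet] of element sense-strand
#'   sequences, names = element ids.
#' @param orf1_min,orf2_min Minimum stop-free stretch lengths in bp
#'   (defaults 900 and 3500, the approximate lengths of L1 ORF1/ORF2).
#' @param full_length_bp Minimum element length for the UTRs to be
#'   considered retained (default 6000).
#' @return data.frame with `element_id` and the four intactness flags.
#' @export
scan_orf_intactness <- function(seqs, orf1_min = 900L, orf2_min = 3500L,
                                full_length_bp = 6000L) {
  longest_stop_free <- function(s) {
    n <- nchar(s)
    best <- 0L
    for (frame in 0:2) {
      if (n - frame < 3) next
      codon_starts <- seq.int(1L + frame, n - 2L, by = 3L)
      codons <- substring(s, codon_starts, codon_starts + 2L)
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      run <- rle(!is_stop)
      open <- run$lengths[run$values]
      if (length(open) > 0) best <- max(best, max(open) * 3L)
    }
    best
  }
  s <- as.character(seqs)
  longest <- vapply(s, longest_stop_free, integer(1), USE.NAMES = FALSE)
  full <- nchar(s) >= full_length_bp
  data.frame(
    element_id = names(seqs),
    orf1_intact = longest >= orf1_min,
    orf2_intact = longest >= orf2_min,
    utr5_intact = full,
    utr3_intact = full,
    stringsAsFactors = FALSE
  )
}

#' Annotate TE fragments with subfamily evolutionary age
#'
#' Joins an age table onto TE fragments and flags hominoid-specific L1
#' subfamilies: those younger than 12.5 million years (L1HS, L1PA2, L1PA3
#' under the default table). Subfamilies absent from the table are flagged
#' age-unknown and belong to neither age group.
#'
#' @param fragments `GRanges` of TE fragments.
#' @param age_table data.frame with `subfamily` and `age_my` columns; see
#'   [default_age_table()].
#' @param hominoid_max_my Age cut in million years (strict upper bound,
#'   default 12.5) applied to L1-family subfamilies.
#' @return The input `GRanges` with added metadata columns `age_my`,
#'   `age_known`, `hominoid_specific`.
#' @export
assign_subfamily_ages <- function(fragments, age_table = default_age_table(),
                                  hominoid_max_my = 12.5) {
  stopifnot(all(c("subfamily", "age_my") %in% names(age_table)),
            all(age_table$age_my > 0))
  idx <- match(fragments$subfamily, age_table$subfamily)
  fragments$age_my <- age_table$age_my[idx]
  fragments$age_known <- !is.na(idx)
  fragments$hominoid_specific <- fragments$age_known &
    fragments$family == "L1" &
    !is.na(fragments$age_my) & fragments$age_my < hominoid_max_my
  fragments
}

#' Default subfamily age table
#'
#' Literature-derived placeholder ages (million years) for the subfamilies
#' used by the synthetic-data module plus common real subfamilies. Only
#' the < 12.5 My hominoid-specific cut (placing L1HS, L1PA2 and L1PA3 in
#' the young group) is taken as fixed; individual ages are editable.
#'
#' @return data.frame with columns `subfamily`, `age_my`.
#' @export
default_age_table <- function() {
  data.frame(
    subfamily = c("L1HS", "L1PA2", "L1PA3", "L1PA4", "L1PA5", "L1PA6",
                  "L1PA7", "L1PA8", "L1PA13", "L1MA4", "AluY", "AluSx",
                  "LTR12C", "HERVH-int", "HERVK-int", "SVA_D", "SVA_E"),
    age_my = c(3.1, 7.6, 12.4, 18, 21, 23,
               25, 40, 60, 90, 15, 35,
               35, 35, 30, 9, 4),
    stringsAsFactors = FALSE
  )
}

#' Remove TE fragments overlapping any annotated exon
#'
#' Before quantification, TEs overlapping gene exons are excluded so that
#' exonic reads cannot inflate TE counts. A fragment is removed iff at
#' least one base of it intersects at least one exon of any gene,
#' strand-blind. Intervals touching only at a boundary (half-open
#' adjacency in BED terms) do not overlap.
#'
#' @param fragments `GRanges` of TE fragments.
#' @param exons `GRanges` of exons (e.g. `parse_gene_annotation(path)$exons`),
#'   or the list returned by [parse_gene_annotation()].
#' @return The non-exonic subset of `fragments`.
#' @export
filter_nonexonic <- function(fragments, exons) {
  if (!inherits(exons, "GRanges") && is.list(exons) && !is.null(exons$exons))
    exons <- exons$exons
  hits <- GenomicRanges::findOverlaps(fragments, exons, ignore.strand = TRUE,
                                      minoverlap = 1L)
  fragments[setdiff(seq_along(fragments), unique(S4Vectors::queryHits(hits)))]
}
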