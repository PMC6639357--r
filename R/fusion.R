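#' TE elements overlapping protein-coding transcription start sites
#'
#' Intersects the TSSs of protein-coding transcripts with TE coordinates
#' (typically L1 or LTR12C subfamilies): one promoter candidate per
#' (element, transcript) pair whose TSS base falls inside the element
#' interval. Orientation records whether the TE strand is sense or
#' antisense relative to the gene; for young L1 promoters the antisense
#' configuration (the ORF0 geometry) is the common one.
#'
#' @param genes Output of [parse_gene_annotation()].
#' @param te_set `GRanges` of TE fragments, pre-restricted to the
#'   subfamilies of interest.
#' @return data.frame: `element_id`, `transcript_id`, `gene_id`,
#'   `orientation` (`"sense"`/`"antisense"`).
#' @export
find_te_tss_overlaps <- function(genes, te_set) {
  tx <- genes$transcripts
  tx <- tx[tx$coding, , drop = FALSE]
  if (nrow(tx) == 0)
    return(data.frame(element_id = character(), transcript_id = character(),
                      gene_id = character(), orientation = character(),
                      stringsAsFactors = FALSE))
  tss <- GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tx$tss, width = 1L))
  hits <- GenomicRanges::findOverlaps(tss, te_set, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  te_strand <- as.character(GenomicRanges::strand(te_set))[s]
  data.frame(
    element_id = te_set$element_id[s],
    transcript_id = tx$transcript_id[q],
    gene_id = tx$gene_id[q],
    orientation = ifelse(te_strand == tx$strand[q], "sense", "antisense"),
    stringsAsFactors = FALSE
  )
}

#' Detect TE-gene fusion fragments
#'
#' A fragment is a fusion read iff (a) at least `min_overlap` aligned
#' bases overlap a TE element, (b) at least `min_overlap` aligned bases
#' overlap an exon of a protein-coding transcript, and (c) the fragment
#' strand equals the gene strand (sense to the gene). The TE orientation
#' is unrestricted - both sense and antisense TE promoters are kept.
#' Evidence is `"split-read"` when a single mate's (possibly spliced)
#' blocks provide both overlaps, `"spanning-pair"` when the two mates do
#' so separately.
#'
#' @param fragments `read_fragments` (stranded protocol required).
#' @param te_set `GRanges` of TE fragments with `element_id`.
#' @param genes Output of [parse_gene_annotation()].
#' @param min_overlap Minimum overlap in bases on each side (default 1).
#' @param gene_side `"exon"` (default) requires overlap with an exon;
#'   `"transcript-span"` accepts any base inside the transcript span.
#' @return data.frame, one row per fusion fragment: `query_id`,
#'   `te_element_id`, `gene_id`, `gene_sense` (always `TRUE`),
#'   `te_orientation`, `evidence`.
#' @export
detect_fusion_reads <- function(fragments, te_set, genes, min_overlap = 1L,
                                gene_side = c("exon", "transcript-span")) {
  gene_side <- match.arg(gene_side)
  if (fragments$protocol == "unstranded")
    stop("fusion detection requires a stranded protocol")
  exons <- genes$exons[genes$exons$coding]
  if (gene_side == "transcript-span") {
    spl <- GenomicRanges::split(exons, exons$transcript_id)
    rng <- unlist(range(spl))
    ids <- names(rng)
    tx <- genes$transcripts
    exons <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(rng), IRanges::ranges(rng),
      strand = GenomicRanges::strand(rng),
      transcript_id = ids,
      gene_id = tx$gene_id[match(ids, tx$transcript_id)],
      coding = TRUE)
  }
  uniq <- which(fragments$meta$unique)
  if (length(uniq) == 0) return(empty_fusion_df())

  overlap_pairs <- function(blocks_grl, targets, target_ids) {
    ub <- unlist(blocks_grl, use.names = FALSE)
    frag_of <- rep(seq_along(blocks_grl), lengths(blocks_grl))
    hits <- GenomicRanges::findOverlaps(ub, targets, ignore.strand = TRUE,
                                        minoverlap = min_overlap)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    unique(data.frame(frag = frag_of[q], id = target_ids[s],
                      tidx = s, stringsAsFactors = FALSE))
  }
  check_mate <- function(mate_grl, targets, min_ov) {
    ub <- unlist(mate_grl, use.names = FALSE)
    frag_of <- rep(seq_along(mate_grl), lengths(mate_grl))
    hits <- GenomicRanges::findOverlaps(ub, targets, ignore.strand = TRUE,
                                        minoverlap = min_ov)
    unique(frag_of[S4Vectors::queryHits(hits)])
  }

  blocks <- fragments$blocks[uniq]
  te_hits <- overlap_pairs(blocks, te_set, te_set$element_id)
  ex_hits <- overlap_pairs(blocks, exons, exons$gene_id)
  if (nrow(te_hits) == 0 || nrow(ex_hits) == 0) return(empty_fusion_df())

  # strand of gene per (frag, gene) hit
  ex_hits$gene_strand <- as.character(GenomicRanges::strand(exons))[ex_hits$tidx]
  ex_hits <- unique(ex_hits[, c("frag", "id", "gene_strand")])
  frag_strand <- fragments$meta$fragment_strand[uniq]
  ex_hits <- ex_hits[frag_strand[ex_hits$frag] == ex_hits$gene_strand, ,
                     drop = FALSE]
  if (nrow(ex_hits) == 0) return(empty_fusion_df())

  # best TE per fragment (largest overlap) among TE-overlapping fragments
  te_feats <- te_set
  te_feats$feature_id <- te_set$element_id
  best_te <- assign_fragments(blocks, te_feats, mode = "largest-overlap")

  cand <- merge(ex_hits[, c("frag", "id")], best_te,
                by = "frag")
  if (nrow(cand) == 0) return(empty_fusion_df())

  # evidence: split-read if one mate alone overlaps both sides
  m1 <- fragments$mate_blocks[[1]][uniq]
  m2 <- fragments$mate_blocks[[2]][uniq]
  m1_te <- check_mate(m1, te_set, min_overlap)
  m1_ex <- check_mate(m1, exons, min_overlap)
  m2_te <- check_mate(m2, te_set, min_overlap)
  m2_ex <- check_mate(m2, exons, min_overlap)
  split_frags <- union(intersect(m1_te, m1_ex), intersect(m2_te, m2_ex))

  te_strand <- as.character(GenomicRanges::strand(te_set))
  names(te_strand) <- te_set$element_id
  out <- data.frame(
    query_id = fragments$meta$qname[uniq][cand$frag],
    te_element_id = cand$feature_id,
    gene_id = cand$id,
    gene_sense = TRUE,
    te_orientation = ifelse(frag_strand[cand$frag] ==
                              te_strand[cand$feature_id],
                            "sense", "antisense"),
    evidence = ifelse(cand$frag %in% split_frags,
                      "split-read", "spanning-pair"),
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  out[order(out$query_id, out$gene_id), , drop = FALSE]
}

empty_fusion_df <- function() {
  data.frame(query_id = character(), te_element_id = character(),
             gene_id = character(), gene_sense = logical(),
             te_orientation = character(), evidence = character(),
             stringsAsFactors = FALSE)
}

#' Gene x sample fusion-read matrix
#'
#' Counts fusion fragments per gene per sample and restricts the matrix
#' to genes whose annotated TSS overlaps a TE (the promoter-candidate
#' rule); counts are library-scaled when library sizes are supplied.
#'
#' @param fusion_reads_per_sample Named list of data.frames from
#'   [detect_fusion_reads()], one per sample.
#' @param promoter_candidates data.frame from [find_te_tss_overlaps()].
#' @param library_size Optional named vector of per-sample library sizes;
#'   when given, counts are scaled by `mean(library_size) / library_size`.
#' @return list: `counts` (gene x sample), `normalized` (same shape;
#'   equals `counts` when no library sizes given).
#' @export
fusion_matrix <- function(fusion_reads_per_sample, promoter_candidates,
                          library_size = NULL) {
  genes <- sort(unique(promoter_candidates$gene_id))
  samples <- names(fusion_reads_per_sample)
  if (is.null(samples))
    samples <- paste0("sample", seq_along(fusion_reads_per_sample))
  counts <- matrix(0, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
  for (j in seq_along(fusion_reads_per_sample)) {
    fr <- fusion_reads_per_sample[[j]]
    fr <- fr[fr$gene_id %in% genes, , drop = FALSE]
    if (nrow(fr) > 0) {
      # one fragment counted once per gene
      fr <- unique(fr[, c("query_id", "gene_id")])
      tab <- table(fr$gene_id)
      counts[names(tab), j] <- as.numeric(tab)
    }
  }
  normalized <- counts
  if (!is.null(library_size)) {
    stopifnot(length(library_size) == ncol(counts))
    normalized <- sweep(counts, 2, mean(library_size) / library_size, "*")
  }
  list(counts = counts, normalized = normalized)
}
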