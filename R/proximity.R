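#' Protein-coding genes near upregulated TE elements
#'
#' For each gene, finds the nearest qualifying element and keeps genes
#' whose minimal gap between the gene body and any element is at most
#' `window_bp` (default 50 kb); overlap counts as distance 0. Distances
#' are strand-blind.
#'
#' @param genes `GRanges` of gene bodies with a `gene_id` metadata
#'   column, or the list from [parse_gene_annotation()] (gene bodies are
#'   then the per-gene exon span).
#' @param upregulated_tes `GRanges` of significantly upregulated elements
#'   with `element_id`.
#' @param window_bp Maximum gap in bp (default 50000).
#' @return data.frame: `gene_id`, `te_element_id` (nearest element),
#'   `distance_bp`.
#' @export
genes_near_elements <- function(genes, upregulated_tes, window_bp = 50000L) {
  gr <- gene_bodies(genes)
  if (length(upregulated_tes) == 0 || length(gr) == 0)
    return(data.frame(gene_id = character(), te_element_id = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  dn <- GenomicRanges::distanceToNearest(gr, upregulated_tes,
                                         ignore.strand = TRUE)
  q <- S4Vectors::queryHits(dn); s <- S4Vectors::subjectHits(dn)
  d <- S4Vectors::mcols(dn)$distance
  keep <- d <= window_bp
  data.frame(gene_id = gr$gene_id[q][keep],
             te_element_id = upregulated_tes$element_id[s][keep],
             distance_bp = d[keep],
             stringsAsFactors = FALSE)
}

# Gene bodies as per-gene exon span, or pass-through for a GRanges input.
gene_bodies <- function(genes) {
  if (inherits(genes, "GRanges")) {
    stopifnot(!is.null(genes$gene_id))
    return(genes)
  }
  exons <- genes$exons
  spl <- GenomicRanges::split(exons, exons$gene_id)
  rng <- unlist(range(spl, ignore.strand = TRUE))
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(rng),
                               IRanges::ranges(rng))
  gr$gene_id <- names(rng)
  names(gr) <- NULL
  gr
}

#' Expression shift of genes near activated elements
#'
#' Compares the log2 fold changes of genes near upregulated elements
#' against the background of all other tested genes with a two-sided
#' Wilcoxon rank-sum test, reporting group means (the "black dot" summary
#' of the distribution comparison).
#'
#' @param de_genes data.frame from [differential_test()] over genes.
#' @param near_gene_ids Character vector of gene ids in the near-set
#'   (e.g. `genes_near_elements(...)$gene_id`).
#' @return list: `mean_near`, `mean_background`, `n_near`,
#'   `n_background`, `p_value`, `undefined` (TRUE when the near-set is
#'   empty after intersection with tested genes).
#' @export
expression_shift_test <- function(de_genes, near_gene_ids) {
  tested <- de_genes[!is.na(de_genes$p_value), , drop = FALSE]
  near <- tested$log2_fold_change[tested$feature_id %in% near_gene_ids]
  bg <- tested$log2_fold_change[!tested$feature_id %in% near_gene_ids]
  if (length(near) == 0 || length(bg) == 0)
    return(list(mean_near = NA_real_, mean_background = NA_real_,
                n_near = length(near), n_background = length(bg),
                p_value = NA_real_, undefined = TRUE))
  ht <- rank_sum_test(near, bg)
  list(mean_near = mean(near), mean_background = mean(bg),
       n_near = length(near), n_background = length(bg),
       p_value = ht$p_value, undefined = FALSE)
}
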