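#' Configuration for the synthetic hNPC demethylation dataset
#'
#' Builds the full parameter set for the toy dataset: a 2-Mb two-chromosome
#' genome carrying age-stratified L1 copies (divergence tracking subfamily
#' age), genes, antisense L1 promoters overlapping gene TSSs, Beta-distributed
#' CpG methylomes (mean 0.79 in control, 0.079 after demethylation, CH level
#' 0.004 in both), negative-binomial expression with +4 log2FC activation of
#' hominoid-specific L1s in the knockout, ChIP enrichment at activated L1 5'
#' ends, and a CRISPR amplicon with editing rate 0.935 over a fixed indel
#' spectrum. All randomness is driven by `seed`; a fixed seed gives
#' bit-reproducible output.
#'
#' @param seed Integer master seed (default 42).
#' @param ... Named overrides of any top-level config entry.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chrom_bp = c(chr1 = 2000000L, chr2 = 2000000L),
    gap_bp_range = c(500L, 30000L),
    reserve_bp = 50000L,             # feature-free zone per chromosome
    subfamilies = data.frame(
      name = c("L1HS", "L1PA2", "L1PA3", "L1PA7", "L1MA4",
               "HERVH-int", "SVA_D", "AluY"),
      class = c("LINE", "LINE", "LINE", "LINE", "LINE",
                "LTR", "SVA", "SINE"),
      family = c("L1", "L1", "L1", "L1", "L1", "HERVH", "SVA", "Alu"),
      age_my = c(3.1, 7.6, 12.4, 25, 90, 35, 9, 15),
      n_copies = c(12L, 12L, 12L, 12L, 10L, 8L, 8L, 15L),
      consensus_bp = c(6500L, 6500L, 6500L, 6500L, 6500L,
                       5000L, 1500L, 300L),
      full_frac = c(0.5, 0.4, 0.3, 0.2, 0.1, 1, 1, 1),
      intact_frac = c(0.7, 0.4, 0.2, 0, 0, 0, 0, 0),
      stringsAsFactors = FALSE),
    div_pct_per_my = 0.442,          # L1HS at 3.1 My ~ 1.37% divergence
    n_genes = 30L,
    n_fusion_genes = 3L,
    exon_n_range = c(3L, 6L),
    exon_bp_range = c(150L, 400L),
    intron_bp_range = c(500L, 3000L),
    meth = list(mean_control = 0.79, mean_ko = 0.079, beta_conc = 10,
                ch_level = 0.004, coverage_mean = 10, n_cpg = 10000L,
                n_ch = 4000L),
    rnaseq = list(n_replicates = 3L, te_mean = 20, gene_mean = 60,
                  dispersion = 0.05, activation_log2fc = 4,
                  gene_near_log2fc = 1.5, read_bp = 100L, frag_bp = 250L,
                  multimap_frac = 0.1, fusion_reads_per_gene = 10L,
                  target_depth = 30000L, antisense_frac = 0),
    chip = list(read_bp = 50L, background_reads = 20000L,
                enrichment_fold = 8, promoter_bp = 500L,
                n_replicates = 2L, lowmapq_frac = 0.05),
    crispr = list(amplicon_bp = 1400L, cut_pos = 700L,
                  editing_rate = 0.935, n_reads = 5000L, read_bp = 300L,
                  flank_bp = 10L)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config entry: ", nm)
    if (is.list(cfg[[nm]]) && !is.data.frame(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = c("sim_config", "list"))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitution-mutate a sequence at the given per-base rate; returns the
# mutated string and the realized divergence percentage.
mutate_seq <- function(s, rate) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n_mut <- stats::rbinom(1L, length(chars), rate)
  if (n_mut > 0) {
    at <- sample.int(length(chars), n_mut)
    for (i in at) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
  }
  list(seq = paste(chars, collapse = ""),
       divergence_pct = 100 * n_mut / length(chars))
}

#' Simulate the toy genome with TE and gene annotations
#'
#' Generates random background chromosomes, plants mutated copies of
#' per-subfamily consensus sequences (younger subfamilies less diverged),
#' lays out protein-coding gene models, and places full-length L1HS
#' copies in antisense orientation over the TSS of the designated fusion
#' genes. Writes `genome.fa`, `te.bed` (BED+ 8 columns) and `genes.gtf`
#' to `out_dir` and returns them together with machine-readable ground
#' truth.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return list: `config`, `paths` (fasta/te_bed/gtf), `genome`
#'   (DNAStringSet), `genes` (list of per-gene structures), `truth`
#'   (list with `te` and `genes` data.frames).
#' @export
simulate_genome_and_annotations <- function(config = sim_config(),
                                            out_dir = tempfile("sim")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  chrom_bp <- config$chrom_bp
  chroms <- lapply(chrom_bp, function(n)
    strsplit(random_dna(n), "", fixed = TRUE)[[1]])

  sf <- config$subfamilies
  consensus <- stats::setNames(
    vapply(sf$consensus_bp, random_dna, character(1)), sf$name)

  ## --- build feature descriptors -------------------------------------
  te_rows <- list()
  for (i in seq_len(nrow(sf))) {
    for (k in seq_len(sf$n_copies[i])) {
      full <- stats::runif(1) < sf$full_frac[i]
      cons <- consensus[[sf$name[i]]]
      len <- if (full) nchar(cons)
             else sample(seq(max(300L, round(nchar(cons) * 0.05)),
                             max(301L, round(nchar(cons) * 0.6))), 1L)
      # 5' truncation: retain the 3' end of the consensus
      seq0 <- substr(cons, nchar(cons) - len + 1L, nchar(cons))
      mut <- mutate_seq(seq0, sf$age_my[i] * config$div_pct_per_my / 100)
      intact <- full && stats::runif(1) < sf$intact_frac[i]
      te_rows[[length(te_rows) + 1L]] <- list(
        subfamily = sf$name[i], class = sf$class[i], family = sf$family[i],
        age_my = sf$age_my[i], width = len, seq = mut$seq,
        divergence_pct = mut$divergence_pct, full_length = full,
        intact = intact, strand = sample(c("+", "-"), 1L),
        fusion_promoter = FALSE)
    }
  }

  gene_structs <- list()
  for (g in seq_len(config$n_genes)) {
    n_ex <- sample(seq(config$exon_n_range[1], config$exon_n_range[2]), 1L)
    ex_w <- sample(seq(config$exon_bp_range[1], config$exon_bp_range[2]),
                   n_ex, replace = TRUE)
    in_w <- sample(seq(config$intron_bp_range[1], config$intron_bp_range[2]),
                   n_ex - 1L, replace = TRUE)
    fusion <- g <= config$n_fusion_genes
    gene_structs[[g]] <- list(
      gene_id = sprintf("gene%02d", g),
      strand = if (fusion) "+" else sample(c("+", "-"), 1L),
      exon_w = ex_w, intron_w = in_w, fusion = fusion)
  }

  ## --- placement ------------------------------------------------------
  # one unit per TE or gene; fusion genes carry their antisense L1HS
  units <- c(
    lapply(seq_along(te_rows), function(i) list(type = "te", idx = i,
      width = te_rows[[i]]$width)),
    lapply(seq_along(gene_structs), function(g) {
      gs <- gene_structs[[g]]
      span <- sum(gs$exon_w) + sum(gs$intron_w)
      list(type = "gene", idx = g,
           width = span + if (gs$fusion) 6200L else 0L)
    }))
  units <- units[sample.int(length(units))]
  chrom_names <- names(chrom_bp)
  cursor <- stats::setNames(rep(1000L, length(chrom_bp)), chrom_names)
  limit <- chrom_bp - config$reserve_bp
  # draw inter-feature gaps up front and shrink them if the layout would
  # not fit, so any seed yields a valid genome
  gaps <- sample(seq(config$gap_bp_range[1], config$gap_bp_range[2]),
                 length(units), replace = TRUE)
  capacity <- sum(limit - 1000L)
  need <- sum(vapply(units, function(u) u$width, numeric(1)))
  while (need + sum(gaps) > 0.9 * capacity)
    gaps <- pmax(500L, as.integer(gaps * 0.8))
  chrom_i <- 1L
  placed_te <- list(); placed_gene <- list()
  l1hs_cons <- consensus[["L1HS"]]
  for (ui in seq_along(units)) {
    u <- units[[ui]]
    gap <- gaps[ui]
    while (cursor[chrom_i] + gap + u$width > limit[chrom_i]) {
      chrom_i <- chrom_i + 1L
      if (chrom_i > length(chrom_bp))
        stop("feature copies exceed genome capacity")
    }
    at <- cursor[chrom_i] + gap
    chr <- chrom_names[chrom_i]
    if (u$type == "te") {
      te <- te_rows[[u$idx]]
      te$chrom <- chr; te$start <- at; te$end <- at + te$width - 1L
      s <- te$seq
      if (te$strand == "-")
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      chroms[[chr]][te$start:te$end] <- strsplit(s, "", fixed = TRUE)[[1]]
      placed_te[[length(placed_te) + 1L]] <- te
    } else {
      gs <- gene_structs[[u$idx]]
      tss_offset <- if (gs$fusion) 6200L else 0L
      gstart <- at + tss_offset
      bounds <- gene_exon_coords(gstart, gs$exon_w, gs$intron_w)
      gs$chrom <- chr
      gs$exons <- bounds
      gs$tss <- if (gs$strand == "+") bounds$start[1]
                else bounds$end[nrow(bounds)]
      if (gs$fusion) {
        # antisense full-length L1HS whose interval contains the TSS
        l1_end <- gs$tss + 300L
        l1_start <- l1_end - 6500L + 1L
        mut <- mutate_seq(l1hs_cons,
                          3.1 * config$div_pct_per_my / 100)
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(mut$seq)))
        chroms[[chr]][l1_start:l1_end] <- strsplit(s, "", fixed = TRUE)[[1]]
        placed_te[[length(placed_te) + 1L]] <- list(
          subfamily = "L1HS", class = "LINE", family = "L1", age_my = 3.1,
          width = 6500L, seq = mut$seq,
          divergence_pct = mut$divergence_pct, full_length = TRUE,
          intact = TRUE, strand = "-", fusion_promoter = TRUE,
          chrom = chr, start = l1_start, end = l1_end)
        gs$promoter_l1 <- c(l1_start, l1_end)
      }
      placed_gene[[length(placed_gene) + 1L]] <- gs
    }
    cursor[chrom_i] <- at + u$width
  }

  ## --- truth + files --------------------------------------------------
  te_df <- do.call(rbind, lapply(placed_te, function(t) data.frame(
    chrom = t$chrom, start0 = t$start - 1L, end0 = t$end,
    strand = t$strand, subfamily = t$subfamily, class = t$class,
    family = t$family, divergence_pct = round(t$divergence_pct, 2),
    age_my = t$age_my, full_length = t$full_length, intact = t$intact,
    fusion_promoter = t$fusion_promoter, stringsAsFactors = FALSE)))
  ord <- order(te_df$chrom, te_df$start0)
  te_df <- te_df[ord, , drop = FALSE]
  te_df$element_id <- sprintf("%s|%s:%d-%d(%s)", te_df$subfamily,
                              te_df$chrom, te_df$start0, te_df$end0,
                              te_df$strand)
  te_df$hominoid <- te_df$family == "L1" & te_df$age_my < 12.5
  te_df$overlaps_exon <- te_df$fusion_promoter
  te_df$activated <- te_df$hominoid & !te_df$overlaps_exon

  genes_df <- do.call(rbind, lapply(placed_gene, function(g) data.frame(
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
    start = g$exons$start[1], end = g$exons$end[nrow(g$exons)],
    tss = g$tss, fusion = g$fusion, stringsAsFactors = FALSE)))

  # genes within 50 kb of an activated element get a KO expression boost
  gene_gr <- GenomicRanges::GRanges(genes_df$chrom,
    IRanges::IRanges(genes_df$start, genes_df$end))
  act <- te_df[te_df$activated, , drop = FALSE]
  act_gr <- GenomicRanges::GRanges(act$chrom,
    IRanges::IRanges(act$start0 + 1L, act$end0))
  near <- rep(FALSE, nrow(genes_df))
  if (length(act_gr) > 0) {
    dn <- GenomicRanges::distanceToNearest(gene_gr, act_gr,
                                           ignore.strand = TRUE)
    near[S4Vectors::queryHits(dn)] <- S4Vectors::mcols(dn)$distance <= 50000L
  }
  genes_df$near_activated <- near

  genome <- Biostrings::DNAStringSet(
    vapply(chroms, paste, character(1), collapse = ""))
  names(genome) <- chrom_names
  paths <- list(fasta = file.path(out_dir, "genome.fa"),
                te_bed = file.path(out_dir, "te.bed"),
                gtf = file.path(out_dir, "genes.gtf"))
  Biostrings::writeXStringSet(genome, paths$fasta)
  utils::write.table(
    te_df[, c("chrom", "start0", "end0", "strand", "subfamily", "class",
              "family", "divergence_pct")],
    paths$te_bed, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write_sim_gtf(placed_gene, paths$gtf)

  list(config = config, paths = paths, out_dir = out_dir, genome = genome,
       genes = placed_gene,
       truth = list(te = te_df, genes = genes_df))
}

gene_exon_coords <- function(gstart, exon_w, intron_w) {
  starts <- integer(length(exon_w)); ends <- integer(length(exon_w))
  pos <- gstart
  for (e in seq_along(exon_w)) {
    starts[e] <- pos
    ends[e] <- pos + exon_w[e] - 1L
    pos <- ends[e] + 1L + if (e < length(exon_w)) intron_w[e] else 0L
  }
  data.frame(start = starts, end = ends)
}

write_sim_gtf <- function(placed_gene, path) {
  lines <- character(0)
  for (g in placed_gene) {
    attr_str <- sprintf(
      'gene_id "%s"; transcript_id "%s.t1"; gene_type "protein_coding";',
      g$gene_id, g$gene_id)
    ex <- g$exons
    ord <- if (g$strand == "-") rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
    for (e in ord)
      lines <- c(lines, paste(g$chrom, "sim", "exon", ex$start[e], ex$end[e],
                              ".", g$strand, ".", attr_str, sep = "\t"))
  }
  writeLines(lines, path)
}

#' Simulate a whole-genome bisulfite methylome
#'
#' Samples per-CpG methylation probabilities from a Beta distribution with
#' the condition mean (0.79 control, 0.079 knockout by default), draws
#' Poisson coverage and binomial methylated counts per site, and adds CH
#' (non-CpG) sites at a constant low methylation probability (0.4%).
#' Sites are real CG dinucleotides of the simulated genome.
#'
#' @param sim Output of [simulate_genome_and_annotations()].
#' @param condition `"control"` or `"ko"`.
#' @param path Optional output path for a 7-column Bismark-style coverage
#'   file (`chrom, start0, end0, pct, n_meth, n_unmeth, context`).
#' @return list: `calls` (data.frame as from [read_methylation_calls()]),
#'   `truth` (list `mean_cg`, `ch_level`, per-site true probabilities),
#'   `path` (or `NULL`).
#' @export
simulate_methylome <- function(sim, condition = c("control", "ko"),
                               path = NULL) {
  condition <- match.arg(condition)
  cfg <- sim$config$meth
  set.seed(sim$config$seed + if (condition == "control") 101L else 102L)
  mean_cg <- if (condition == "control") cfg$mean_control else cfg$mean_ko

  site_scan <- lapply(names(sim$genome), function(chr) {
    chars <- strsplit(as.character(sim$genome[[chr]]), "", fixed = TRUE)[[1]]
    is_c <- chars == "C"
    next_g <- c(chars[-1] == "G", FALSE)
    list(cg = which(is_c & next_g), ch = which(is_c & !next_g))
  })
  names(site_scan) <- names(sim$genome)
  cg_pos <- do.call(rbind, lapply(names(sim$genome), function(chr)
    data.frame(chrom = chr, pos = site_scan[[chr]]$cg - 1L,
               stringsAsFactors = FALSE)))
  if (nrow(cg_pos) > cfg$n_cpg)
    cg_pos <- cg_pos[sort(sample.int(nrow(cg_pos), cfg$n_cpg)), ,
                     drop = FALSE]
  a <- mean_cg * cfg$beta_conc
  b <- (1 - mean_cg) * cfg$beta_conc
  p_cg <- stats::rbeta(nrow(cg_pos), a, b)

  ch_pos <- do.call(rbind, lapply(names(sim$genome), function(chr)
    data.frame(chrom = chr, pos = site_scan[[chr]]$ch - 1L,
               stringsAsFactors = FALSE)))
  if (nrow(ch_pos) > cfg$n_ch)
    ch_pos <- ch_pos[sort(sample.int(nrow(ch_pos), cfg$n_ch)), ,
                     drop = FALSE]
  p_ch <- rep(cfg$ch_level, nrow(ch_pos))

  calls <- rbind(
    data.frame(cg_pos, context = "CG", p = p_cg, stringsAsFactors = FALSE),
    data.frame(ch_pos, context = "CH", p = p_ch, stringsAsFactors = FALSE))
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  cov <- stats::rpois(nrow(calls), cfg$coverage_mean)
  n_meth <- stats::rbinom(nrow(calls), cov, calls$p)
  out <- data.frame(chrom = calls$chrom, pos = calls$pos,
                    context = calls$context, n_meth = n_meth,
                    n_unmeth = cov - n_meth, stringsAsFactors = FALSE)
  truth <- list(mean_cg = mean_cg, ch_level = cfg$ch_level,
                p_site = calls$p)
  keep <- cov > 0
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    cov_k <- out$n_meth + out$n_unmeth
    utils::write.table(
      data.frame(out$chrom, out$pos, out$pos + 1L,
                 round(100 * out$n_meth / cov_k, 2), out$n_meth,
                 out$n_unmeth, out$context),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  list(calls = out, truth = truth, path = path)
}
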