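# SAM emission and read-level simulators. Alignments are written directly
# as SAM (the pipeline consumes aligner output; no read-level FASTQ stage).

write_sam <- function(records, seqlens, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens),
                      as.integer(seqlens)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\t%s",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, records$rnext, records$pnext,
                  records$tlen, records$seq, "*", records$tags)
  writeLines(c(header, body), path)
  path
}

write_sam_lines <- function(lines, seqlens, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens),
                      as.integer(seqlens)))
  writeLines(c(header, lines), path)
  path
}

# Vectorised emission of proper pairs with single-block mates: returns a
# character vector of 2n SAM lines. Mate 1 aligns opposite the fragment.
pair_lines_simple <- function(qname, chrom, b1s, b1e, b2s, b2e, strand,
                              nh = 1L, mapq = 60L) {
  f1 <- ifelse(strand == "+", 83L, 99L)
  f2 <- ifelse(strand == "+", 163L, 147L)
  lo <- pmin(b1s, b2s); hi <- pmax(b1e, b2e)
  tl <- hi - lo + 1L
  tags <- sprintf("NH:i:%d", nh)
  c(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t*\t*\t%s",
            qname, f1, chrom, b1s, mapq, b1e - b1s + 1L, b2s,
            ifelse(b1s <= b2s, tl, -tl), tags),
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t*\t*\t%s",
            qname, f2, chrom, b2s, mapq, b2e - b2s + 1L, b1s,
            ifelse(b2s < b1s, tl, -tl), tags))
}

# One pair where the mates may be spliced (block matrices).
pair_lines_blocks <- function(qname, chrom, blocks1, blocks2, strand,
                              nh = 1L, mapq = 60L) {
  f1 <- if (strand == "+") 83L else 99L
  f2 <- if (strand == "+") 163L else 147L
  pos1 <- blocks1[1, 1]; pos2 <- blocks2[1, 1]
  lo <- min(pos1, pos2)
  hi <- max(blocks1[nrow(blocks1), 2], blocks2[nrow(blocks2), 2])
  tl <- hi - lo + 1L
  tags <- sprintf("NH:i:%d", nh)
  c(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*\t%s",
            qname, f1, chrom, pos1, mapq, cigar_from_blocks(blocks1), pos2,
            if (pos1 <= pos2) tl else -tl, tags),
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*\t%s",
            qname, f2, chrom, pos2, mapq, cigar_from_blocks(blocks2), pos1,
            if (pos2 < pos1) tl else -tl, tags))
}

# Map a transcript-coordinate interval [t_lo, t_hi] (1-based, 5'->3') to
# ascending genomic blocks, given ascending exon coordinates and strand.
tx_blocks <- function(exons, strand, t_lo, t_hi) {
  w <- exons$end - exons$start + 1L
  ord <- if (strand == "-") rev(seq_len(nrow(exons))) else seq_len(nrow(exons))
  cum <- c(0L, cumsum(w[ord]))
  blocks <- list()
  for (k in seq_along(ord)) {
    lo <- max(t_lo, cum[k] + 1L); hi <- min(t_hi, cum[k + 1L])
    if (lo > hi) next
    e <- ord[k]
    if (strand == "+") {
      gs <- exons$start[e] + (lo - cum[k] - 1L)
      ge <- exons$start[e] + (hi - cum[k] - 1L)
    } else {
      ge <- exons$end[e] - (lo - cum[k] - 1L)
      gs <- exons$end[e] - (hi - cum[k] - 1L)
    }
    blocks[[length(blocks) + 1L]] <- c(gs, ge)
  }
  m <- do.call(rbind, blocks)
  m[order(m[, 1]), , drop = FALSE]
}

cigar_from_blocks <- function(blocks) {
  parts <- character(0)
  for (i in seq_len(nrow(blocks))) {
    if (i > 1) {
      gap <- blocks[i, 1] - blocks[i - 1, 2] - 1L
      parts <- c(parts, sprintf("%dN", gap))
    }
    parts <- c(parts, sprintf("%dM", blocks[i, 2] - blocks[i, 1] + 1L))
  }
  paste(parts, collapse = "")
}

#' Simulate stranded paired-end RNA-seq alignments
#'
#' Emits one SAM per replicate with TruSeq-style reverse-stranded
#' geometry. Per-feature fragment counts are negative-binomial with
#' condition-specific means: hominoid-specific L1 elements are boosted by
#' the activation log2 fold change in the knockout (sense orientation
#' only), genes near activated elements get a milder boost, and the
#' designated fusion genes receive spliced antisense-L1-promoter fusion
#' fragments in the knockout. A configurable fraction of L1 fragments is
#' marked multi-mapping (NH = 3, with a secondary record) to exercise the
#' uniqueness filter. Each library is topped up with intergenic background
#' fragments to a fixed sequencing depth, emulating the rest of the
#' transcriptome, so per-sample totals are comparable. Ground truth
#' records every planted unique count.
#'
#' @param sim Output of [simulate_genome_and_annotations()].
#' @param condition `"control"` or `"ko"`.
#' @param out_dir Output directory for SAM files.
#' @param n_replicates Number of replicates (default from config).
#' @return list: `paths` (SAM per replicate), `truth` (list with
#'   `te_counts` and `gene_counts` matrices of planted unique fragments,
#'   `fusion_qnames` per replicate, `library_size`).
#' @export
simulate_rnaseq <- function(sim, condition = c("control", "ko"),
                            out_dir = sim$out_dir,
                            n_replicates = sim$config$rnaseq$n_replicates) {
  condition <- match.arg(condition)
  cfg <- sim$config$rnaseq
  te <- sim$truth$te
  genes <- sim$genes
  seqlens <- sim$config$chrom_bp
  limit <- seqlens - sim$config$reserve_bp
  read_bp <- cfg$read_bp; frag_bp <- cfg$frag_bp

  te_counts <- matrix(0L, nrow = nrow(te), ncol = n_replicates,
                      dimnames = list(te$element_id, NULL))
  gene_ids <- vapply(genes, function(g) g$gene_id, character(1))
  gene_counts <- matrix(0L, nrow = length(gene_ids), ncol = n_replicates,
                        dimnames = list(gene_ids, NULL))
  fusion_qnames <- vector("list", n_replicates)
  library_size <- integer(n_replicates)
  paths <- character(n_replicates)

  base_seed <- sim$config$seed + if (condition == "control") 200L else 210L
  for (r in seq_len(n_replicates)) {
    set.seed(base_seed + r)
    lines <- list()
    qn <- 0L
    new_qname <- function(n = 1L) {
      out <- sprintf("%s_r%d_f%06d", condition, r, qn + seq_len(n))
      qn <<- qn + n
      out
    }
    n_unique <- 0L

    ## TE fragments (sense to the element)
    for (i in seq_len(nrow(te))) {
      mu <- cfg$te_mean
      if (condition == "ko" && te$activated[i])
        mu <- mu * 2^cfg$activation_log2fc
      n_frag <- stats::rnbinom(1L, mu = mu, size = 1 / cfg$dispersion)
      if (n_frag == 0) next
      st <- te$start0[i] + 1L
      en <- te$end0[i]
      if (te$fusion_promoter[i]) en <- en - 301L   # keep clear of exon 1
      flen <- min(frag_bp, en - st + 1L)
      rb <- min(read_bp, flen)
      fs <- st + sample.int(en - st + 1L - flen + 1L, n_frag,
                            replace = TRUE) - 1L
      strand_i <- if (cfg$antisense_frac > 0)
        ifelse(stats::runif(n_frag) < cfg$antisense_frac,
               setdiff(c("+", "-"), te$strand[i]), te$strand[i])
      else rep(te$strand[i], n_frag)
      multi <- te$family[i] == "L1" &
        stats::runif(n_frag) < cfg$multimap_frac
      bAs <- fs; bAe <- fs + rb - 1L
      bBs <- fs + flen - rb; bBe <- fs + flen - 1L
      plus <- strand_i == "+"
      b1s <- ifelse(plus, bBs, bAs); b1e <- ifelse(plus, bBe, bAe)
      b2s <- ifelse(plus, bAs, bBs); b2e <- ifelse(plus, bAe, bBe)
      qns <- new_qname(n_frag)
      nh <- ifelse(multi, 3L, 1L)
      mq <- ifelse(multi, 0L, 60L)
      lines[[length(lines) + 1L]] <-
        pair_lines_simple(qns, te$chrom[i], b1s, b1e, b2s, b2e, strand_i,
                          nh = nh, mapq = mq)
      if (any(multi)) {
        # one secondary record per multimapping fragment
        spos <- pmin(b1s[multi] + 10000L, seqlens[[te$chrom[i]]] - rb)
        f1 <- ifelse(strand_i[multi] == "+", 83L, 99L) + 256L
        lines[[length(lines) + 1L]] <-
          sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t%d\t%d\t*\t*\tNH:i:3",
                  qns[multi], f1, te$chrom[i], spos, 0L, rb, 0L, 0L)
      }
      te_counts[i, r] <- sum(!multi)
      n_unique <- n_unique + sum(!multi)
    }

    ## gene fragments (spliced, sense to the gene)
    for (g in genes) {
      gi <- which(sim$truth$genes$gene_id == g$gene_id)
      mu <- cfg$gene_mean
      if (condition == "ko" && sim$truth$genes$near_activated[gi])
        mu <- mu * 2^cfg$gene_near_log2fc
      n_frag <- stats::rnbinom(1L, mu = mu, size = 1 / cfg$dispersion)
      if (n_frag == 0) next
      L <- sum(g$exons$end - g$exons$start + 1L)
      flen <- min(frag_bp, L)
      t_min <- 1L
      if (g$fusion) {
        # canonical promoter silenced: sample downstream of exon 1
        w1 <- g$exons$end[1] - g$exons$start[1] + 1L
        t_min <- w1 + 1L
      }
      if (L - flen + 1L < t_min) next
      ts <- sample(seq.int(t_min, L - flen + 1L), n_frag, replace = TRUE)
      qns <- new_qname(n_frag)
      gl <- character(2L * n_frag)
      for (k in seq_len(n_frag)) {
        b2 <- tx_blocks(g$exons, g$strand, ts[k], ts[k] + read_bp - 1L)
        b1 <- tx_blocks(g$exons, g$strand, ts[k] + flen - read_bp,
                        ts[k] + flen - 1L)
        gl[c(2L * k - 1L, 2L * k)] <-
          pair_lines_blocks(qns[k], g$chrom, b1, b2, g$strand)
      }
      lines[[length(lines) + 1L]] <- gl
      gene_counts[gi, r] <- gene_counts[gi, r] + n_frag
      n_unique <- n_unique + n_frag
    }

    ## fusion fragments: spliced from the antisense L1 promoter into exon 2
    fq <- character(0)
    if (condition == "ko") {
      for (g in genes) {
        if (!isTRUE(g$fusion)) next
        gi <- which(sim$truth$genes$gene_id == g$gene_id)
        e2 <- g$exons[2, ]
        for (k in seq_len(cfg$fusion_reads_per_gene)) {
          qname <- new_qname()
          b1 <- rbind(c(g$tss - 150L, g$tss - 51L),
                      c(e2$start, e2$start + 49L))
          b2 <- matrix(c(e2$start + 50L, e2$start + 149L), 1)
          lines[[length(lines) + 1L]] <-
            pair_lines_blocks(qname, g$chrom, b1, b2, "+")
          fq <- c(fq, qname)
          gene_counts[gi, r] <- gene_counts[gi, r] + 1L
          n_unique <- n_unique + 1L
        }
      }
    }
    fusion_qnames[[r]] <- fq

    ## intergenic background in the reserved feature-free zone, filling
    ## the library up to the fixed sequencing depth so sample totals are
    ## comparable (as real libraries sequenced to a set depth are)
    n_bg <- max(cfg$target_depth - n_unique, 0L)
    bg_chrom <- sample(names(seqlens), n_bg, replace = TRUE)
    lo <- limit[bg_chrom] + 1000L
    hi <- seqlens[bg_chrom] - 1000L - frag_bp
    fs <- lo + as.integer(floor(stats::runif(n_bg) * (hi - lo + 1L)))
    strand_bg <- sample(c("+", "-"), n_bg, replace = TRUE)
    bAs <- fs; bAe <- fs + read_bp - 1L
    bBs <- fs + frag_bp - read_bp; bBe <- fs + frag_bp - 1L
    plus <- strand_bg == "+"
    lines[[length(lines) + 1L]] <-
      pair_lines_simple(new_qname(n_bg), bg_chrom,
                        ifelse(plus, bBs, bAs), ifelse(plus, bBe, bAe),
                        ifelse(plus, bAs, bBs), ifelse(plus, bAe, bBe),
                        strand_bg)
    n_unique <- n_unique + n_bg

    library_size[r] <- n_unique
    paths[r] <- file.path(out_dir,
                          sprintf("rnaseq_%s_rep%d.sam", condition, r))
    write_sam_lines(unlist(lines), seqlens, paths[r])
  }
  names(paths) <- sprintf("%s_rep%d", condition, seq_len(n_replicates))
  colnames(te_counts) <- colnames(gene_counts) <- names(paths)
  names(library_size) <- names(paths)
  list(paths = paths,
       truth = list(te_counts = te_counts, gene_counts = gene_counts,
                    fusion_qnames = fusion_qnames,
                    library_size = library_size))
}

#' Simulate ChIP-seq alignments and CRISPR amplicon reads
#'
#' ChIP: single-end reads with uniform genome-wide background for every
#' library; in the knockout, H3K27ac and Pol II libraries receive extra
#' reads over the 5' promoter region of each activated L1 so that local
#' coverage reaches `enrichment_fold` times background. A small fraction
#' of reads carries MAPQ 5 to exercise the MAPQ filter. One input library
#' per condition (background only).
#'
#' Amplicon: single-end reads over a random amplicon reference; each read
#' is modified with probability `editing_rate` by one event drawn from a
#' fixed indel spectrum anchored at the cut site.
#'
#' @param sim Output of [simulate_genome_and_annotations()].
#' @param out_dir Output directory.
#' @return list: `chip` (list `paths` named `<mark>_<condition>_rep<r>`
#'   and `input_<condition>`, `promoters` data.frame of enriched 5'
#'   regions), `amplicon` (list `sam`, `fasta`, `reference`, `cut_pos`,
#'   `truth` with the planted spectrum and realized counts).
#' @export
simulate_chip_and_amplicons <- function(sim, out_dir = sim$out_dir) {
  cfg <- sim$config$chip
  seqlens <- sim$config$chrom_bp
  te <- sim$truth$te
  act <- te[te$activated, , drop = FALSE]
  prom <- data.frame(
    element_id = act$element_id, chrom = act$chrom,
    start = ifelse(act$strand == "+", act$start0 + 1L,
                   act$end0 - cfg$promoter_bp + 1L),
    stringsAsFactors = FALSE)
  prom$end <- prom$start + cfg$promoter_bp - 1L

  genome_bp <- sum(seqlens)
  bg_density <- cfg$background_reads / genome_bp
  chip_paths <- character(0)
  seed0 <- sim$config$seed + 300L
  emit_chip <- function(path, enriched) {
    n_bg <- cfg$background_reads
    chr <- sample(names(seqlens), n_bg, replace = TRUE,
                  prob = seqlens / genome_bp)
    pos <- 1L + as.integer(floor(stats::runif(n_bg) *
                                   (seqlens[chr] - cfg$read_bp)))
    strand_flag <- sample(c(0L, 16L), n_bg, replace = TRUE)
    mapq <- ifelse(stats::runif(n_bg) < cfg$lowmapq_frac, 5L, 30L)
    df <- data.frame(qname = sprintf("chip%07d", seq_len(n_bg)),
                     flag = strand_flag, rname = chr, pos = pos,
                     mapq = mapq, cigar = sprintf("%dM", cfg$read_bp),
                     rnext = "*", pnext = 0L, tlen = 0L, seq = "*",
                     tags = "NH:i:1", stringsAsFactors = FALSE)
    if (enriched && nrow(prom) > 0) {
      extra <- list()
      per_el <- stats::rpois(nrow(prom),
                             bg_density * cfg$promoter_bp *
                               (cfg$enrichment_fold - 1))
      for (i in seq_len(nrow(prom))) {
        if (per_el[i] == 0) next
        p <- prom$start[i] +
          sample.int(max(cfg$promoter_bp - cfg$read_bp, 1L), per_el[i],
                     replace = TRUE) - 1L
        extra[[i]] <- data.frame(
          qname = sprintf("peak%02d_%04d", i, seq_len(per_el[i])),
          flag = sample(c(0L, 16L), per_el[i], replace = TRUE),
          rname = prom$chrom[i], pos = p, mapq = 30L,
          cigar = sprintf("%dM", cfg$read_bp), rnext = "*", pnext = 0L,
          tlen = 0L, seq = "*", tags = "NH:i:1", stringsAsFactors = FALSE)
      }
      df <- rbind(df, do.call(rbind, extra))
    }
    write_sam(df, seqlens, path)
  }
  k <- 0L
  for (cond in c("control", "ko")) {
    for (mark in c("H3K27ac", "PolII")) {
      for (r in seq_len(cfg$n_replicates)) {
        k <- k + 1L
        set.seed(seed0 + k)
        path <- file.path(out_dir,
                          sprintf("chip_%s_%s_rep%d.sam", mark, cond, r))
        emit_chip(path, enriched = (cond == "ko"))
        chip_paths[sprintf("%s_%s_rep%d", mark, cond, r)] <- path
      }
    }
    k <- k + 1L
    set.seed(seed0 + 50L + k)
    path <- file.path(out_dir, sprintf("chip_input_%s.sam", cond))
    emit_chip(path, enriched = FALSE)
    chip_paths[sprintf("input_%s", cond)] <- path
  }

  ## ---- CRISPR amplicon ----------------------------------------------
  ccfg <- sim$config$crispr
  set.seed(sim$config$seed + 400L)
  ref <- random_dna(ccfg$amplicon_bp)
  cut <- ccfg$cut_pos
  del_sizes <- c(1L, 2L, 3L, 4L, 6L, 9L, 12L)
  del_probs <- c(0.28, 0.18, 0.12, 0.08, 0.06, 0.04, 0.04)
  ins_sizes <- c(1L, 2L, 3L)
  ins_probs <- c(0.12, 0.05, 0.03)
  ins_seqs <- vapply(ins_sizes, random_dna, character(1))
  spectrum <- rbind(
    data.frame(kind = "deletion", size = del_sizes,
               pos = cut - del_sizes %/% 2L,
               ref_allele = vapply(seq_along(del_sizes), function(i) {
                 p <- cut - del_sizes[i] %/% 2L
                 substr(ref, p, p + del_sizes[i] - 1L)
               }, character(1)),
               alt_allele = "", prob = del_probs, stringsAsFactors = FALSE),
    data.frame(kind = "insertion", size = ins_sizes, pos = cut + 1L,
               ref_allele = "", alt_allele = ins_seqs, prob = ins_probs,
               stringsAsFactors = FALSE))
  spectrum$prob <- spectrum$prob / sum(spectrum$prob) * ccfg$editing_rate
  spectrum$net_length <- nchar(spectrum$alt_allele) -
    nchar(spectrum$ref_allele)

  n <- ccfg$n_reads
  rb <- ccfg$read_bp
  starts <- cut - 250L + sample.int(190L, n, replace = TRUE) - 1L
  modified <- stats::runif(n) < ccfg$editing_rate
  which_ev <- integer(n)
  which_ev[modified] <- sample.int(nrow(spectrum), sum(modified),
                                   replace = TRUE,
                                   prob = spectrum$prob / sum(spectrum$prob))
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- starts[i]
    if (!modified[i]) {
      cigar <- sprintf("%dM", rb)
      seq_i <- substr(ref, s, s + rb - 1L)
    } else {
      ev <- spectrum[which_ev[i], ]
      if (ev$kind == "deletion") {
        x <- ev$pos - s
        y <- rb - x
        cigar <- sprintf("%dM%dD%dM", x, ev$size, y)
        de <- ev$pos + ev$size - 1L
        seq_i <- paste0(substr(ref, s, ev$pos - 1L),
                        substr(ref, de + 1L, de + y))
      } else {
        x <- cut - s + 1L
        y <- rb - x - ev$size
        cigar <- sprintf("%dM%dI%dM", x, ev$size, y)
        seq_i <- paste0(substr(ref, s, cut), ev$alt_allele,
                        substr(ref, cut + 1L, cut + y))
      }
    }
    recs[[i]] <- data.frame(qname = sprintf("amp%06d", i), flag = 0L,
                            rname = "amplicon", pos = s, mapq = 60L,
                            cigar = cigar, rnext = "*", pnext = 0L,
                            tlen = 0L, seq = seq_i, tags = "NH:i:1",
                            stringsAsFactors = FALSE)
  }
  amp_sam <- file.path(out_dir, "amplicon.sam")
  write_sam(do.call(rbind, recs),
            c(amplicon = ccfg$amplicon_bp), amp_sam)
  amp_fa <- file.path(out_dir, "amplicon.fa")
  writeLines(c(">amplicon", ref), amp_fa)
  realized <- table(factor(which_ev[modified], levels = seq_len(nrow(spectrum))))
  spectrum$planted_reads <- as.integer(realized)

  list(chip = list(paths = chip_paths, promoters = prom),
       amplicon = list(sam = amp_sam, fasta = amp_fa, reference = ref,
                       cut_pos = cut,
                       truth = list(spectrum = spectrum,
                                    n_reads = n,
                                    n_modified = sum(modified),
                                    editing_rate = ccfg$editing_rate)))
}

#' Generate the complete synthetic dataset
#'
#' Convenience wrapper: genome + annotations, control and knockout
#' methylomes, RNA-seq for both conditions, ChIP libraries and the CRISPR
#' amplicon, all under one output directory with shared ground truth.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return list: `sim` (genome stage), `methylome` (per condition),
#'   `rnaseq` (per condition), `chip_amplicon`.
#' @export
simulate_dataset <- function(config = sim_config(),
                             out_dir = tempfile("simdata")) {
  sim <- simulate_genome_and_annotations(config, out_dir)
  meth <- list(
    control = simulate_methylome(sim, "control",
      path = file.path(out_dir, "meth_control.cov")),
    ko = simulate_methylome(sim, "ko",
      path = file.path(out_dir, "meth_ko.cov")))
  rna <- list(control = simulate_rnaseq(sim, "control"),
              ko = simulate_rnaseq(sim, "ko"))
  ca <- simulate_chip_and_amplicons(sim)
  list(sim = sim, methylome = meth, rnaseq = rna, chip_amplicon = ca)
}
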