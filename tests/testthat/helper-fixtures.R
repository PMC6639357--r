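# Shared fixtures. The default synthetic dataset is expensive enough to
# build once and reuse across test files; everything is seeded.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_env[[name]]))
    .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

default_sim <- function() {
  cached("sim", function() simulate_genome_and_annotations(sim_config(42)))
}

default_rnaseq <- function() {
  cached("rnaseq", function() {
    sim <- default_sim()
    list(control = simulate_rnaseq(sim, "control"),
         ko = simulate_rnaseq(sim, "ko"))
  })
}

default_fragments <- function() {
  cached("fragments", function() {
    rna <- default_rnaseq()
    lapply(c(rna$control$paths, rna$ko$paths), load_fragments)
  })
}

default_chip_amp <- function() {
  cached("chip_amp", function() simulate_chip_and_amplicons(default_sim()))
}

default_te_annotation <- function() {
  cached("te_annot", function() {
    sim <- default_sim()
    assign_subfamily_ages(parse_te_annotation(sim$paths$te_bed))
  })
}

default_genes <- function() {
  cached("genes", function() parse_gene_annotation(default_sim()$paths$gtf))
}

# GRanges TE set from a compact spec, 1-based closed coordinates.
make_te_gr <- function(chrom, start, end, strand = "+", subfamily = "L1HS",
                       class = "LINE", family = "L1", divergence = 1) {
  n <- max(lengths(list(chrom, start, end)))
  gr <- GenomicRanges::GRanges(rep(chrom, length.out = n),
                               IRanges::IRanges(start, end),
                               strand = rep(strand, length.out = n))
  gr$element_id <- sprintf("el%03d", seq_len(n))
  gr$subfamily <- rep(subfamily, length.out = n)
  gr$class <- rep(class, length.out = n)
  gr$family <- rep(family, length.out = n)
  gr$divergence_pct <- rep(divergence, length.out = n)
  gr
}

# Minimal gene annotation object matching parse_gene_annotation()'s shape.
make_genes_obj <- function(df) {
  # df: gene_id, chrom, strand, exon_start, exon_end (list columns ok)
  ex_list <- lapply(seq_len(nrow(df)), function(i) {
    GenomicRanges::GRanges(df$chrom[i],
                           IRanges::IRanges(df$exon_start[[i]],
                                            df$exon_end[[i]]),
                           strand = df$strand[i],
                           transcript_id = paste0(df$gene_id[i], ".t1"),
                           gene_id = df$gene_id[i], coding = TRUE)
  })
  exons <- do.call(c, ex_list)
  tx <- data.frame(
    transcript_id = paste0(df$gene_id, ".t1"), gene_id = df$gene_id,
    chrom = df$chrom, strand = df$strand, coding = TRUE,
    tss = vapply(seq_len(nrow(df)), function(i) {
      if (df$strand[i] == "-") max(df$exon_end[[i]])
      else min(df$exon_start[[i]])
    }, numeric(1)),
    stringsAsFactors = FALSE)
  list(transcripts = tx, exons = exons)
}

# Write a SAM file from a data.frame of records (columns qname, flag,
# rname, pos, mapq, cigar, rnext, pnext, tlen, seq, tags).
write_test_sam <- function(records, seqlens, path = tempfile(fileext = ".sam")) {
  defaults <- list(mapq = 60L, rnext = "*", pnext = 0L, tlen = 0L,
                   seq = "*", tags = "NH:i:1")
  for (nm in names(defaults))
    if (is.null(records[[nm]])) records[[nm]] <- defaults[[nm]]
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens),
                     as.integer(seqlens)),
             sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*\t%s",
                     records$qname, records$flag, records$rname,
                     records$pos, records$mapq, records$cigar,
                     records$rnext, records$pnext, records$tlen,
                     records$seq, records$tags))
  writeLines(lines, path)
  path
}

# Amplicon read constructors for the CRISPR indel tests.
amp_ref <- function(n = 1400, seed = 61) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

amp_read <- function(qname, pos, cigar, seq) {
  data.frame(qname = qname, flag = 0L, rname = "amplicon", pos = pos,
             mapq = 60L, cigar = cigar, rnext = "*", pnext = 0L, tlen = 0L,
             seq = seq, tags = "NH:i:1", stringsAsFactors = FALSE)
}

perfect_read <- function(qname, ref, pos, len) {
  amp_read(qname, pos, sprintf("%dM", len), substr(ref, pos, pos + len - 1))
}

del_read <- function(qname, ref, pos, del_at, del_len, read_len = 150) {
  x <- del_at - pos
  y <- read_len - x
  de <- del_at + del_len - 1
  amp_read(qname, pos, sprintf("%dM%dD%dM", x, del_len, y),
           paste0(substr(ref, pos, del_at - 1), substr(ref, de + 1, de + y)))
}

ins_read <- function(qname, ref, pos, ins_after, ins_seq, read_len = 150) {
  x <- ins_after - pos + 1
  y <- read_len - x - nchar(ins_seq)
  amp_read(qname, pos, sprintf("%dM%dI%dM", x, nchar(ins_seq), y),
           paste0(substr(ref, pos, ins_after), ins_seq,
                  substr(ref, ins_after + 1, ins_after + y)))
}

# A proper pair (both mates plain M blocks) as two SAM record rows.
test_pair <- function(qname, chrom, start1, len1, start2, len2,
                      frag_strand = "+", nh = 1L, mapq = 60L) {
  if (frag_strand == "+") { f1 <- 83L; f2 <- 163L }
  else { f1 <- 99L; f2 <- 147L }
  data.frame(qname = qname, flag = c(f1, f2), rname = chrom,
             pos = c(start1, start2), mapq = mapq,
             cigar = sprintf("%dM", c(len1, len2)), rnext = "=",
             pnext = c(start2, start1), tlen = 0L, seq = "*",
             tags = sprintf("NH:i:%d", nh), stringsAsFactors = FALSE)
}
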