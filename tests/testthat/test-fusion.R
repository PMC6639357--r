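seqlens_f <- c(chr1 = 200000L)

simple_gene <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                        exon_start = list(c(10000, 12000, 14000)),
                        exon_end = list(c(10200, 12300, 14400))) {
  make_genes_obj(data.frame(gene_id = gene_id, chrom = chrom,
                            strand = strand, exon_start = I(exon_start),
                            exon_end = I(exon_end)))
}

test_that("TSS-in-element containment defines promoter candidates", {
  te <- make_te_gr("chr1", 501, 1500, strand = "-")   # BED [500,1500)
  g_in <- simple_gene(exon_start = list(c(1000, 3000)),
                      exon_end = list(c(1200, 3300)))
  cand <- find_te_tss_overlaps(g_in, te)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$orientation, "antisense")

  # TSS at BED position 1500 sits one past the element end: no candidate
  g_edge <- simple_gene(exon_start = list(c(1501, 3000)),
                        exon_end = list(c(1700, 3300)))
  expect_equal(nrow(find_te_tss_overlaps(g_edge, te)), 0)
})

test_that("candidate sets match per-TSS brute force on a planted fixture", {
  set.seed(41)
  te <- make_te_gr("chr1", s <- seq(10000, by = 10000, length.out = 6),
                   s + 5999, strand = sample(c("+", "-"), 6, TRUE))
  tss <- c(s[1:5] + 100, seq(80000, by = 5000, length.out = 7))  # 5 inside
  genes <- make_genes_obj(data.frame(
    gene_id = sprintf("g%02d", seq_along(tss)), chrom = "chr1",
    strand = "+", exon_start = I(as.list(tss)),
    exon_end = I(as.list(tss + 200))))
  cand <- find_te_tss_overlaps(genes, te)
  oracle <- vapply(tss, function(x)
    any(x >= GenomicRanges::start(te) & x <= GenomicRanges::end(te)),
    logical(1))
  expect_equal(nrow(cand), sum(oracle))
  expect_setequal(cand$gene_id, sprintf("g%02d", which(oracle)))
})

fusion_fixture <- function() {
  te <- make_te_gr("chr1", 4000, 10500, strand = "-")  # antisense L1 over TSS
  genes <- simple_gene(exon_start = list(c(10200, 12000, 14000)),
                       exon_end = list(c(10500, 12300, 14400)))
  # split fusion read: block in L1 upstream of the TSS, spliced to exon 2
  fus <- data.frame(qname = "fus", flag = c(83L, 163L), rname = "chr1",
                    pos = c(10000L, 12050L), mapq = 60L,
                    cigar = c("100M1900N50M", "100M"), rnext = "=",
                    pnext = c(12050L, 10000L), tlen = 0L, seq = "*",
                    tags = "NH:i:1", stringsAsFactors = FALSE)
  # same geometry but antisense to the gene: must be rejected
  anti <- fus
  anti$qname <- "anti"
  anti$flag <- c(99L, 147L)
  # mate-spanning evidence: mate 1 in the L1, mate 2 in exon 2
  pair <- rbind(
    test_pair("pair", "chr1", 12100, 100, 9800, 100, frag_strand = "+"))
  # exonic-only fragment: no TE overlap
  exonic <- test_pair("ex", "chr1", 12000, 100, 12150, 100,
                      frag_strand = "+")
  p <- write_test_sam(rbind(fus, anti, pair, exonic), seqlens_f)
  list(te = te, genes = genes, sam = p)
}

test_that("fusion fragments need TE + exon overlap and gene-sense orientation", {
  fx <- fusion_fixture()
  fr <- load_fragments(fx$sam)
  fus <- detect_fusion_reads(fr, fx$te, fx$genes)
  expect_setequal(fus$query_id, c("fus", "pair"))
  expect_true(all(fus$gene_sense))
  expect_equal(fus$te_orientation[fus$query_id == "fus"], "antisense")
  expect_equal(fus$evidence[fus$query_id == "fus"], "split-read")
  expect_equal(fus$evidence[fus$query_id == "pair"], "spanning-pair")

  expect_error(detect_fusion_reads(
    load_fragments(fx$sam, protocol = "unstranded"), fx$te, fx$genes),
    "stranded")
})

test_that("fusion detection is invariant to record order", {
  fx <- fusion_fixture()
  lines <- readLines(fx$sam)
  hdr <- grepl("^@", lines)
  set.seed(43)
  shuf <- c(lines[hdr], sample(lines[!hdr]))
  p2 <- tempfile(fileext = ".sam")
  writeLines(shuf, p2)
  a <- detect_fusion_reads(load_fragments(fx$sam), fx$te, fx$genes)
  b <- detect_fusion_reads(load_fragments(p2), fx$te, fx$genes)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("the fusion matrix keeps only genes with a TSS-overlapping TE", {
  cand <- data.frame(element_id = "el001", transcript_id = "g1.t1",
                     gene_id = "g1", orientation = "antisense")
  per_sample <- list(
    s1 = data.frame(query_id = c("a", "b"), te_element_id = "el001",
                    gene_id = "g1", gene_sense = TRUE,
                    te_orientation = "antisense", evidence = "split-read"),
    s2 = data.frame(query_id = "c", te_element_id = "el999",
                    gene_id = "gX",  # no candidate: must be excluded
                    gene_sense = TRUE, te_orientation = "sense",
                    evidence = "split-read"))
  fm <- fusion_matrix(per_sample, cand, library_size = c(s1 = 100, s2 = 200))
  expect_equal(rownames(fm$counts), "g1")
  expect_equal(unname(fm$counts["g1", ]), c(2, 0))
  expect_equal(unname(fm$normalized["g1", "s1"]), 2 * 150 / 100)

  empty <- fusion_matrix(list(s1 = per_sample$s2[0, ]), cand)
  expect_equal(dim(empty$counts), c(1L, 1L))  # candidate gene row, zero count
  expect_equal(sum(empty$counts), 0)
})

test_that("planted fusions are recovered with full recall and no false calls", {
  sim <- default_sim()
  rna <- default_rnaseq()
  frags <- default_fragments()
  te <- default_te_annotation()
  genes <- default_genes()
  ko_names <- grep("^ko", names(frags), value = TRUE)
  for (i in seq_along(ko_names)) {
    fus <- detect_fusion_reads(frags[[ko_names[i]]], te, genes)
    planted <- rna$ko$truth$fusion_qnames[[i]]
    expect_setequal(fus$query_id, planted)
    expect_true(all(fus$gene_sense))
    expect_true(all(fus$te_orientation == "antisense"))
  }
  ctrl <- detect_fusion_reads(frags[["control_rep1"]], te, genes)
  expect_equal(nrow(ctrl), 0)
})
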