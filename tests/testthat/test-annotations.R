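write_te_table <- function(rows, path = tempfile(fileext = ".bed")) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

test_that("TE table rows map to fragments and foreign classes are dropped", {
  path <- write_te_table(list(
    c("chr1", 100, 7100, "+", "L1HS", "LINE", "L1", 0.8),
    c("chr1", 9000, 9300, "-", "AluY", "SINE", "Alu", 4.1),
    c("chr1", 20000, 20500, "+", "MER1", "DNA", "MER", 10)))
  te <- suppressMessages(parse_te_annotation(path))
  expect_length(te, 2)
  expect_equal(attr(te, "n_excluded"), 1)
  expect_equal(GenomicRanges::width(te)[1], 7000)
  expect_equal(GenomicRanges::start(te)[1], 101)  # BED start converted
  expect_equal(te$class[1], "LINE")
  expect_equal(te$subfamily[2], "AluY")
})

test_that("TE fragment count equals an independent line count oracle", {
  set.seed(11)
  classes <- sample(c("LINE", "SINE", "LTR", "SVA", "DNA", "Simple_repeat"),
                    10, replace = TRUE)
  rows <- lapply(seq_along(classes), function(i)
    c("chr1", 1000 * i, 1000 * i + 500, "+", "X", classes[i], "F", 1))
  path <- write_te_table(rows)
  te <- suppressMessages(parse_te_annotation(path))
  n_expected <- sum(readLines(path) != "" &
                      classes %in% c("LINE", "SINE", "LTR", "SVA"))
  expect_length(te, n_expected)
  expect_equal(attr(te, "n_excluded"), 10 - n_expected)
})

test_that("malformed TE rows raise errors naming the line", {
  bad <- write_te_table(list(c("chr1", 500, 400, "+", "L1HS", "LINE", "L1", 1)))
  expect_error(parse_te_annotation(bad), "start >= end.*line 1")
  neg <- write_te_table(list(c("chr1", 1, 400, "+", "L1HS", "LINE", "L1", -2)))
  expect_error(parse_te_annotation(neg), "divergence")
})

test_that("FLI-L1 classification needs >6 kb and all four intact flags", {
  te <- make_te_gr("chr1", c(1000, 20000), c(7999, 25499))
  flags <- data.frame(element_id = te$element_id,
                      orf1_intact = TRUE, orf2_intact = TRUE,
                      utr5_intact = TRUE, utr3_intact = TRUE)
  fli <- classify_fli_l1(te, flags)
  expect_equal(fli$element_id, "el001")   # 7000 bp in, 5500 bp out
  expect_equal(fli$length_bp, 7000)

  flags$orf2_intact[1] <- FALSE
  expect_equal(nrow(classify_fli_l1(te, flags)), 0)
})

test_that("FLI-L1 calls match a per-element brute-force check", {
  set.seed(21)
  n <- 20
  te <- make_te_gr("chr1", seq(1, by = 20000, length.out = n),
                   seq(1, by = 20000, length.out = n) +
                     sample(c(5000, 6500, 7000), n, replace = TRUE) - 1)
  flags <- data.frame(element_id = te$element_id,
                      orf1_intact = sample(c(TRUE, FALSE), n, replace = TRUE),
                      orf2_intact = sample(c(TRUE, FALSE), n, replace = TRUE),
                      utr5_intact = sample(c(TRUE, FALSE), n, replace = TRUE),
                      utr3_intact = sample(c(TRUE, FALSE), n, replace = TRUE))
  expected <- te$element_id[
    GenomicRanges::width(te) > 6000 & flags$orf1_intact & flags$orf2_intact &
      flags$utr5_intact & flags$utr3_intact]
  fli <- classify_fli_l1(te, flags)
  expect_setequal(fli$element_id, expected)

  # classification is a subset of input and idempotent on its own output
  expect_true(all(fli$element_id %in% te$element_id))
  again <- classify_fli_l1(te[te$element_id %in% fli$element_id], flags)
  expect_setequal(again$element_id, fli$element_id)
})

test_that("fragments without intactness flags are skipped with a warning", {
  te <- make_te_gr("chr1", c(1, 10000), c(7000, 17000))
  flags <- data.frame(element_id = "el001", orf1_intact = TRUE,
                      orf2_intact = TRUE, utr5_intact = TRUE,
                      utr3_intact = TRUE)
  expect_warning(fli <- classify_fli_l1(te, flags), "lack intactness")
  expect_equal(fli$element_id, "el001")
})

test_that("ORF scan flags stop-free frames of sufficient length", {
  orf <- paste(rep("ATG", 400), collapse = "")           # 1200 bp stop-free
  # 10-bp unit: 10 mod 3 = 1, so the stops cycle through all three frames
  stops <- paste(rep("TAATAGTGAC", 126), collapse = "")
  seqs <- Biostrings::DNAStringSet(c(a = orf, b = stops))
  res <- scan_orf_intactness(seqs, orf1_min = 900, orf2_min = 3500,
                             full_length_bp = 1000)
  expect_true(res$orf1_intact[res$element_id == "a"])
  expect_false(res$orf2_intact[res$element_id == "a"])  # only 1200 bp
  expect_false(res$orf1_intact[res$element_id == "b"])
})

test_that("subfamily ages drive the hominoid-specific flag", {
  te <- make_te_gr("chr1", c(1, 10, 20, 30) * 1000,
                   c(7, 16, 26, 36) * 1000,
                   subfamily = c("L1HS", "L1PA7", "L1XX", "AluY"),
                   family = c("L1", "L1", "L1", "Alu"))
  te <- assign_subfamily_ages(te)
  expect_true(te$hominoid_specific[te$subfamily == "L1HS"])
  expect_false(te$hominoid_specific[te$subfamily == "L1PA7"])
  expect_false(te$age_known[te$subfamily == "L1XX"])
  expect_false(te$hominoid_specific[te$subfamily == "L1XX"])
  # AluY is young-ish but not an L1, so never hominoid-flagged
  expect_false(te$hominoid_specific[te$subfamily == "AluY"])
  expect_true(all(te$hominoid_specific ==
                    (te$age_known & te$family == "L1" & te$age_my < 12.5)))
})

test_that("exon-overlapping TEs are removed with half-open adjacency kept", {
  te <- make_te_gr("chr1", c(101, 101), c(200, 200))
  te$element_id <- c("hit", "adj")
  te <- te[1]
  genes <- make_genes_obj(data.frame(
    gene_id = "g1", chrom = "chr1", strand = "+",
    exon_start = I(list(151)), exon_end = I(list(160))))
  expect_length(filter_nonexonic(te, genes), 0)

  # BED [100,200) vs exon [200,300): converted 1-based they touch but
  # do not share a base
  genes2 <- make_genes_obj(data.frame(
    gene_id = "g1", chrom = "chr1", strand = "+",
    exon_start = I(list(201)), exon_end = I(list(300))))
  expect_length(filter_nonexonic(te, genes2), 1)
})

test_that("exon filtering agrees with a per-base brute-force oracle", {
  set.seed(31)
  n_te <- 200; n_ex <- 50; genome <- 100000
  te <- make_te_gr("chr1", s <- sample(genome - 600, n_te),
                   s + sample(50:500, n_te, replace = TRUE))
  ex_start <- sample(genome - 600, n_ex)
  exons <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(ex_start, ex_start + sample(50:400, n_ex, TRUE)),
    strand = sample(c("+", "-"), n_ex, TRUE),
    transcript_id = "t", gene_id = "g", coding = TRUE)

  occupied <- logical(genome)
  for (i in seq_len(n_ex))
    occupied[GenomicRanges::start(exons)[i]:GenomicRanges::end(exons)[i]] <- TRUE
  keep_oracle <- vapply(seq_len(n_te), function(i)
    !any(occupied[GenomicRanges::start(te)[i]:GenomicRanges::end(te)[i]]),
    logical(1))

  kept <- filter_nonexonic(te, exons)
  expect_setequal(kept$element_id, te$element_id[keep_oracle])

  # monotone: adding exons never increases the surviving set
  kept2 <- filter_nonexonic(te, exons[1:25])
  expect_true(all(kept$element_id %in% kept2$element_id))
})
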