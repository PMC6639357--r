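chip_read <- function(qname, chrom, pos, len = 50, mapq = 30L,
                      flag = 0L) {
  data.frame(qname = qname, flag = flag, rname = chrom, pos = pos,
             mapq = mapq, cigar = sprintf("%dM", len), rnext = "*",
             pnext = 0L, tlen = 0L, seq = "*", tags = "NH:i:1",
             stringsAsFactors = FALSE)
}

test_that("coverage lands in the read's bins and MAPQ filters apply", {
  recs <- rbind(chip_read("a", "chr1", 101, 50),
                chip_read("low", "chr1", 501, 50, mapq = 5L))
  p <- write_test_sam(recs, c(chr1 = 1000L))
  tr <- coverage_track(p, bin_bp = 10)
  expect_equal(tr$n_reads, 1)           # MAPQ 5 read excluded
  v <- tr$values$chr1
  expect_true(all(v[11:15] > 0))        # bases 101-150 = bins 11-15
  expect_true(all(v[-(11:15)] == 0))
})

test_that("CPM scaling sums to 1e6 x read span over bin width", {
  set.seed(81)
  pos <- sample(900, 200) + 1
  recs <- do.call(rbind, lapply(seq_along(pos), function(i)
    chip_read(sprintf("r%03d", i), "chr1", pos[i], 50)))
  p <- write_test_sam(recs, c(chr1 = 2000L))
  tr <- coverage_track(p, bin_bp = 10)
  expect_equal(sum(tr$values$chr1), 1e6 * 50 / 10, tolerance = 0.01)
})

test_that("track combination follows the replicate-mean and log2-ratio formulas", {
  mk <- function(vals) structure(
    list(values = list(chr1 = vals), bin_bp = 10L,
         normalization = "raw-coverage", n_reads = 100L,
         seqlengths = c(chr1 = length(vals) * 10L)),
    class = "signal_track")
  a <- mk(c(1, 2, 3, 4)); b <- mk(c(3, 2, 1, 0))
  m <- combine_tracks(list(a, b), "replicate-mean")
  expect_equal(m$values$chr1, c(2, 2, 2, 2))
  expect_equal(combine_tracks(list(a, a), "replicate-mean")$values$chr1,
               a$values$chr1)                    # idempotent on identical
  lr <- combine_tracks(list(a, b), "log2-ratio", pseudocount = 1)
  expect_equal(lr$values$chr1, log2((c(1, 2, 3, 4) + 1) / (c(3, 2, 1, 0) + 1)))
  expect_equal(combine_tracks(list(a, a), "log2-ratio")$values$chr1,
               rep(0, 4))                        # IP = input everywhere
  bad <- mk(c(1, 2, 3))
  expect_error(combine_tracks(list(a, bad)), "mismatch")
})

test_that("constant tracks give constant heatmaps for long elements", {
  mk <- function(vals) structure(
    list(values = list(chr1 = vals), bin_bp = 10L,
         normalization = "raw-coverage", n_reads = 100L,
         seqlengths = c(chr1 = length(vals) * 10L)),
    class = "signal_track")
  tr <- mk(rep(1, 2000))
  el <- make_te_gr("chr1", c(3000, 9000), c(8999, 15000),
                   strand = c("+", "-"))
  hm <- element_heatmap(tr, el, body_bins = 20, flank_bp = 500,
                        flank_bins = 5)
  expect_equal(dim(hm), c(2L, 30L))
  expect_true(all(hm == 1))
  expect_false(any(attr(hm, "short_rows")))
})

test_that("5' signal appears on the left for both strands (orientation flip)", {
  vals <- rep(0, 2000)
  vals[300:310] <- 5      # 5' end of the + element at 3000
  vals[1490:1500] <- 5    # 5' end of the - element at 15000
  tr <- structure(list(values = list(chr1 = vals), bin_bp = 10L,
                       normalization = "raw-coverage", n_reads = 100L,
                       seqlengths = c(chr1 = 20000L)),
                  class = "signal_track")
  el <- make_te_gr("chr1", c(3000, 9000), c(8999, 15000),
                   strand = c("+", "-"))
  hm <- element_heatmap(tr, el, body_bins = 20, flank_bp = 500,
                        flank_bins = 5)
  body <- hm[, 6:25]
  expect_equal(unname(apply(body, 1, which.max)), c(1, 1))

  # flipping the strand annotation twice restores each row exactly
  el_flip <- el
  GenomicRanges::strand(el_flip) <- ifelse(
    as.character(GenomicRanges::strand(el)) == "+", "-", "+")
  hm_flip <- element_heatmap(tr, el_flip, body_bins = 20, flank_bp = 500,
                             flank_bins = 5)
  expect_equal(unname(hm_flip[1, ]), rev(unname(hm[1, ])))
  expect_equal(unname(hm_flip[2, ]), rev(unname(hm[2, ])))
})

test_that("short elements are interpolated and flagged", {
  tr <- structure(list(values = list(chr1 = seq(0, 1, length.out = 200)),
                       bin_bp = 10L, normalization = "raw-coverage",
                       n_reads = 10L, seqlengths = c(chr1 = 2000L)),
                  class = "signal_track")
  el <- make_te_gr("chr1", 1000, 1009)      # 10 bp << 20 body bins
  hm <- element_heatmap(tr, el, body_bins = 20, flank_bp = 100,
                        flank_bins = 2)
  expect_true(attr(hm, "short_rows")[1])
  expect_false(any(is.na(hm[1, 3:22])))
})

test_that("knockout H3K27ac metaprofiles peak at young-L1 5' ends only", {
  sim <- default_sim()
  ca <- default_chip_amp()
  tr1 <- coverage_track(ca$chip$paths[["H3K27ac_ko_rep1"]])
  tr2 <- coverage_track(ca$chip$paths[["H3K27ac_ko_rep2"]])
  ip <- combine_tracks(list(tr1, tr2), "replicate-mean")
  lr <- combine_tracks(list(ip, coverage_track(ca$chip$paths[["input_ko"]])),
                       "log2-ratio")
  te <- default_te_annotation()
  fus <- default_sim()$truth$te$element_id[default_sim()$truth$te$fusion_promoter]
  young <- te[te$hominoid_specific & !te$element_id %in% fus &
                GenomicRanges::width(te) > 6000]
  old <- te[!te$hominoid_specific & GenomicRanges::width(te) > 3000]
  hm_y <- element_heatmap(lr, young)
  hm_o <- element_heatmap(lr, old)
  ct <- attr(hm_y, "column_type")
  body <- which(ct == "body")
  py <- colMeans(hm_y, na.rm = TRUE)[body]
  po <- colMeans(hm_o, na.rm = TRUE)[body]
  # young: maximum bin in the 5'-most fifth of the body; old: flat
  expect_lte(which.max(py), length(body) / 5)
  q <- length(body) %/% 4
  expect_gt(mean(py[1:q]), 2 * mean(py[(length(body) - q):length(body)]))
  expect_lt(mean(po[1:q]), 1.3 * mean(po[(length(body) - q):length(body)]) + 0.2)
})
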