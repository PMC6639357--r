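test_that("CIGAR deletions in the window are extracted with correct net length", {
  ref <- amp_ref()
  recs <- rbind(del_read("d3", ref, 640, 710, 3),
                perfect_read("ok", ref, 600, 200),
                perfect_read("short", ref, 720, 100))  # misses the window
  p <- write_test_sam(recs, c(amplicon = 1400L))
  calls <- call_read_indels(p, cut_pos = 700, flank_bp = 10, reference = ref)
  expect_equal(calls$n_informative, 2)   # "short" is uninformative
  expect_equal(calls$n_uninformative, 1)
  expect_equal(calls$n_unmodified, 1)
  ev <- calls$events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$net_length, -3)
  expect_equal(ev$ref_allele, substr(ref, 710, 712))
})

test_that("indels outside the flanked window leave reads unmodified", {
  ref <- amp_ref()
  recs <- del_read("far", ref, 600, 650, 2)   # deletion at 650, window 690-710
  p <- write_test_sam(recs, c(amplicon = 1400L))
  calls <- call_read_indels(p, 700, 10, ref)
  expect_equal(calls$n_unmodified, 1)
  expect_equal(nrow(calls$events), 0)
})

test_that("mixed insertions and deletions on one read collapse to a complex event", {
  ref <- amp_ref()
  # 60M 2D 5M 3I 85M starting at 650: D at 710-711, I after 716
  seq <- paste0(substr(ref, 650, 709), substr(ref, 712, 716), "ACG",
                substr(ref, 717, 801))
  recs <- amp_read("cx", 650, "60M2D5M3I85M", seq)
  p <- write_test_sam(recs, c(amplicon = 1400L))
  calls <- call_read_indels(p, 700, 20, ref)
  ev <- calls$events
  expect_equal(ev$kind, "complex")
  expect_equal(ev$net_length, 1)   # -2 + 3
  expect_equal(ev$ref_allele, substr(ref, 710, 716))
  expect_equal(ev$alt_allele, paste0(substr(ref, 712, 716), "ACG"))
})

test_that("deleting any base of a homopolymer run left-aligns to the run start", {
  ref <- paste0("TGCT", "AAAA", "CGTCGT")   # run at positions 5-8
  edited <- vapply(5:8, function(p)
    paste0(substr(ref, 1, p - 1), substr(ref, p + 1, nchar(ref))),
    character(1))
  expect_length(unique(edited), 1)          # enumeration: all equivalent
  canon <- lapply(5:8, function(p) canonicalize_indel(p, "A", "", ref))
  expect_true(all(vapply(canon, `[[`, numeric(1), "pos") == 5))
  expect_length(unique(vapply(canon, `[[`, character(1), "ref_allele")), 1)
})

test_that("insertions shift left through a dinucleotide repeat", {
  ref <- paste0("G", "ATATAT", "CCGG")      # (AT)x3 at positions 2-7
  # inserting AT before positions 2, 4, 6, 8 gives the same sequence
  edited <- vapply(c(2, 4, 6, 8), function(p)
    paste0(substr(ref, 1, p - 1), "AT", substr(ref, p, nchar(ref))),
    character(1))
  expect_length(unique(edited), 1)
  canon <- lapply(c(2, 4, 6, 8), function(p)
    canonicalize_indel(p, "", "AT", ref))
  expect_true(all(vapply(canon, `[[`, numeric(1), "pos") == 2))
})

test_that("canonicalization is idempotent and fixed in non-repetitive context", {
  ref <- "GACTGACCTGA"
  c1 <- canonicalize_indel(5, "G", "", ref)
  expect_equal(c1$pos, 5)
  expect_equal(c1$ref_allele, "G")
  c2 <- canonicalize_indel(c1$pos, c1$ref_allele, c1$alt_allele, ref)
  expect_equal(c1, c2)
  expect_error(canonicalize_indel(5, "T", "", ref), "inconsistent")
})

test_that("frame classes follow the mod-3 rule and an edit-string oracle", {
  ref <- amp_ref()
  recs <- rbind(del_read("d3", ref, 640, 700, 3),
                ins_read("i2", ref, 640, 700, "CT"),
                del_read("d1", ref, 640, 695, 1),
                perfect_read("u1", ref, 600, 200))
  p <- write_test_sam(recs, c(amplicon = 1400L))
  res <- tally_indels(call_read_indels(p, 700, 10, ref), ref)
  fc <- setNames(res$tally$frame_class,
                 sprintf("%d", res$tally$net_length))
  expect_equal(unname(fc["-3"]), "in-frame")
  expect_equal(unname(fc["2"]), "frameshift")
  expect_equal(unname(fc["-1"]), "frameshift")

  # oracle: apply each unique edit to the reference and compare the
  # length change of the actual edited string modulo 3
  for (i in seq_len(nrow(res$tally))) {
    t1 <- res$tally[i, ]
    edited <- paste0(substr(ref, 1, t1$pos - 1), t1$alt_allele,
                     substr(ref, t1$pos + nchar(t1$ref_allele), nchar(ref)))
    preserved <- (nchar(edited) - nchar(ref)) %% 3 == 0
    expect_equal(t1$frame_class == "in-frame", preserved)
  }
})

test_that("tally frequencies and the modification summary are coherent", {
  ref <- amp_ref()
  recs <- do.call(rbind, c(
    lapply(1:93, function(i) del_read(sprintf("d%03d", i), ref, 640, 700, 3)),
    lapply(1:7, function(i) perfect_read(sprintf("u%03d", i), ref, 600, 200))))
  p <- write_test_sam(recs, c(amplicon = 1400L))
  res <- tally_indels(call_read_indels(p, 700, 10, ref), ref)
  expect_equal(res$summary$pct_modified, 93.0)
  expect_equal(sum(res$tally$frequency) +
                 res$summary$total_reads - res$summary$modified_reads >= 0, TRUE)
  expect_equal(sum(res$tally$frequency) +
                 (res$summary$total_reads - res$summary$modified_reads) /
                 res$summary$total_reads, 1, tolerance = 1e-9)
})

test_that("the tally is invariant to read order", {
  ref <- amp_ref()
  recs <- rbind(del_read("a", ref, 640, 700, 3),
                ins_read("b", ref, 650, 701, "G"),
                del_read("c", ref, 660, 700, 3),
                perfect_read("d", ref, 600, 200))
  p1 <- write_test_sam(recs, c(amplicon = 1400L))
  set.seed(67)
  p2 <- write_test_sam(recs[sample(nrow(recs)), ], c(amplicon = 1400L))
  r1 <- tally_indels(call_read_indels(p1, 700, 10, ref), ref)
  r2 <- tally_indels(call_read_indels(p2, 700, 10, ref), ref)
  expect_equal(r1$tally, r2$tally)
  expect_equal(r1$summary, r2$summary)
})

test_that("a planted 0.4/0.3/0.2 spectrum is recovered within 0.03 at n = 2000", {
  ref <- amp_ref(seed = 71)
  set.seed(73)
  n <- 2000
  kind <- sample(1:4, n, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  pos <- 700 - sample(150:250, n, replace = TRUE)
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    q <- sprintf("r%05d", i)
    switch(kind[i],
           del_read(q, ref, pos[i], 700, 3, read_len = 400),
           ins_read(q, ref, pos[i], 700, "TTG", read_len = 400),
           del_read(q, ref, pos[i], 699, 5, read_len = 400),
           perfect_read(q, ref, pos[i], 400))
  }))
  p <- write_test_sam(recs, c(amplicon = 1400L))
  res <- tally_indels(call_read_indels(p, 700, 10, ref), ref)
  expect_equal(nrow(res$tally), 3)        # unique event list exact
  freq <- sort(res$tally$frequency, decreasing = TRUE)
  expect_true(all(abs(freq - c(0.4, 0.3, 0.2)) < 0.03))
  expect_lt(abs(res$summary$pct_modified - 90), 3)
})
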