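# SV extraction from alignment geometry, per-cell and bulk filtering,
# cross-cell consensus merging, benchmarking metrics, NGS-style matching, and
# the duplication placement test.

test_that("large CIGAR deletions become DEL calls; small ones are ignored", {
  aln <- seg_row("r1", 1, 0, 2000, "chr1", 10000, 14000,
                 cigar = "1000M2000D1000M")
  calls <- extract_cell_svs(aln)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$svtype, "DEL")
  expect_equal(calls$start, 11000)
  expect_equal(calls$end, 13000)
  expect_equal(calls$svlen, -2000)

  small <- seg_row("r2", 1, 0, 2000, "chr1", 10000, 12030,
                   cigar = "1000M30D1000M")
  expect_equal(nrow(extract_cell_svs(small)), 0)
})

test_that("cross-chromosome split pairs become TRA calls at junction ends", {
  aln <- dplyr::bind_rows(
    seg_row("r1", 1, 0, 3000, "chr1", 20000, 23000, read_length = 6000),
    seg_row("r1", 2, 3000, 6000, "chr5", 50000, 53000, read_length = 6000))
  calls <- extract_cell_svs(aln)
  expect_equal(calls$svtype, "TRA")
  expect_equal(calls$chrom, "chr1")
  expect_equal(calls$start, 23000)   # end of the read-earlier segment
  expect_equal(calls$chrom2, "chr5")
  expect_equal(calls$pos2, 50000)    # start of the read-later segment
})

test_that("opposite-strand pairs become INV and colinear split pairs DEL", {
  inv <- dplyr::bind_rows(
    seg_row("r1", 1, 0, 3000, "chr2", 10000, 13000, read_length = 6000),
    seg_row("r1", 2, 3000, 6000, "chr2", 13000, 16000, strand = "-",
            read_length = 6000))
  calls <- extract_cell_svs(inv)
  expect_equal(calls$svtype, "INV")

  del <- dplyr::bind_rows(
    seg_row("r2", 1, 0, 3000, "chr2", 10000, 13000, read_length = 6000),
    seg_row("r2", 2, 3000, 6000, "chr2", 18000, 21000, read_length = 6000))
  calls <- extract_cell_svs(del)
  expect_equal(calls$svtype, "DEL")
  expect_equal(c(calls$start, calls$end), c(13000, 18000))
})

test_that("chiastic pairs extending beyond the junction span become DUP calls", {
  # segments run past the duplicated unit [20000, 24000): duplication evidence
  dup <- dplyr::bind_rows(
    seg_row("r1", 1, 0, 3000, "chr3", 21000, 24000, read_length = 8000),
    seg_row("r1", 2, 3000, 8000, "chr3", 20000, 25000, read_length = 8000))
  calls <- extract_cell_svs(dup)
  expect_equal(calls$svtype, "DUP")
  expect_equal(c(calls$start, calls$end), c(20000, 24000))

  # confined pair (circle-shaped): left to the ecDNA stage, no DUP call
  circ <- dplyr::bind_rows(
    seg_row("r2", 1, 0, 3000, "chr3", 21000, 24000, read_length = 7000),
    seg_row("r2", 2, 3000, 7000, "chr3", 20000, 24000, read_length = 7000))
  expect_equal(nrow(extract_cell_svs(circ)), 0)
})

test_that("per-cell read filtration keeps only PASS calls with enough reads", {
  calls <- sv_calls("DEL", "chr1", c(100, 200, 300), c(1100, 1200, 1300),
                    read_support = c(2L, 10L, 1L),
                    filter = c("PASS", "IMPRECISE", "PASS"))
  kept <- filter_cell_calls(calls)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$start, 100)
})

test_that("bulk filtration applies the read floor and the strict ratio rule", {
  calls <- sv_calls("DEL", "chr1", c(100, 200, 300), c(1100, 1200, 1300),
                    read_support = c(4L, 4L, 3L),
                    total_depth = c(20L, 40L, 10L))
  kept <- filter_bulk_calls(calls)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$start, 100)   # 4/20 = 0.20 > 0.15; 4/40 = 0.10 fails; 3 reads fail

  zero_depth <- sv_calls("DEL", "chr1", 500, 1500, read_support = 5L,
                         total_depth = 0L)
  expect_warning(out <- filter_bulk_calls(zero_depth), "without depth")
  expect_equal(nrow(out), 0)
})

test_that("merging links same-type calls within 1 kb and unions their cells", {
  a <- sv_calls("DEL", "chr1", c(1000, 1500), c(2000, 2500),
                read_support = 2L, cell_id = "cellA")
  b <- sv_calls("DEL", "chr1", c(1000, 1500), c(2000, 2500),
                read_support = 2L, cell_id = "cellB")
  merged <- merge_across_cells(list(a, b))
  expect_equal(nrow(merged), 1)   # 500 <= 1000 on both breakpoints: one cluster
  expect_equal(merged$cells[[1]], c("cellA", "cellB"))
  expect_equal(merged$n_cells, 2L)

  # different types at identical positions never merge
  mix <- dplyr::bind_rows(
    sv_calls("DEL", "chr1", 1000, 2000, cell_id = "cellA"),
    sv_calls("INS", "chr1", 1000, 2000, svlen = 100, cell_id = "cellB"))
  expect_equal(nrow(merge_across_cells(mix, min_cells = 1)), 2)

  # single cell with min_cells = 1 is the identity up to consensus
  # coordinates, for calls farther apart than the merge distance
  solo <- sv_calls("DEL", "chr1", c(1000, 50000), c(2000, 51000),
                   read_support = 2L, cell_id = "cellA")
  merged1 <- merge_across_cells(list(solo), min_cells = 1)
  expect_equal(nrow(merged1), 2)
  expect_setequal(merged1$start, c(1000, 50000))
})

test_that("merging is invariant under cell permutation and idempotent on separated clusters", {
  withr::with_seed(60, {
    centers <- seq(10000, 400000, by = 20000)  # clusters are >> 1 kb apart
    callsets <- lapply(paste0("cell", 1:5), function(cid) {
      pick <- sort(sample(seq_along(centers), 12))
      sv_calls("DEL", "chr1", centers[pick] + sample(-300:300, 12, TRUE),
               centers[pick] + 5000 + sample(-300:300, 12, TRUE),
               read_support = 2L, cell_id = cid)
    })
  })
  m1 <- merge_across_cells(callsets)
  m2 <- merge_across_cells(rev(callsets))
  expect_equal(as.data.frame(m1), as.data.frame(m2))
  again <- merge_across_cells(m1 |> dplyr::mutate(cell_id = NA_character_),
                              min_cells = 2)
  expect_equal(again$start, m1$start)
  expect_equal(again$end, m1$end)
  expect_equal(again$cells, m1$cells)
})

test_that("compute_metrics reproduces the printed formulas and conventions", {
  m <- compute_metrics(5, 0, 0)
  expect_equal(unlist(m[, c("precision", "recall", "fpr", "fnr", "hm", "f1")]),
               c(precision = 1, recall = 1, fpr = 0, fnr = 0, hm = 0, f1 = 1))

  m <- compute_metrics(3, 1, 2)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$fpr, 0.25)
  expect_equal(m$fnr, 0.4)
  expect_equal(m$hm, 2 * 0.25 * 0.4 / 0.65, tolerance = 1e-12)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)

  # 0/0 is explicit NA, not silent 0
  m <- compute_metrics(0, 0, 3)
  expect_true(is.na(m$precision) && is.na(m$fpr))
  expect_error(compute_metrics(-1, 0, 0), "non-negative")
})

test_that("benchmarking test = truth gives perfect metrics", {
  truth <- random_calls(20, seed = 71)
  bm <- benchmark_svs(truth, truth)
  expect_equal(bm$metrics$precision, 1)
  expect_equal(bm$metrics$recall, 1)
  expect_equal(bm$metrics$hm, 0)
})

test_that("multimatch allows several test calls per truth call", {
  truth <- sv_calls("DEL", "chr1", 10000, 12000)
  test <- sv_calls("DEL", "chr1", c(10000, 10500), c(12000, 12500))
  bm <- benchmark_svs(test, truth, multimatch = TRUE)
  expect_equal(bm$metrics$tp, 2)
  bm1 <- benchmark_svs(test, truth, multimatch = FALSE)
  expect_equal(bm1$metrics$tp, 1)
  expect_equal(bm1$metrics$fp, 1)
})

test_that("NGS-style matching uses strict reciprocal overlap and INS distance", {
  a <- sv_calls("DEL", "chr1", 1000, 2000, svlen = -1000)
  b <- sv_calls("DEL", "chr1", 1900, 3000, svlen = -1100)
  expect_equal(nrow(match_ngs_style(a, b)), 0)  # 100/1000 = 0.10, not > 0.10

  expect_equal(nrow(match_ngs_style(a, a)), 1)

  i1 <- sv_calls("INS", "chr1", 5000, 5001, svlen = 200)
  i2 <- sv_calls("INS", "chr1", 5999, 6000, svlen = 300)
  i3 <- sv_calls("INS", "chr1", 6100, 6101, svlen = 300)
  expect_equal(nrow(match_ngs_style(i1, i2)), 1)
  expect_equal(nrow(match_ngs_style(i1, i3)), 0)

  expect_error(match_ngs_style(sv_calls("DUP", "chr1", 1, 10), a),
               "only DEL and INS")
})

test_that("indel length filtering removes sub-100 bp DEL/INS only", {
  calls <- dplyr::bind_rows(
    sv_calls("DEL", "chr1", 100, 180, svlen = -80),
    sv_calls("INS", "chr1", 500, 501, svlen = 99),
    sv_calls("INS", "chr1", 900, 901, svlen = 100),
    sv_calls("INV", "chr1", 2000, 2050, svlen = 50))
  kept <- filter_short_indels(calls)
  expect_setequal(kept$svtype, c("INS", "INV"))
  expect_equal(kept$start[kept$svtype == "INS"], 900)
})

test_that("the telomere placement test is calibrated and powered", {
  arms <- tibble::tibble(chrom = "chr1", start = c(0, 45e6),
                         end = c(45e6, 100e6), arm = c("p", "q"))
  # perfectly even counts: statistic 0, p = 1
  even_pos <- 45e6 + (seq_len(100) - 0.5) / 100 * 55e6
  even <- sv_calls("DUP", "chr1", round(even_pos), round(even_pos) + 1000)
  res <- duplication_telomere_test(even, arms)
  expect_equal(res$statistic, 0, tolerance = 1e-9)
  expect_equal(res$p_value, 1)

  withr::with_seed(81, {
    u <- runif(500)
    unif_pos <- 45e6 + u * 55e6
    unif <- sv_calls("DUP", "chr1", round(unif_pos), round(unif_pos) + 1000)
    expect_gt(duplication_telomere_test(unif, arms)$p_value, 0.01)

    r <- c(runif(200), runif(300, 0.9, 1))   # 60% in the last decile
    tel_pos <- pmin(45e6 + r * 55e6, 100e6 - 2000)
    tel <- sv_calls("DUP", "chr1", round(tel_pos), round(tel_pos) + 1000)
    expect_lt(duplication_telomere_test(tel, arms)$p_value, 1e-3)
  })

  outside <- sv_calls("DUP", "chr2", 100, 1100)
  expect_warning(
    expect_error(duplication_telomere_test(outside, arms), "no duplications"),
    "skipped")
})
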