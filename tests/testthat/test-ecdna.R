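# The ecDNA pipeline: chiastic geometry, the two filters, cross-cell merging,
# same-length evidence, and end-to-end recovery on simulated circles.

chiastic_read <- function(read_id, cell_id = "cellA", circle_start = 4000,
                          circle_end = 6000, cut = 1200, strand = "+") {
  b <- circle_start + cut
  L <- circle_end - circle_start
  if (strand == "+") {
    dplyr::bind_rows(
      seg_row(read_id, 1, 0, circle_end - b, "chr1", b, circle_end,
              strand = "+", read_length = L, cell_id = cell_id),
      seg_row(read_id, 2, circle_end - b, L, "chr1", circle_start, b,
              strand = "+", read_length = L, cell_id = cell_id,
              primary = FALSE))
  } else {
    # reverse-complement read: query order flips, both segments minus
    dplyr::bind_rows(
      seg_row(read_id, 1, 0, b - circle_start, "chr1", circle_start, b,
              strand = "-", read_length = L, cell_id = cell_id),
      seg_row(read_id, 2, b - circle_start, L, "chr1", b, circle_end,
              strand = "-", read_length = L, cell_id = cell_id,
              primary = FALSE))
  }
}

test_that("a chiastic two-segment read yields the forced circle geometry", {
  cand <- detect_chiastic_reads(chiastic_read("r1"))
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 4000)
  expect_equal(cand$end, 6000)
  expect_true(cand$full_length)
})

test_that("minus-strand chiastic reads are normalized to genome orientation", {
  cand <- detect_chiastic_reads(chiastic_read("r1", strand = "-"))
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$start, cand$end), c(4000, 6000))
})

test_that("non-qualifying reads yield no candidate", {
  one_seg <- seg_row("r1", 1, 0, 2000, "chr1", 4000, 6000)
  expect_equal(nrow(detect_chiastic_reads(one_seg)), 0)

  three <- dplyr::bind_rows(
    seg_row("r3", 1, 0, 700, "chr1", 5300, 6000, read_length = 2000),
    seg_row("r3", 2, 700, 1400, "chr1", 4000, 4700, read_length = 2000,
            primary = FALSE),
    seg_row("r3", 3, 1400, 2000, "chr1", 4700, 5300, read_length = 2000,
            primary = FALSE))
  expect_equal(nrow(detect_chiastic_reads(three)), 0)

  colinear <- dplyr::bind_rows(
    seg_row("r4", 1, 0, 1000, "chr1", 4000, 5000, read_length = 2000),
    seg_row("r4", 2, 1000, 2000, "chr1", 8000, 9000, read_length = 2000,
            primary = FALSE))
  expect_equal(nrow(detect_chiastic_reads(colinear)), 0)
})

test_that("query gaps beyond the tolerance disqualify a read", {
  wide <- dplyr::bind_rows(
    seg_row("r5", 1, 0, 800, "chr1", 5200, 6000, read_length = 2100),
    seg_row("r5", 2, 900, 2100, "chr1", 4000, 5200, read_length = 2100,
            primary = FALSE))
  expect_equal(nrow(detect_chiastic_reads(wide, max_query_gap = 50)), 0)
  expect_equal(nrow(detect_chiastic_reads(wide, max_query_gap = 150)), 1)
})

test_that("the repeat filter removes junctions in long repeats only", {
  cand <- detect_chiastic_reads(chiastic_read("r1"))
  long_rep <- genome_interval("chr1", 3000, 5500)   # 2500 bp, covers junction
  expect_equal(nrow(filter_tandem_repeats(cand, long_rep)), 0)
  short_rep <- genome_interval("chr1", 3500, 4300)  # 800 bp: ignored
  expect_equal(nrow(filter_tandem_repeats(cand, short_rep)), 1)
  none <- genome_interval("chr9", 1, 2)[0, ]
  expect_equal(nrow(filter_tandem_repeats(cand, none)), 1)
})

test_that("the duplication filter honors cell support and coordinate tolerance", {
  cand <- detect_chiastic_reads(chiastic_read("r1"))
  dup5 <- merge_across_cells(
    lapply(paste0("cell", 1:5), function(cid) {
      sv_calls("DUP", "chr1", 4010, 5990, svlen = 1980, read_support = 2L,
               cell_id = cid)
    }), min_cells = 4)
  expect_equal(nrow(filter_duplications(cand, dup5)), 0)

  dup3 <- merge_across_cells(
    lapply(paste0("cell", 1:3), function(cid) {
      sv_calls("DUP", "chr1", 4010, 5990, svlen = 1980, read_support = 2L,
               cell_id = cid)
    }), min_cells = 1)
  expect_equal(nrow(filter_duplications(cand, dup3)), 1)

  far <- merge_across_cells(
    lapply(paste0("cell", 1:5), function(cid) {
      sv_calls("DUP", "chr1", 4150, 5990, svlen = 1840, read_support = 2L,
               cell_id = cid)
    }), min_cells = 4)
  expect_equal(nrow(filter_duplications(cand, far)), 1)  # start delta 150 > 100
})

test_that("merging requires two cells and respects the 50 bp tolerance", {
  two_cells <- dplyr::bind_rows(
    detect_chiastic_reads(chiastic_read("r1", "cellA", cut = 1200)),
    detect_chiastic_reads(chiastic_read("r2", "cellB", cut = 700)))
  two_cells$start <- two_cells$start + c(0, 20)   # 20 bp jitter
  merged <- merge_ecdna(two_cells)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$cells[[1]], c("cellA", "cellB"))
  expect_equal(merged$n_reads, 2L)

  one_cell <- detect_chiastic_reads(chiastic_read("r1", "cellA"))
  expect_equal(nrow(merge_ecdna(one_cell)), 0)

  apart <- dplyr::bind_rows(
    detect_chiastic_reads(chiastic_read("r1", "cellA")),
    detect_chiastic_reads(chiastic_read("r2", "cellB")))
  apart$start[2] <- apart$start[2] + 200
  apart$end[2] <- apart$end[2] + 200
  expect_equal(nrow(merge_ecdna(apart, min_cells = 1)), 2)
})

test_that("same-length evidence groups full-length reads and flags heterogeneity", {
  reads <- dplyr::bind_rows(
    detect_chiastic_reads(chiastic_read("r1", "cellA")),
    detect_chiastic_reads(chiastic_read("r2", "cellA")),
    detect_chiastic_reads(chiastic_read("r3", "cellB")))
  reads$read_length <- c(2000, 2001, 1999)
  merged <- same_length_evidence(merge_ecdna(reads), reads)
  expect_equal(merged$modal_reads, 3L)
  expect_equal(merged$modal_cells, 2L)
  expect_false(merged$length_heterogeneous)

  dimer <- reads[1:2, ]
  dimer$read_length <- c(2000, 4000)
  m2 <- same_length_evidence(
    merge_ecdna(dplyr::mutate(dimer, cell_id = c("cellA", "cellB"))), dimer)
  expect_equal(m2$n_length_groups, 2L)
  expect_true(m2$length_heterogeneous)

  junction_only <- reads
  junction_only$full_length <- FALSE
  m3 <- same_length_evidence(merge_ecdna(junction_only), junction_only)
  expect_true(is.na(m3$modal_length))
})

test_that("mitochondrial candidates are reported separately", {
  mito_reads <- dplyr::bind_rows(
    chiastic_read("m1", "cellA", circle_start = 0, circle_end = 16569,
                  cut = 5000),
    chiastic_read("m2", "cellB", circle_start = 0, circle_end = 16569,
                  cut = 9000))
  mito_reads$chrom <- "chrM"
  no_dups <- sv_calls(character(), character(), numeric(), numeric())
  res <- detect_ecdna(mito_reads, dup_calls = no_dups)
  expect_equal(nrow(res$candidates), 0)
  expect_equal(nrow(res$mito), 1)
  expect_equal(res$mito$end - res$mito$start, 16569)
})

test_that("planted circles are recovered from simulated cells at error rate 0", {
  circles <- tibble::tibble(chrom = "chr1",
                            start = c(5e5, 1.5e6), end = c(5.2e5, 1.58e6),
                            copies = 4, cell_fraction = 1)
  cfg <- sim_config(seed = 51, n_cells = 6, chrom_lengths = c(chr1 = 3e6),
                    per_cell_coverage = 0.5, circles = circles)
  sim <- simulate_dataset(cfg)
  res <- detect_ecdna(sim$alignments, trf_intervals = sim$reference$repeats)
  cand <- res$candidates
  # precision: every candidate matches a truth circle within 50 bp
  for (i in seq_len(nrow(cand))) {
    expect_true(any(abs(circles$start - cand$start[i]) <= 50 &
                      abs(circles$end - cand$end[i]) <= 50))
  }
  # every circle with chiastic reads in >= 2 cells is reported
  sup <- event_read_support(sim)
  detectable <- sup |> dplyr::filter(grepl("^circle", .data$event)) |>
    dplyr::count(.data$event) |> dplyr::filter(.data$n >= 2)
  for (e in detectable$event) {
    t <- sim$truth_circles[sim$truth_circles$event == e, ]
    expect_true(any(cand$chrom == t$chrom & abs(cand$start - t$start) <= 50 &
                      abs(cand$end - t$end) <= 50))
  }
})
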