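# The synthetic-data generator: determinism, Tn5 fragmentation statistics,
# forced alignment geometry of planted variants, coverage accounting, and the
# noise layer of emitted call sets.

test_that("identical configs give identical datasets", {
  cfg <- tiny_config(seed = 11,
                     circles = tibble::tibble(chrom = "chr1", start = 1e6,
                                              end = 1.01e6, copies = 2,
                                              cell_fraction = 1))
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(s1$origin, s2$origin)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  f1 <- file.path(d1, "cell001.sam"); f2 <- file.path(d2, "cell001.sam")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("build_reference emits the requested genome deterministically", {
  cfg <- sim_config(seed = 2, chrom_lengths = c(chrA = 5e6, chrB = 5e6),
                    n_cells = 1, emit_sequences = TRUE)
  ref <- build_reference(cfg)
  expect_equal(names(ref$sequences), c("chrA", "chrB"))
  expect_equal(unname(nchar(ref$sequences)), c(5e6, 5e6))
  ref2 <- build_reference(cfg)
  expect_identical(ref$sequences, ref2$sequences)
  # arms: p/q around a centromere, telomeres at the chromosome ends
  expect_equal(nrow(ref$arms), 4)
  expect_setequal(ref$arms$arm, c("p", "q"))
})

test_that("planted repeat-tract count sits in the Poisson 99% band", {
  cfg <- sim_config(seed = 8, chrom_lengths = c(chr1 = 10e6), n_cells = 1,
                    repeat_per_mb = 1)
  ref <- build_reference(cfg)
  n <- nrow(ref$repeats)
  expect_gte(n, qpois(0.005, 10))
  expect_lte(n, qpois(0.995, 10))
  expect_true(all(ref$repeats$end - ref$repeats$start > 1000))
})

test_that("fragment_tn5 tiles the molecule and hits the target mean length", {
  expect_equal(as.data.frame(fragment_tn5(5e4, 0)),
               data.frame(start = 0, end = 5e4))
  withr::with_seed(3, {
    f <- fragment_tn5(60e6, 1 / 6000)
    expect_equal(sum(f$end - f$start), 60e6)     # exact partition
    expect_equal(f$start[-1], f$end[-nrow(f)])   # contiguous
    expect_lt(abs(mean(f$end - f$start) - 6000) / 6000, 0.10)
  })
})

test_that("a single-cut circle read has forced chiastic geometry", {
  # circle chr1:4000-6000 cut at offset 1200 from the circle start
  pieces <- rbind(smoothsv:::m_piece("chr1", 5200, 6000),
                  smoothsv:::m_piece("chr1", 4000, 5200))
  mol <- smoothsv:::new_molecule("c", pieces, circular = TRUE)
  segs <- smoothsv:::fragment_to_segments(mol, 0, 2000)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$start, c(5200, 4000))
  expect_equal(segs$end, c(6000, 5200))
  expect_equal(segs$query_start, c(0, 800))
  expect_equal(segs$query_end, c(800, 2000))
  expect_equal(segs$strand, c("+", "+"))
})

test_that("reads spanning a homozygous deletion carry the deletion in CIGAR", {
  # 2 haplotypes bound attainable depth below ~1.9x, so spread the sampling
  # over a few cells to make a junction-spanning read near-certain
  cfg <- sim_config(seed = 6, n_cells = 4, chrom_lengths = c(chr1 = 1e6),
                    per_cell_coverage = 1.5,
                    svs = tibble::tibble(svtype = "DEL", chrom = "chr1",
                                         start = 5e5, end = 5.02e5,
                                         cell_fraction = 1))
  sim <- simulate_dataset(cfg)
  expect_gt(sum(grepl("2000D", sim$alignments$cigar)), 0)
  # and those reads are recorded as supporting the event
  sup <- event_read_support(sim)
  expect_gt(sum(sup$n_reads[sup$event == "sv1"]), 0)
})

test_that("per-cell read count matches the coverage target", {
  cfg <- sim_config(seed = 12, n_cells = 3, chrom_lengths = c(chr1 = 10e6),
                    per_cell_coverage = 0.4)
  sim <- simulate_dataset(cfg)
  expected <- 0.4 * 10e6 / 6000
  counts <- table(sim$origin$cell_id)
  expect_true(all(abs(counts - expected) / expected < 0.2))
  # conservation: emitted bases match the target within one read
  for (cid in sim$cells) {
    bases <- sum(sim$origin$read_length[sim$origin$cell_id == cid])
    expect_lt(abs(bases - 0.4 * 10e6), max(sim$origin$read_length))
  }
})

test_that("every emitted read appears exactly once in the origin table", {
  cfg <- tiny_config(seed = 5)
  sim <- simulate_dataset(cfg)
  expect_false(any(duplicated(sim$origin$read_id)))
  expect_setequal(unique(sim$alignments$read_id), sim$origin$read_id)
})

test_that("no chiastic artifacts arise without circles or duplications", {
  cfg <- sim_config(seed = 14, n_cells = 3, chrom_lengths = c(chr1 = 5e6),
                    per_cell_coverage = 0.4,
                    svs = tibble::tibble(svtype = c("DEL", "INS"),
                                         chrom = "chr1",
                                         start = c(1e6, 3e6),
                                         end = c(1.005e6, 3e6 + 1),
                                         svlen = c(-5000, 500),
                                         cell_fraction = 1))
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(detect_chiastic_reads(sim$alignments)), 0)
})

test_that("emit_cell_callsets at zero noise only emits truth-backed calls", {
  cfg <- sim_config(seed = 21, n_cells = 4, chrom_lengths = c(chr1 = 5e6),
                    per_cell_coverage = 0.5, fp_sv_per_cell = 0,
                    svs = tibble::tibble(svtype = "DEL", chrom = "chr1",
                                         start = 2e6, end = 2.003e6,
                                         cell_fraction = 1))
  sim <- simulate_dataset(cfg)
  callsets <- emit_cell_callsets(sim)
  all_calls <- dplyr::bind_rows(callsets)
  expect_true(all(all_calls$svtype == "DEL"))
  expect_true(all(all_calls$start == 2e6 & all_calls$end == 2.003e6))
})

test_that("spurious calls appear at the configured Poisson rate, private to cells", {
  cfg <- sim_config(seed = 22, n_cells = 10, chrom_lengths = c(chr1 = 5e6),
                    per_cell_coverage = 0.2, fp_sv_per_cell = 20)
  sim <- simulate_dataset(cfg)
  callsets <- emit_cell_callsets(sim)
  n_fp <- sum(vapply(callsets, nrow, integer(1)))
  lambda <- 20 * 10
  expect_gte(n_fp, qpois(0.005, lambda))
  expect_lte(n_fp, qpois(0.995, lambda))
  all_calls <- dplyr::bind_rows(callsets)
  expect_true(all(all_calls$n_cells == 1))
  expect_true(all(all_calls$read_support %in% 1:2))
})

test_that("a ubiquitous deletion is called in most cells at high coverage", {
  cfg <- sim_config(seed = 23, n_cells = 10, chrom_lengths = c(chr1 = 2e6),
                    per_cell_coverage = 3, ploidy = 4,
                    svs = tibble::tibble(svtype = "DEL", chrom = "chr1",
                                         start = 1e6, end = 1.002e6,
                                         cell_fraction = 1))
  sim <- simulate_dataset(cfg)
  callsets <- emit_cell_callsets(sim)
  frac <- mean(vapply(callsets, nrow, integer(1)) > 0)
  # junction-spanning reads per cell ~ Poisson(lambda) with lambda ≈
  # coverage * (1 - 2*margin/fragment) ≈ 3.7, so P(no call) ≈ 2.5% per cell
  expect_gte(frac, 0.9)
})
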