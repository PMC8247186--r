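# Dataset-level simulation: carrier assignment, truth bookkeeping, call-set
# emission with controlled false-positive noise, and file output.

#' Simulate a full single-cell long-read dataset
#'
#' Builds the reference, assigns each planted SV and circle to a carrier
#' subset of cells (`round(cell_fraction * n_cells)`, at least one), simulates
#' every cell's reads, and assembles the machine-readable truth. Deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset`:
#' \describe{
#'   \item{config, reference, cells}{inputs and cell ids.}
#'   \item{alignments}{segment-level alignment tibble over all cells.}
#'   \item{origin}{per-read truth (see [simulate_cell()]); every emitted read
#'     appears exactly once.}
#'   \item{truth_svs}{planted SVs with `event` ids and carrier `cells`.}
#'   \item{truth_circles}{planted circles with carrier `cells`.}
#'   \item{truth_cnv}{per-window expected copy number (1 Mb windows).}
#' }
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 7, n_cells = 2,
#'   chrom_lengths = c(chr1 = 2e6), per_cell_coverage = 0.05))
#' nrow(sim$alignments)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  reference <- build_reference(config)
  with_seed(config$seed, {
    cells <- sprintf("cell%03d", seq_len(config$n_cells))
    svs <- tag_events(config$svs, "sv")
    circles <- tag_events(config$circles, "circle")
    svs$cells <- lapply(seq_len(nrow(svs)), function(i) {
      sort(sample(cells, max(1, round(svs$cell_fraction[i] * config$n_cells))))
    })
    circles$cells <- lapply(seq_len(nrow(circles)), function(i) {
      sort(sample(cells,
                  max(1, round(circles$cell_fraction[i] * config$n_cells))))
    })

    per_cell <- map(cells, function(cid) {
      sv_c <- svs[vapply(svs$cells, function(x) cid %in% x, logical(1)), ,
                  drop = FALSE]
      circ_c <- circles[vapply(circles$cells, function(x) cid %in% x,
                               logical(1)), , drop = FALSE]
      simulate_cell(reference, config, cid, svs = sv_c, circles = circ_c)
    })

    structure(list(
      config = config, reference = reference, cells = cells,
      alignments = bind_rows(map(per_cell, "alignments")),
      origin = bind_rows(map(per_cell, "origin")),
      truth_svs = svs, truth_circles = circles,
      truth_cnv = cnv_truth(config)
    ), class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>\n")
  cat(sprintf("  %d cells, %d reads (%d aligned segments)\n",
              length(x$cells), nrow(x$origin), nrow(x$alignments)))
  cat(sprintf("  truth: %d SV(s), %d circle(s)\n",
              nrow(x$truth_svs), nrow(x$truth_circles)))
  invisible(x)
}

#' Expected per-window copy number implied by a simulation config
#'
#' @param config A [sim_config()].
#' @param window_size Window size in bp.
#' @return Window tibble with `chrom`, `start`, `end`, `copy_number` (the
#'   window-average copy, accounting for partial overlap of planted steps).
#' @export
cnv_truth <- function(config, window_size = 1e6) {
  wins <- genome_windows(config$chrom_lengths, window_size)
  cn <- rep(config$ploidy, nrow(wins))
  steps <- config$cnv_steps
  if (nrow(steps) > 0) {
    for (i in seq_len(nrow(steps))) {
      ov <- overlap_width(wins$chrom, wins$start, wins$end,
                          steps$chrom[i], steps$start[i], steps$end[i])
      frac <- ov / (wins$end - wins$start)
      cn <- cn + frac * (steps$copy_number[i] - config$ploidy)
    }
  }
  wins$copy_number <- cn
  wins
}

#' Read counts per planted event and cell
#'
#' Tallies, from the simulation truth, how many emitted reads of each cell
#' span each planted junction (SV or circle).
#'
#' @param sim A [simulate_dataset()] result.
#' @return Tibble `event`, `cell_id`, `n_reads`.
#' @export
event_read_support <- function(sim) {
  ori <- sim$origin |>
    select("read_id", "cell_id", "events") |>
    unnest("events") |>
    rename(event = "events")
  ori |> count(.data$event, .data$cell_id, name = "n_reads")
}

#' Emit per-cell SV call sets with controlled noise
#'
#' Models the output of a per-cell SV caller: every planted SV spanned by at
#' least one read in a cell becomes a call with `read_support` equal to the
#' spanning-read count, and Poisson(`fp_sv_per_cell`) spurious calls are added
#' at uniform random loci, each private to its cell with support drawn from
#' {1, 2}. A fraction `imprecise_frac` of all calls is flagged IMPRECISE.
#' Spurious calls being private to single cells is the mechanism that makes
#' multi-cell support informative.
#'
#' @param sim A [simulate_dataset()] result.
#' @param seed RNG seed for the noise layer (default derives from the config).
#' @return Named list of per-cell SV call tibbles.
#' @export
emit_cell_callsets <- function(sim, seed = sim$config$seed + 1000L) {
  config <- sim$config
  support <- event_read_support(sim)
  truth <- sim$truth_svs
  with_seed(seed, {
    out <- map(sim$cells, function(cid) {
      sup_c <- support[support$cell_id == cid &
                         support$event %in% truth$event, , drop = FALSE]
      calls <- list()
      if (nrow(sup_c) > 0) {
        idx <- match(sup_c$event, truth$event)
        t <- truth[idx, ]
        calls$true <- sv_calls(
          t$svtype, t$chrom, t$start, t$end, svlen = t$svlen,
          chrom2 = t$chrom2, pos2 = t$pos2,
          read_support = sup_c$n_reads,
          total_depth = sup_c$n_reads + rpois(nrow(t), 0.5),
          cell_id = cid)
      }
      n_fp <- rpois(1, config$fp_sv_per_cell)
      if (n_fp > 0) {
        chrom <- sample(names(config$chrom_lengths), n_fp, replace = TRUE)
        len <- round(runif(n_fp, 120, 5000))
        start <- vapply(seq_len(n_fp), function(i) {
          round(runif(1, 0, config$chrom_lengths[[chrom[i]]] - len[i] - 1))
        }, numeric(1))
        svtype <- sample(c("DEL", "INS"), n_fp, replace = TRUE)
        calls$fp <- sv_calls(
          svtype, chrom, start,
          end = ifelse(svtype == "INS", start + 1, start + len),
          svlen = ifelse(svtype == "DEL", -len, len),
          read_support = sample(1:2, n_fp, replace = TRUE),
          total_depth = 2L, cell_id = cid)
      }
      cs <- bind_rows(calls)
      if (nrow(cs) == 0) return(empty_sv_calls())
      if (config$imprecise_frac > 0) {
        flag <- runif(nrow(cs)) < config$imprecise_frac
        cs$filter[flag] <- "IMPRECISE"
      }
      canonicalize_svs(cs)
    })
    setNames(out, sim$cells)
  })
}

#' Emit a bulk-like SV call set from the simulation truth
#'
#' Stands in for a deeply sequenced bulk sample: every planted SV becomes one
#' call with high read support and realistic depth, suitable as the benchmark
#' set for single-cell comparisons.
#'
#' @param sim A [simulate_dataset()] result.
#' @param mean_support Mean supporting reads per call.
#' @param seed RNG seed.
#' @return SV call tibble with `cell_id = "bulk"`.
#' @export
emit_bulk_callset <- function(sim, mean_support = 30,
                              seed = sim$config$seed + 2000L) {
  t <- sim$truth_svs
  if (nrow(t) == 0) return(empty_sv_calls())
  with_seed(seed, {
    sup <- 4L + rpois(nrow(t), mean_support - 4)
    canonicalize_svs(sv_calls(
      t$svtype, t$chrom, t$start, t$end, svlen = t$svlen,
      chrom2 = t$chrom2, pos2 = t$pos2, read_support = sup,
      total_depth = sup + rpois(nrow(t), sup), cell_id = "bulk"))
  })
}

#' Simulate per-cell and bulk SNV call sets
#'
#' The bulk truth is `n_bulk_snvs` SNVs at distinct random positions. Each
#' cell calls a bulk SNV with probability `snv_detection_prob` (sparse
#' coverage), and adds private false positives at `snv_fp_rate` per covered
#' base, where each cell's covered bases are `snv_breadth * genome` length.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to `config$seed + 3000`).
#' @return List with `bulk` (SNV tibble), `cells` (SNV tibble with `cell_id`
#'   and a logical `true_snv` column), `covered_bases` (named vector), and
#'   `cell_ids`.
#' @export
simulate_snv_callsets <- function(config, seed = config$seed + 3000L) {
  genome <- sum(config$chrom_lengths)
  with_seed(seed, {
    chrom <- sample(names(config$chrom_lengths), config$n_bulk_snvs,
                    replace = TRUE,
                    prob = config$chrom_lengths / genome)
    pos <- vapply(chrom, function(ch) {
      sample.int(config$chrom_lengths[[ch]], 1)
    }, numeric(1))
    key <- paste0(chrom, ":", pos)
    keep <- !duplicated(key)
    chrom <- chrom[keep]; pos <- pos[keep]
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    bulk <- snv_calls(chrom, pos, ref, alt, cell_id = "bulk")

    cell_ids <- sprintf("cell%03d", seq_len(config$n_cells))
    covered <- setNames(rep(round(config$snv_breadth * genome),
                            config$n_cells), cell_ids)
    cells <- map_dfr(cell_ids, function(cid) {
      det <- runif(nrow(bulk)) < config$snv_detection_prob
      true_part <- bulk[det, ] |> mutate(cell_id = cid, true_snv = TRUE)
      n_fp <- rpois(1, covered[[cid]] * config$snv_fp_rate)
      fp_part <- NULL
      if (n_fp > 0) {
        fchrom <- sample(names(config$chrom_lengths), n_fp, replace = TRUE,
                         prob = config$chrom_lengths / genome)
        fpos <- vapply(fchrom, function(ch) {
          sample.int(config$chrom_lengths[[ch]], 1)
        }, numeric(1))
        fref <- sample(bases, n_fp, replace = TRUE)
        falt <- vapply(fref, function(r) sample(setdiff(bases, r), 1),
                       character(1))
        fp_part <- snv_calls(fchrom, fpos, fref, falt, cell_id = cid) |>
          mutate(true_snv = FALSE)
      }
      bind_rows(true_part, fp_part)
    })
    list(bulk = bulk, cells = cells, covered_bases = covered,
         cell_ids = cell_ids)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the external files of a run: `reference.fa` (when sequences were
#' generated), `arms.bed`, `trf.bed`, per-cell `cellNNN.sam`, per-cell SV and
#' SNV VCFs, `truth_svs.tsv`, `truth_circles.tsv`, `truth_cnv.tsv`,
#' `read_origin.tsv` and a flat `simconfig.txt`.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @param callsets Optional [emit_cell_callsets()] output to write as VCFs.
#' @param snvs Optional [simulate_snv_callsets()] output.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, callsets = NULL, snvs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- sim$reference
  if (!is.null(ref$sequences)) {
    writeXStringSet(DNAStringSet(ref$sequences), file.path(dir, "reference.fa"))
  }
  write_bed(ref$arms[, c("chrom", "start", "end", "arm")],
            file.path(dir, "arms.bed"))
  write_bed(ref$repeats, file.path(dir, "trf.bed"))
  for (cid in sim$cells) {
    aln <- sim$alignments[sim$alignments$cell_id == cid, , drop = FALSE]
    write_sam(aln, file.path(dir, paste0(cid, ".sam")), ref$lengths)
  }
  if (!is.null(callsets)) {
    for (cid in names(callsets)) {
      write_sv_vcf(callsets[[cid]], file.path(dir, paste0(cid, ".sv.vcf")),
                   ref$lengths)
    }
  }
  if (!is.null(snvs)) {
    write_snv_vcf(snvs$bulk, file.path(dir, "bulk.snv.vcf"))
    for (cid in unique(snvs$cells$cell_id)) {
      write_snv_vcf(snvs$cells[snvs$cells$cell_id == cid,
                               c("chrom", "pos", "ref", "alt", "cell_id")],
                    file.path(dir, paste0(cid, ".snv.vcf")))
    }
  }
  truth_svs <- sim$truth_svs
  truth_circles <- sim$truth_circles
  if (nrow(truth_svs) > 0) {
    truth_svs$cells <- vapply(truth_svs$cells, paste, character(1),
                              collapse = ",")
  }
  if (nrow(truth_circles) > 0) {
    truth_circles$cells <- vapply(truth_circles$cells, paste, character(1),
                                  collapse = ",")
  }
  write_tsv(truth_svs, file.path(dir, "truth_svs.tsv"))
  write_tsv(truth_circles, file.path(dir, "truth_circles.tsv"))
  write_tsv(sim$truth_cnv, file.path(dir, "truth_cnv.tsv"))
  origin <- sim$origin
  origin$events <- vapply(origin$events, paste, character(1), collapse = ",")
  write_tsv(origin, file.path(dir, "read_origin.tsv"))
  cfg <- sim$config
  scal <- vapply(cfg, function(x) !is.data.frame(x) && length(x) <= 8,
                 logical(1))
  lines <- map_chr(names(cfg)[scal], function(k) {
    v <- cfg[[k]]
    paste0(k, ": ", paste(if (!is.null(names(v)))
      paste0(names(v), "=", v) else v, collapse = ","))
  })
  writeLines(lines, file.path(dir, "simconfig.txt"))
  invisible(dir)
}
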