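# Simulation configuration and RNG discipline.
#
# All stochastic simulator entry points draw from R's global RNG after
# seeding; `with_seed()` restores the caller's RNG state so simulation never
# perturbs user code.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the single-cell long-read simulator
#'
#' Describes the data-generating process being emulated: a sparse single-cell
#' whole-genome library made by one-adaptor Tn5 tagmentation (every fragment
#' recoverable, ~6 kb fragment mode), sequenced as high-accuracy long reads at
#' well below 1x depth per cell, over a genome carrying planted structural
#' variants, extrachromosomal circles and copy-number steps.
#'
#' @param seed Integer seed; identical configs give byte-identical outputs.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param n_cells Number of cells.
#' @param ploidy Baseline copy number of every autosomal window (haplotype
#'   copies simulated per chromosome).
#' @param mean_fragment_bp Mean Tn5 fragment length; cutting is a homogeneous
#'   Poisson process at rate `1/mean_fragment_bp`.
#' @param per_cell_coverage Target mean sequencing depth per cell (fraction of
#'   haploid genome length emitted as read bases).
#' @param min_read_bp Fragments shorter than this are not sequenced.
#' @param ccs_error_rate Substitution error rate applied when read sequences
#'   are emitted.
#' @param emit_sequences Generate reference/read sequences? Geometry-only
#'   simulation is much faster and sufficient for the alignment-driven stages.
#' @param svs Planted SVs: tibble with columns `svtype` (DEL/INS/DUP/INV/TRA),
#'   `chrom`, `start`, `end` (0-based half-open; for INS `end = start + 1` and
#'   `svlen` gives the inserted length; for TRA `chrom2`,`pos2` give the
#'   second breakpoint), `cell_fraction`.
#' @param circles Planted ecDNA circles: tibble with `chrom`, `start`, `end`,
#'   `copies` (circle molecules per carrying cell), `cell_fraction`.
#' @param cnv_steps Planted copy-number steps: tibble with `chrom`, `start`,
#'   `end`, `copy_number` (integer; regions default to `ploidy`).
#' @param fp_sv_per_cell Expected spurious SV calls injected per cell (Poisson),
#'   each private to its cell.
#' @param imprecise_frac Fraction of emitted calls flagged IMPRECISE.
#' @param tra_flank_bp Span simulated around a translocation fusion junction.
#' @param repeat_per_mb Density of planted tandem-repeat tracts (each >1 kb)
#'   recorded in the synthetic repeat annotation.
#' @param n_bulk_snvs,snv_detection_prob,snv_breadth,snv_fp_rate SNV layer:
#'   size of the bulk truth set, probability a cell covers (and calls) a bulk
#'   SNV, fraction of the genome counted as covered bases per cell, and
#'   per-covered-base false-positive rate.
#'
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(seed = 1, n_cells = 4, chrom_lengths = c(chr1 = 2e6))
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr1 = 20e6, chr2 = 20e6, chr3 = 20e6),
                       n_cells = 30,
                       ploidy = 2,
                       mean_fragment_bp = 6000,
                       per_cell_coverage = 0.4,
                       min_read_bp = 1000,
                       ccs_error_rate = 0.001,
                       emit_sequences = FALSE,
                       svs = NULL,
                       circles = NULL,
                       cnv_steps = NULL,
                       fp_sv_per_cell = 0,
                       imprecise_frac = 0,
                       tra_flank_bp = 50000,
                       repeat_per_mb = 1,
                       n_bulk_snvs = 2000,
                       snv_detection_prob = 0.2,
                       snv_breadth = 0.19,
                       snv_fp_rate = 2e-5) {
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  stopifnot(mean_fragment_bp > 0, per_cell_coverage > 0, ploidy >= 1,
            n_cells >= 1, ccs_error_rate >= 0, fp_sv_per_cell >= 0)
  if (any(chrom_lengths < 10 * mean_fragment_bp)) {
    abort("chromosome lengths must be at least 10 x mean_fragment_bp")
  }
  empty_svs <- tibble(svtype = character(), chrom = character(),
                      start = numeric(), end = numeric(), svlen = numeric(),
                      chrom2 = character(), pos2 = numeric(),
                      cell_fraction = numeric())
  svs <- normalize_planted(svs, empty_svs)
  circles <- normalize_planted(
    circles, tibble(chrom = character(), start = numeric(), end = numeric(),
                    copies = numeric(), cell_fraction = numeric()))
  cnv_steps <- normalize_planted(
    cnv_steps, tibble(chrom = character(), start = numeric(),
                      end = numeric(), copy_number = numeric()))
  if (nrow(svs) > 0) {
    if (!"svlen" %in% names(svs)) svs$svlen <- NA_real_
    if (!"chrom2" %in% names(svs)) svs$chrom2 <- NA_character_
    if (!"pos2" %in% names(svs)) svs$pos2 <- NA_real_
    svs$svlen <- ifelse(is.na(svs$svlen),
                        ifelse(svs$svtype == "DEL", -(svs$end - svs$start),
                        ifelse(svs$svtype == "TRA", 0, svs$end - svs$start)),
                        svs$svlen)
    if (!"cell_fraction" %in% names(svs)) svs$cell_fraction <- 1
  }
  if (nrow(circles) > 0) {
    if (!"copies" %in% names(circles)) circles$copies <- 2
    if (!"cell_fraction" %in% names(circles)) circles$cell_fraction <- 1
  }
  bad_frac <- c(svs$cell_fraction, circles$cell_fraction)
  if (length(bad_frac) > 0 && any(bad_frac <= 0 | bad_frac > 1)) {
    abort("cell_fraction must be in (0, 1]")
  }
  structure(list(
    seed = seed, chrom_lengths = chrom_lengths, n_cells = n_cells,
    ploidy = ploidy, mean_fragment_bp = mean_fragment_bp,
    per_cell_coverage = per_cell_coverage, min_read_bp = min_read_bp,
    ccs_error_rate = ccs_error_rate, emit_sequences = emit_sequences,
    svs = svs, circles = circles, cnv_steps = cnv_steps,
    fp_sv_per_cell = fp_sv_per_cell, imprecise_frac = imprecise_frac,
    tra_flank_bp = tra_flank_bp, repeat_per_mb = repeat_per_mb,
    n_bulk_snvs = n_bulk_snvs, snv_detection_prob = snv_detection_prob,
    snv_breadth = snv_breadth, snv_fp_rate = snv_fp_rate
  ), class = "sim_config")
}

normalize_planted <- function(x, template) {
  if (is.null(x)) return(template)
  x <- as_tibble(x)
  x
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosome(s), %.1f Mb total; ploidy %d\n",
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6, x$ploidy))
  cat(sprintf("  cells: %d at %.2fx, ~%d bp fragments (>= %d bp sequenced)\n",
              x$n_cells, x$per_cell_coverage, x$mean_fragment_bp,
              x$min_read_bp))
  cat(sprintf("  planted: %d SV(s), %d circle(s), %d CNV step(s); %.1f FP calls/cell\n",
              nrow(x$svs), nrow(x$circles), nrow(x$cnv_steps),
              x$fp_sv_per_cell))
  invisible(x)
}
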