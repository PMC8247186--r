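# Synthetic reference genome: i.i.d. uniform ACGT sequence with explicitly
# planted tandem-repeat tracts, a fixed centromere per chromosome (arms
# annotation), and the repeat annotation used by the ecDNA junction filter.

#' Build a synthetic reference genome
#'
#' Deterministic given `config$seed`. Plants tandem-repeat tracts of length
#' 1.2-3 kb (a short random motif repeated head-to-tail) at Poisson-distributed
#' positions with density `config$repeat_per_mb`, and places a centromere at
#' 45% of each chromosome, defining a p arm (telomere at the left end) and a
#' q arm (telomere at the right end).
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes `reference.fa`
#'   (only if `config$emit_sequences`), `arms.bed` and `trf.bed`.
#' @return A list with `lengths` (named vector), `arms` (tibble: chrom, start,
#'   end, arm, centromere, telomere), `repeats` (interval tibble), and
#'   `sequences` (named character vector, or NULL when sequences are not
#'   emitted).
#' @examples
#' ref <- build_reference(sim_config(seed = 1, chrom_lengths = c(chr1 = 1e6)))
#' ref$arms
#' @export
build_reference <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    lens <- config$chrom_lengths
    arms <- map_dfr(names(lens), function(ch) {
      cen <- round(0.45 * lens[[ch]])
      tibble(chrom = ch,
             start = c(0, cen),
             end = c(cen, lens[[ch]]),
             arm = c("p", "q"),
             centromere = c(cen, cen),
             telomere = c(0, lens[[ch]]))
    })

    repeats <- map_dfr(names(lens), function(ch) {
      n <- rpois(1, config$repeat_per_mb * lens[[ch]] / 1e6)
      if (n == 0) {
        return(tibble(chrom = character(), start = numeric(),
                      end = numeric(), motif_bp = numeric()))
      }
      len <- round(runif(n, 1200, 3000))
      start <- round(runif(n, 0, lens[[ch]] - len - 1))
      tibble(chrom = ch, start = start, end = start + len,
             motif_bp = pmax(10, round(runif(n, 10, 100)))) |>
        arrange(.data$start)
    })

    sequences <- NULL
    if (isTRUE(config$emit_sequences)) {
      bases <- c("A", "C", "G", "T")
      sequences <- vapply(names(lens), function(ch) {
        s <- sample(bases, lens[[ch]], replace = TRUE)
        reps <- repeats[repeats$chrom == ch, ]
        if (nrow(reps) > 0) {
          for (i in seq_len(nrow(reps))) {
            motif <- sample(bases, reps$motif_bp[i], replace = TRUE)
            tract_len <- reps$end[i] - reps$start[i]
            tract <- rep_len(motif, tract_len)
            s[(reps$start[i] + 1):reps$end[i]] <- tract
          }
        }
        paste0(s, collapse = "")
      }, character(1))
    }

    ref <- list(lengths = lens, arms = arms,
                repeats = repeats[, c("chrom", "start", "end")],
                sequences = sequences)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      if (!is.null(sequences)) {
        writeXStringSet(DNAStringSet(sequences),
                        file.path(dir, "reference.fa"))
      }
      write_bed(arms[, c("chrom", "start", "end", "arm")],
                file.path(dir, "arms.bed"))
      write_bed(ref$repeats, file.path(dir, "trf.bed"))
    }
    ref
  })
}
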