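# SNV benchmarking against a bulk reference call set, and the six-class
# base-substitution spectrum.

snv_key <- function(snvs) paste0(snvs$chrom, ":", snvs$pos, ":", snvs$alt)

#' Benchmark multi-cell-supported SNVs against a bulk reference
#'
#' For each support level k, the candidate set is the SNVs called with an
#' identical alternative allele in at least k distinct cells. A candidate is a
#' true positive when the bulk set contains the same position with the same
#' alternative allele. Detection efficiency is TP divided by the bulk set
#' size; precision is TP/(TP+FP).
#'
#' @param snv_callsets SNV tibble across cells (with `cell_id`), or a list of
#'   per-cell tibbles.
#' @param bulk_snvs Bulk SNV tibble.
#' @param k Vector of support levels (default 1:10).
#' @return Tibble with one row per k: `k`, `n_candidates`, `tp`, `fp`,
#'   `efficiency`, `precision`.
#' @export
snv_multicell_support <- function(snv_callsets, bulk_snvs, k = 1:10) {
  cells <- if (is.data.frame(snv_callsets)) snv_callsets else
    bind_rows(snv_callsets)
  stopifnot(all(k >= 1))
  support <- cells |>
    distinct(.data$chrom, .data$pos, .data$alt, .data$cell_id) |>
    count(.data$chrom, .data$pos, .data$alt, name = "n_cells")
  bulk_keys <- snv_key(bulk_snvs)
  map_dfr(sort(k), function(kk) {
    cand <- support[support$n_cells >= kk, , drop = FALSE]
    tp <- sum(snv_key(cand) %in% bulk_keys)
    fp <- nrow(cand) - tp
    tibble(k = kk, n_candidates = nrow(cand), tp = tp, fp = fp,
           efficiency = tp / nrow(bulk_snvs),
           precision = if (nrow(cand) > 0) tp / nrow(cand) else NA_real_)
  })
}

#' Per-cell SNV false-positive rate
#'
#' The number of cell SNVs absent from the bulk set (matching on position and
#' alternative allele) divided by the cell's covered bases.
#'
#' @param cell_snvs One cell's SNV tibble.
#' @param bulk_snvs Bulk SNV tibble.
#' @param covered_bases Total reference bases covered in the cell (> 0).
#' @return False positives per covered base.
#' @export
snv_fpr <- function(cell_snvs, bulk_snvs, covered_bases) {
  if (is.na(covered_bases) || covered_bases <= 0) {
    abort("covered_bases must be a positive count")
  }
  fp <- sum(!snv_key(cell_snvs) %in% snv_key(bulk_snvs))
  fp / covered_bases
}

#' Six-class base-substitution spectrum
#'
#' Collapses strand-complementary substitutions (C>T with G>A, and so on) into
#' the six base-pair classes CG>TA, CG>AT, CG>GC, TA>AT, TA>CG, TA>GC, and
#' returns counts and fractions. When `reference` sequences are supplied, each
#' SNV's stated reference base is verified against the genome and a mismatch
#' raises a record-level error.
#'
#' @param snvs SNV tibble.
#' @param reference Optional named character vector of chromosome sequences.
#' @return A `mutation_spectrum` tibble: `class`, `n`, `fraction`.
#' @export
mutation_spectrum <- function(snvs, reference = NULL) {
  if (!is.null(reference) && nrow(snvs) > 0) {
    actual <- vapply(seq_len(nrow(snvs)), function(i) {
      substr(reference[[snvs$chrom[i]]], snvs$pos[i], snvs$pos[i])
    }, character(1))
    bad <- which(toupper(actual) != snvs$ref)
    if (length(bad) > 0) {
      abort(sprintf("reference mismatch at %s:%d (stated %s, genome %s)",
                    snvs$chrom[bad[1]], as.integer(snvs$pos[bad[1]]),
                    snvs$ref[bad[1]], actual[bad[1]]))
    }
  }
  classes <- c("CG>TA", "CG>AT", "CG>GC", "TA>AT", "TA>CG", "TA>GC")
  cls <- substitution_class(snvs$ref, snvs$alt)
  n <- as.integer(table(factor(cls, levels = classes)))
  out <- tibble(class = classes, n = n,
                fraction = if (sum(n) > 0) n / sum(n) else rep(0, 6))
  class(out) <- c("mutation_spectrum", class(out))
  out
}

#' @rdname mutation_spectrum
#' @param ref,alt Single-base reference and alternative alleles (vectors).
#' @export
substitution_class <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- toupper(ref); alt <- toupper(alt)
  flip <- ref %in% c("G", "A")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  paste0(ref, comp[ref], ">", alt, comp[alt])
}
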