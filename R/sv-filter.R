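#' Filter one cell's SV calls
#'
#' Keeps calls whose FILTER is exactly PASS (anything flagged IMPRECISE or
#' SHADOWED is removed) and whose read support is at least `min_reads`
#' (default two reads, the single-cell support floor).
#'
#' @param calls SV call tibble with `filter` and `read_support`.
#' @param min_reads Minimum supporting reads.
#' @return The retained calls.
#' @export
filter_cell_calls <- function(calls, min_reads = 2) {
  calls |>
    filter(.data$filter == "PASS",
           !is.na(.data$read_support), .data$read_support >= min_reads)
}

#' Filter a bulk SV call set
#'
#' Bulk calls must be PASS, supported by at least `min_reads` reads, and the
#' supporting-read ratio at the locus must be strictly greater than
#' `min_ratio`. Calls with zero recorded depth are removed with a warning.
#'
#' @param calls SV call tibble with `read_support` and `total_depth`.
#' @param min_reads Minimum supporting reads (default 4).
#' @param min_ratio Support / depth must exceed this (default 0.15).
#' @return The retained calls.
#' @export
filter_bulk_calls <- function(calls, min_reads = 4, min_ratio = 0.15) {
  no_depth <- is.na(calls$total_depth) | calls$total_depth == 0
  if (any(no_depth)) {
    warn(sprintf("%d call(s) without depth removed", sum(no_depth)))
    calls <- calls[!no_depth, , drop = FALSE]
  }
  calls |>
    filter(.data$filter == "PASS",
           .data$read_support >= min_reads,
           .data$read_support / .data$total_depth > min_ratio)
}
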