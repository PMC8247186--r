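#' Read a BED file of genomic intervals
#'
#' BED is 0-based half-open, matching the package's internal convention, so no
#' coordinate shift is applied. Columns beyond the first three are preserved
#' as annotation columns named `V4`, `V5`, ... (or their original names for
#' the common `name`/`score` case via `col_names`).
#'
#' @param path BED path (plain text, tab-separated, no header).
#' @param col_names Optional names for the extra columns after chrom/start/end.
#' @return Interval tibble in file order (`chrom`, `start`, `end`, extras).
#' @examples
#' bed <- file.path(tempdir(), "x.bed")
#' writeLines("chr1\t100\t5200", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path, col_names = NULL) {
  if (!file.exists(path)) abort(paste0("no such BED file: ", path))
  raw <- readLines(path)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#") & !startsWith(raw, "track")]
  if (length(raw) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  parts <- str_split(raw, "\t")
  ncol_min <- min(lengths(parts))
  if (ncol_min < 3) abort("BED records need at least 3 tab-separated columns")
  out <- tibble(
    chrom = vapply(parts, `[`, character(1), 1),
    start = as.numeric(vapply(parts, `[`, character(1), 2)),
    end = as.numeric(vapply(parts, `[`, character(1), 3))
  )
  extra <- min(lengths(parts)) - 3
  if (extra > 0) {
    for (k in seq_len(extra)) {
      nm <- if (!is.null(col_names) && k <= length(col_names)) col_names[k]
            else paste0("V", k + 3)
      out[[nm]] <- vapply(parts, `[`, character(1), k + 3)
    }
  }
  validate_intervals(out, "BED record")
  out
}

#' Write intervals as BED
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`, extra columns
#'   written as additional BED fields).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- as.data.frame(intervals)
  if (nrow(df) > 0) {
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
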