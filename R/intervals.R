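#' Construct a tibble of genomic intervals
#'
#' Intervals are 0-based, half-open: a row covers reference positions
#' `start, start+1, ..., end-1`. This is the single coordinate convention used
#' throughout the package; conversion to 1-based coordinates happens only when
#' reading or writing VCF.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-ish vectors, `0 <= start < end`.
#' @param ... Further columns carried along (recycled by [tibble::tibble()]).
#'
#' @return A tibble with columns `chrom`, `start`, `end` and any extras.
#' @examples
#' genome_interval("chr1", 100, 5200)
#' @export
genome_interval <- function(chrom, start, end, ...) {
  out <- tibble(chrom = as.character(chrom),
                start = as.numeric(start),
                end = as.numeric(end), ...)
  validate_intervals(out)
  out
}

validate_intervals <- function(x, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort(paste0(what, " table must have columns chrom, start, end"))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(x$chrom))) {
    abort(paste0(what, ": chrom must be non-empty"))
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    abort(sprintf("%s: need 0 <= start < end (violated at row %d: [%s, %s))",
                  what, bad[1], format(x$start[bad[1]]), format(x$end[bad[1]])))
  }
  invisible(x)
}

#' Test pairwise interval overlap on the same chromosome
#'
#' Vectorised half-open overlap width between two equal-length sets of
#' intervals; 0 when chromosomes differ or the spans are disjoint.
#'
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b Parallel vectors.
#' @return Numeric vector of overlap widths in bp.
#' @keywords internal
overlap_width <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  w <- pmin(end_a, end_b) - pmax(start_a, start_b)
  w[chrom_a != chrom_b] <- 0
  pmax(w, 0)
}

#' Does a point fall within (or near) any interval of a set?
#'
#' Used by the tandem-repeat junction filter: a breakpoint is "hit" when it
#' lies inside an interval or within `tol` bp of its ends.
#'
#' @param chrom,pos Point coordinates (vectors).
#' @param intervals Interval tibble (`chrom`, `start`, `end`).
#' @param tol Padding in bp added to both interval ends.
#' @return Logical vector, one element per point.
#' @keywords internal
point_in_intervals <- function(chrom, pos, intervals, tol = 0) {
  if (nrow(intervals) == 0 || length(pos) == 0) {
    return(rep(FALSE, length(pos)))
  }
  out <- rep(FALSE, length(pos))
  for (ch in unique(chrom)) {
    iv <- intervals[intervals$chrom == ch, ]
    idx <- which(chrom == ch)
    if (nrow(iv) == 0 || length(idx) == 0) next
    for (i in idx) {
      out[i] <- any(pos[i] >= iv$start - tol & pos[i] < iv$end + tol)
    }
  }
  out
}
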