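#' Merge SV calls across cells into consensus calls
#'
#' Single-linkage clustering per SV type: two calls link when both breakpoints
#' lie within `dist` bp of each other (within `tra_dist` for translocations,
#' whose chromosome pair must match). Each cluster becomes one consensus call
#' at the member-median breakpoints; its `cells` list-column is the union of
#' member cells and `read_support` the sum of member supports. Clusters
#' supported by fewer than `min_cells` distinct cells are discarded. The
#' result is invariant under permutation of the input cells.
#'
#' @param callsets A list of per-cell SV call tibbles, or one tibble with a
#'   `cell_id` column.
#' @param dist Breakpoint distance for non-TRA types (bp).
#' @param tra_dist Breakpoint distance for TRA (bp).
#' @param min_cells Minimum number of distinct supporting cells.
#' @return Consensus SV call tibble in canonical order, with `cells` and
#'   `n_cells` filled.
#' @export
merge_across_cells <- function(callsets, dist = 1000, tra_dist = 50000,
                               min_cells = 2) {
  calls <- if (is.data.frame(callsets)) callsets else bind_rows(callsets)
  if (nrow(calls) == 0) return(empty_sv_calls())
  calls <- canonicalize_svs(calls)
  calls$cluster <- sv_link_clusters(calls, dist = dist, tra_dist = tra_dist)
  merged <- calls |>
    group_by(.data$svtype, .data$cluster) |>
    summarise(
      chrom = .data$chrom[1],
      start = round(median(.data$start)),
      end = round(median(.data$end)),
      chrom2 = .data$chrom2[1],
      pos2 = round(median(.data$pos2)),
      svlen = round(median(.data$svlen)),
      read_support = sum(.data$read_support),
      total_depth = sum(.data$total_depth),
      cells = list(sort(unique(c(unlist(.data$cells),
                                 .data$cell_id[!is.na(.data$cell_id)])))),
      .groups = "drop"
    )
  out <- sv_calls(merged$svtype, merged$chrom, merged$start,
                  end = pmax(merged$end, merged$start + 1),
                  svlen = merged$svlen, chrom2 = merged$chrom2,
                  pos2 = merged$pos2, read_support = merged$read_support,
                  total_depth = merged$total_depth, cells = merged$cells)
  out <- out[out$n_cells >= min_cells, , drop = FALSE]
  canonicalize_svs(out)
}
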