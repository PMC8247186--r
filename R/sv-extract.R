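# Minimal split-read / CIGAR SV extraction from segment-level alignments.
# This is plumbing: it turns alignment geometry into typed calls so the
# consensus and benchmarking stages can run without an external caller.

#' Extract per-cell SV calls from alignment geometry
#'
#' Emits DEL/INS from CIGAR D/I runs of at least `min_len` bp; DEL also from
#' colinear same-strand split pairs with a reference gap of at least `min_len`
#' and a query gap under 100 bp; DUP from same-chromosome same-strand chiastic
#' split pairs whose segments extend beyond the inferred junction span (pairs
#' confined within the span are circle-shaped evidence and are left to the
#' ecDNA stage, see [detect_chiastic_reads()]); INV from same-chromosome
#' opposite-strand pairs; TRA from cross-chromosome pairs. Calls are clustered
#' within `cluster_dist` per type per cell; `read_support` is the cluster
#' size.
#'
#' @param alignments Segment-level alignment tibble for one or more cells.
#' @param min_len Minimum SV length in bp (the >50 bp structural-variant
#'   convention).
#' @param max_query_gap Maximum unaligned read bases across a split junction.
#' @param cluster_dist Per-cell clustering distance in bp.
#' @param circle_tol Slack in bp when deciding whether a chiastic pair is
#'   confined to its junction span.
#' @return SV call tibble (see [sv_calls()]) with per-cell `read_support`.
#' @export
extract_cell_svs <- function(alignments, min_len = 50, max_query_gap = 100,
                             cluster_dist = 1000, circle_tol = 50) {
  if (nrow(alignments) == 0) return(empty_sv_calls())
  raw <- bind_rows(
    cigar_indel_calls(alignments, min_len),
    split_pair_calls(alignments, min_len, max_query_gap, circle_tol)
  )
  if (nrow(raw) == 0) return(empty_sv_calls())
  if (!"chrom2" %in% names(raw)) raw$chrom2 <- NA_character_
  if (!"pos2" %in% names(raw)) raw$pos2 <- NA_real_
  split(raw, raw$cell_id) |>
    map(cluster_calls, dist = cluster_dist) |>
    bind_rows() |>
    canonicalize_svs()
}

cigar_indel_calls <- function(alignments, min_len) {
  out <- map_dfr(seq_len(nrow(alignments)), function(i) {
    seg <- alignments[i, ]
    ops <- parse_cigar_ops(seg$cigar, seg$read_id)
    big <- which(ops$op %in% c("D", "I") & ops$len >= min_len)
    if (length(big) == 0) return(NULL)
    ref_consumed <- ifelse(ops$op %in% CIGAR_REF_OPS, ops$len, 0)
    ref_off <- cumsum(ref_consumed) - ref_consumed
    map_dfr(big, function(b) {
      pos <- seg$start + ref_off[b]
      if (ops$op[b] == "D") {
        tibble(svtype = "DEL", chrom = seg$chrom, start = pos,
               end = pos + ops$len[b], svlen = -ops$len[b],
               cell_id = seg$cell_id, read_id = seg$read_id)
      } else {
        tibble(svtype = "INS", chrom = seg$chrom, start = pos,
               end = pos + 1, svlen = ops$len[b],
               cell_id = seg$cell_id, read_id = seg$read_id)
      }
    })
  })
  out
}

split_pair_calls <- function(alignments, min_len, max_query_gap, circle_tol) {
  multi <- alignments |>
    group_by(.data$read_id) |>
    filter(n() > 1) |>
    arrange(.data$segment, .by_group = TRUE) |>
    ungroup()
  if (nrow(multi) == 0) return(NULL)
  map_dfr(split(multi, multi$read_id), function(segs) {
    map_dfr(seq_len(nrow(segs) - 1), function(k) {
      a <- segs[k, ]; b <- segs[k + 1, ]
      qgap <- b$query_start - a$query_end
      if (abs(qgap) > max_query_gap) return(NULL)
      if (a$chrom != b$chrom) {
        bp1 <- if (a$strand == "+") a$end else a$start
        bp2 <- if (b$strand == "+") b$start else b$end
        return(tibble(svtype = "TRA", chrom = a$chrom, start = bp1,
                      end = bp1 + 1, chrom2 = b$chrom, pos2 = bp2, svlen = 0,
                      cell_id = a$cell_id, read_id = a$read_id))
      }
      if (a$strand != b$strand) {
        p1 <- if (a$strand == "+") a$end else a$start
        p2 <- if (b$strand == "+") b$start else b$end
        lo <- min(p1, p2); hi <- max(p1, p2)
        if (hi - lo < min_len) return(NULL)
        return(tibble(svtype = "INV", chrom = a$chrom, start = lo, end = hi,
                      svlen = hi - lo, cell_id = a$cell_id,
                      read_id = a$read_id))
      }
      # same chromosome, same strand: orient to genome order
      first <- if (a$strand == "+") a else b
      second <- if (a$strand == "+") b else a
      gap <- second$start - first$end
      if (gap >= min_len) {
        return(tibble(svtype = "DEL", chrom = a$chrom, start = first$end,
                      end = second$start, svlen = -(second$start - first$end),
                      cell_id = a$cell_id, read_id = a$read_id))
      }
      if (second$start < first$end) {
        # backward jump: chiastic junction (circle or head-to-tail duplication)
        span_lo <- second$start; span_hi <- first$end
        confined <- first$start >= span_lo - circle_tol &&
          second$end <= span_hi + circle_tol
        if (!confined && span_hi - span_lo >= min_len) {
          return(tibble(svtype = "DUP", chrom = a$chrom, start = span_lo,
                        end = span_hi, svlen = span_hi - span_lo,
                        cell_id = a$cell_id, read_id = a$read_id))
        }
      }
      NULL
    })
  })
}

# single-linkage clustering of one cell's raw calls; consensus at median
# breakpoints with read_support = number of distinct supporting reads
cluster_calls <- function(raw, dist) {
  raw$cluster <- sv_link_clusters(raw, dist = dist, tra_dist = dist)
  raw |>
    group_by(.data$svtype, .data$cluster) |>
    summarise(
      chrom = .data$chrom[1],
      start = round(median(.data$start)),
      end = round(median(.data$end)),
      chrom2 = .data$chrom2[1] %||% NA_character_,
      pos2 = round(median(.data$pos2)),
      svlen = round(median(.data$svlen)),
      read_support = n_distinct(.data$read_id),
      cell_id = .data$cell_id[1],
      .groups = "drop"
    ) |>
    (\(d) sv_calls(d$svtype, d$chrom, d$start,
                   end = pmax(d$end, d$start + 1), svlen = d$svlen,
                   chrom2 = d$chrom2, pos2 = d$pos2,
                   read_support = d$read_support, cell_id = d$cell_id))()
}

# Cluster ids under single linkage: two calls link when they are of the same
# type on the same chromosome (pair) and both breakpoints are within `dist`
# (`tra_dist` for TRA). Returns an integer vector.
sv_link_clusters <- function(calls, dist = 1000, tra_dist = 50000) {
  n <- nrow(calls)
  if (n == 0) return(integer(0))
  is_tra <- calls$svtype == "TRA"
  grp_key <- ifelse(is_tra,
                    paste("TRA", calls$chrom, calls$chrom2),
                    paste(calls$svtype, calls$chrom))
  cluster <- integer(n)
  nxt <- 0L
  for (g in unique(grp_key)) {
    idx <- which(grp_key == g)
    m <- length(idx)
    if (m == 1) {
      cluster[idx] <- nxt + 1L
      nxt <- nxt + 1L
      next
    }
    x1 <- calls$start[idx]
    x2 <- if (is_tra[idx[1]]) calls$pos2[idx] else calls$end[idx]
    d <- if (is_tra[idx[1]]) tra_dist else dist
    ok <- abs(outer(x1, x1, "-")) <= d & abs(outer(x2, x2, "-")) <= d
    edges <- which(ok & upper.tri(ok), arr.ind = TRUE)
    g_ig <- graph_from_data_frame(
      data.frame(from = c(edges[, 1], seq_len(m)),
                 to = c(edges[, 2], seq_len(m))),
      directed = FALSE)
    comp <- components(g_ig)$membership
    comp <- comp[as.character(seq_len(m))]
    cluster[idx] <- nxt + comp
    nxt <- nxt + max(comp)
  }
  cluster
}
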