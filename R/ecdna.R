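# ecDNA detection from chiastic two-segment reads: a read sequenced through a
# circular junction aligns as exactly two same-chromosome, same-strand
# segments whose read order is reversed relative to their genome order. The
# pipeline is detect -> tandem-repeat junction filter -> duplication-evidence
# filter -> cross-cell merge; each stage only removes or merges candidates.

#' Detect chiastic two-segment reads (circle junction candidates)
#'
#' A read qualifies when it has exactly two aligned segments, both on the same
#' chromosome and strand, in chiastic order (the read-earlier segment maps
#' genomically downstream of the read-later one), with at most `max_query_gap`
#' unaligned or doubly-aligned read bases at the junction, and at most
#' `junction_tol` bp of genomic overlap between the segments. The inferred
#' circle runs from the start of the read-later segment to the end of the
#' read-earlier segment; `full_length` marks reads whose two segments jointly
#' cover at least 95% of the read (a single-cut, full-circle read).
#' Minus-strand reads are normalized to genome orientation before the test.
#'
#' @param alignments Segment-level alignment tibble.
#' @param max_query_gap Maximum absolute query gap/overlap at the junction (bp).
#' @param junction_tol Maximum genomic overlap between the two segments (bp).
#' @return Per-read candidate tibble: `chrom`, `start`, `end` (the circle),
#'   `read_id`, `cell_id`, `read_length`, `covered_frac`, `full_length`.
#' @export
detect_chiastic_reads <- function(alignments, max_query_gap = 50,
                                  junction_tol = 50) {
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  read_id = character(), cell_id = character(),
                  read_length = numeric(), covered_frac = numeric(),
                  full_length = logical())
  if (nrow(alignments) == 0) return(empty)
  two_seg <- alignments |>
    group_by(.data$read_id) |>
    filter(n() == 2) |>
    arrange(.data$segment, .by_group = TRUE) |>
    ungroup()
  if (nrow(two_seg) == 0) return(empty)
  out <- map_dfr(split(two_seg, two_seg$read_id), function(s) {
    a <- s[1, ]; b <- s[2, ]  # a earlier on the read
    if (a$chrom != b$chrom || a$strand != b$strand) return(NULL)
    if (abs(b$query_start - a$query_end) > max_query_gap) return(NULL)
    # normalize to genome orientation: on the minus strand the read traverses
    # the genome right-to-left, so the roles of the two segments swap
    first <- if (a$strand == "+") a else b   # read-earlier in genome terms
    second <- if (a$strand == "+") b else a
    if (second$start >= first$start) return(NULL)       # colinear, not chiastic
    overlap <- min(first$end, second$end) - max(first$start, second$start)
    if (overlap > junction_tol) return(NULL)
    circle_start <- second$start
    circle_end <- first$end
    if (circle_end <= circle_start) return(NULL)
    qcov <- (a$query_end - a$query_start) + (b$query_end - b$query_start) -
      max(0, a$query_end - b$query_start)
    tibble(chrom = a$chrom, start = circle_start, end = circle_end,
           read_id = a$read_id, cell_id = a$cell_id,
           read_length = a$read_length,
           covered_frac = qcov / a$read_length,
           full_length = qcov / a$read_length >= 0.95)
  })
  if (nrow(out) == 0) empty else arrange(out, .data$chrom, .data$start)
}

#' Remove candidates whose junction lies in a long tandem repeat
#'
#' A chiastic junction inside a tandem-repeat tract is unmappable evidence: a
#' candidate is removed when either junction breakpoint falls within (or
#' within `junction_tol` bp of) a repeat interval longer than `min_repeat_bp`.
#' Shorter annotation entries are ignored. Only the junction breakpoints are
#' tested — a circle may legitimately contain a repeat internally.
#'
#' @param candidates Per-read or merged candidate tibble.
#' @param trf_intervals Tandem-repeat annotation (interval tibble).
#' @param min_repeat_bp Repeat length floor (default 1000, strict).
#' @param junction_tol Breakpoint padding in bp.
#' @return The retained candidates.
#' @export
filter_tandem_repeats <- function(candidates, trf_intervals,
                                  min_repeat_bp = 1000, junction_tol = 50) {
  if (nrow(candidates) == 0 || nrow(trf_intervals) == 0) return(candidates)
  long_reps <- trf_intervals[trf_intervals$end - trf_intervals$start >
                               min_repeat_bp, , drop = FALSE]
  if (nrow(long_reps) == 0) return(candidates)
  hit_left <- point_in_intervals(candidates$chrom, candidates$start,
                                 long_reps, tol = junction_tol)
  hit_right <- point_in_intervals(candidates$chrom, candidates$end,
                                  long_reps, tol = junction_tol)
  candidates[!(hit_left | hit_right), , drop = FALSE]
}

#' Remove candidates explained by multi-cell duplication consensus
#'
#' A candidate is removed when some duplication call supported by at least
#' `min_dup_cells` cells has both coordinates within `tol` bp of the
#' candidate's junction coordinates — the head-to-tail duplication
#' interpretation then takes precedence over the circle interpretation.
#'
#' @param candidates Candidate tibble.
#' @param dup_calls Merged DUP consensus calls with `n_cells` (see
#'   [merge_across_cells()]).
#' @param min_dup_cells Cell-support floor for a disqualifying duplication.
#' @param tol Coordinate tolerance in bp (default 100).
#' @return The retained candidates.
#' @export
filter_duplications <- function(candidates, dup_calls, min_dup_cells = 4,
                                tol = 100) {
  if (nrow(candidates) == 0 || nrow(dup_calls) == 0) return(candidates)
  dups <- dup_calls[dup_calls$svtype == "DUP" &
                      dup_calls$n_cells >= min_dup_cells, , drop = FALSE]
  if (nrow(dups) == 0) return(candidates)
  drop <- vapply(seq_len(nrow(candidates)), function(i) {
    any(dups$chrom == candidates$chrom[i] &
          abs(dups$start - candidates$start[i]) <= tol &
          abs(dups$end - candidates$end[i]) <= tol)
  }, logical(1))
  candidates[!drop, , drop = FALSE]
}

#' Merge per-cell ecDNA candidates across cells
#'
#' Single-linkage clustering of candidates whose two junction coordinates both
#' lie within `tol` bp; each cluster becomes one consensus candidate at the
#' member-median coordinates, and clusters supported by fewer than `min_cells`
#' distinct cells are dropped. Permutation-invariant.
#'
#' @param per_cell_candidates Candidate tibble across cells (needs `cell_id`).
#' @param tol Junction coordinate tolerance in bp (default 50).
#' @param min_cells Minimum distinct supporting cells (default 2).
#' @return Merged candidate tibble: `chrom`, `start`, `end`, `n_cells`,
#'   `n_reads`, `cells`, `read_ids`, `full_length_reads`.
#' @export
merge_ecdna <- function(per_cell_candidates, tol = 50, min_cells = 2) {
  cand <- per_cell_candidates |>
    arrange(.data$chrom, .data$start, .data$end, .data$cell_id, .data$read_id)
  if (nrow(cand) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_cells = integer(), n_reads = integer(), cells = list(),
                  read_ids = list(), full_length_reads = integer()))
  }
  fake <- sv_calls("DUP", cand$chrom, cand$start, cand$end)
  cand$cluster <- sv_link_clusters(fake, dist = tol, tra_dist = tol)
  merged <- cand |>
    group_by(.data$cluster) |>
    summarise(
      chrom = .data$chrom[1],
      start = round(median(.data$start)),
      end = round(median(.data$end)),
      n_cells = n_distinct(.data$cell_id),
      n_reads = n_distinct(.data$read_id),
      cells = list(sort(unique(.data$cell_id))),
      read_ids = list(sort(unique(.data$read_id))),
      full_length_reads = sum(.data$full_length),
      .groups = "drop"
    ) |>
    select(-"cluster")
  merged <- merged[merged$n_cells >= min_cells, , drop = FALSE]
  arrange(merged, .data$chrom, .data$start)
}

#' Same-length read evidence for merged candidates
#'
#' Distinct copies of the same circle linearized by a single cut yield reads
#' of exactly the circle's length — a feature tandem repeats do not share.
#' For each merged candidate this groups its supporting full-length reads by
#' read length (within `len_tol` bp of the modal length) and reports the modal
#' group size and the number of distinct cells contributing to it.
#'
#' @param merged Merged candidate tibble from [merge_ecdna()].
#' @param per_read_candidates The per-read candidate tibble the merge was
#'   built from (source of read lengths and cells).
#' @param len_tol Length tolerance in bp around the modal length (default 20).
#' @return `merged` with columns `modal_length`, `modal_reads`, `modal_cells`,
#'   `n_length_groups`, `length_heterogeneous` added (NA where a candidate has
#'   no full-length reads).
#' @export
same_length_evidence <- function(merged, per_read_candidates, len_tol = 20) {
  fl <- per_read_candidates[per_read_candidates$full_length, , drop = FALSE]
  annot <- map_dfr(seq_len(nrow(merged)), function(i) {
    reads <- fl[fl$read_id %in% merged$read_ids[[i]], , drop = FALSE]
    if (nrow(reads) == 0) {
      return(tibble(modal_length = NA_real_, modal_reads = NA_integer_,
                    modal_cells = NA_integer_, n_length_groups = NA_integer_,
                    length_heterogeneous = NA))
    }
    # greedy grouping around successive modes
    lens <- sort(reads$read_length)
    groups <- list()
    while (length(lens) > 0) {
      centers <- unique(lens)
      sizes <- vapply(centers,
                      function(c) sum(abs(lens - c) <= len_tol), integer(1))
      c0 <- centers[which.max(sizes)]
      in_g <- abs(lens - c0) <= len_tol
      groups[[length(groups) + 1]] <- lens[in_g]
      lens <- lens[!in_g]
    }
    sizes <- lengths(groups)
    best <- groups[[which.max(sizes)]]
    modal_len <- median(best)
    in_modal <- abs(reads$read_length - modal_len) <= len_tol
    tibble(modal_length = modal_len,
           modal_reads = sum(in_modal),
           modal_cells = n_distinct(reads$cell_id[in_modal]),
           n_length_groups = length(groups),
           length_heterogeneous = length(groups) > 1)
  })
  bind_cols(merged, annot)
}

#' Run the full ecDNA detection pipeline
#'
#' detect -> tandem-repeat junction filter -> duplication-evidence filter ->
#' cross-cell merge -> same-length annotation, with the conventional defaults
#' (exactly two chiastic segments; repeats > 1 kb; duplications supported by
#' >= 4 cells within +/-100 bp; candidates merged within +/-50 bp and kept
#' with >= 2 supporting cells). Candidates on the mitochondrial contig are
#' reported separately, not merged with nuclear candidates.
#'
#' @param alignments Segment-level alignment tibble across cells.
#' @param trf_intervals Tandem-repeat annotation (interval tibble), or NULL.
#' @param dup_calls Merged DUP consensus calls, or NULL. By default the
#'   duplication evidence is extracted from the same alignments
#'   ([extract_cell_svs()] + [merge_across_cells()] with `min_cells = 4` and
#'   no read-support floor — junction evidence is single-read by nature at
#'   sparse per-cell coverage).
#' @param max_query_gap,junction_tol,dup_tol,merge_tol,min_cells,min_dup_cells
#'   Stage parameters; see the stage functions.
#' @param mito_chrom Name of the mitochondrial contig (default "chrM").
#' @return List with `candidates` (merged, annotated nuclear candidates),
#'   `mito` (candidates on `mito_chrom`), `per_read` (post-filter per-read
#'   table), and `n_detected`, `n_after_repeat_filter`, `n_after_dup_filter`
#'   stage counts.
#' @export
detect_ecdna <- function(alignments, trf_intervals = NULL, dup_calls = NULL,
                         max_query_gap = 50, junction_tol = 50,
                         dup_tol = 100, merge_tol = 50, min_cells = 2,
                         min_dup_cells = 4, mito_chrom = "chrM") {
  per_read <- detect_chiastic_reads(alignments, max_query_gap, junction_tol)
  n_detected <- nrow(per_read)
  if (!is.null(trf_intervals)) {
    per_read <- filter_tandem_repeats(per_read, trf_intervals,
                                      junction_tol = junction_tol)
  }
  n_repeat <- nrow(per_read)
  if (is.null(dup_calls)) {
    dup_calls <- merge_across_cells(
      extract_cell_svs(alignments), min_cells = min_dup_cells)
  }
  per_read <- filter_duplications(per_read, dup_calls,
                                  min_dup_cells = min_dup_cells, tol = dup_tol)
  n_dup <- nrow(per_read)
  is_mito <- per_read$chrom == mito_chrom
  nuclear <- merge_ecdna(per_read[!is_mito, , drop = FALSE],
                         tol = merge_tol, min_cells = min_cells)
  nuclear <- same_length_evidence(nuclear, per_read[!is_mito, , drop = FALSE])
  mito <- merge_ecdna(per_read[is_mito, , drop = FALSE],
                      tol = merge_tol, min_cells = 1)
  list(candidates = nuclear, mito = mito, per_read = per_read,
       n_detected = n_detected, n_after_repeat_filter = n_repeat,
       n_after_dup_filter = n_dup)
}
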