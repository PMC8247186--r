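# Windowed copy-number profiling: per-window read ratios, ploidy
# normalization, coefficient of variation against a baseline, and
# inter-profile correlation. Windows tile each chromosome (last window
# truncated); reads are assigned to the window containing the leftmost
# position of their primary segment.

genome_windows <- function(reference_lengths, window_size = 1e6) {
  stopifnot(window_size > 0)
  map_dfr(names(reference_lengths), function(ch) {
    L <- reference_lengths[[ch]]
    starts <- seq(0, L - 1, by = window_size)
    tibble(chrom = ch, start = starts, end = pmin(starts + window_size, L))
  })
}

#' Count reads per genomic window
#'
#' Each read is counted once, in the window containing the leftmost reference
#' position of its primary alignment segment. `ratio` is the window count
#' divided by the total number of counted reads.
#'
#' @param alignments Segment-level alignment tibble (see [read_alignments()]).
#' @param reference_lengths Named vector of chromosome lengths.
#' @param window_size Window width in bp (1 Mb default).
#' @param gaps Optional interval tibble of assembly gaps; windows overlapping
#'   any gap are masked (`gap = TRUE`) and excluded from normalization, CV and
#'   correlation.
#' @return A CNV profile tibble: `chrom`, `start`, `end`, `count`, `ratio`,
#'   `gap`. Reads on chromosomes absent from `reference_lengths` are skipped
#'   with a warning.
#' @export
window_counts <- function(alignments, reference_lengths, window_size = 1e6,
                          gaps = NULL) {
  wins <- genome_windows(reference_lengths, window_size)
  prim <- alignments[alignments$primary, , drop = FALSE]
  unknown <- setdiff(unique(prim$chrom), names(reference_lengths))
  if (length(unknown) > 0) {
    warn(paste0("skipping reads on unknown chromosome(s): ",
                paste(unknown, collapse = ", ")))
    prim <- prim[!prim$chrom %in% unknown, , drop = FALSE]
  }
  counts <- integer(nrow(wins))
  if (nrow(prim) > 0) {
    widx <- match(
      paste0(prim$chrom, ":", floor(prim$start / window_size)),
      paste0(wins$chrom, ":", floor(wins$start / window_size)))
    tab <- table(widx)
    counts[as.integer(names(tab))] <- as.integer(tab)
  } else {
    inform("empty profile: no counted reads")
  }
  wins$count <- counts
  wins$ratio <- if (sum(counts) > 0) counts / sum(counts) else rep(0, length(counts))
  wins$gap <- FALSE
  if (!is.null(gaps) && nrow(gaps) > 0) {
    for (i in seq_len(nrow(gaps))) {
      hit <- overlap_width(wins$chrom, wins$start, wins$end,
                           gaps$chrom[i], gaps$start[i], gaps$end[i]) > 0
      wins$gap <- wins$gap | hit
    }
  }
  wins
}

#' Normalize window ratios to a target ploidy
#'
#' Multiplies the per-window ratios by the unique constant that makes their
#' mean over unmasked windows equal `ploidy` (e.g. 3 for a triploid line, 2
#' for diploid cells).
#'
#' @param profile CNV profile from [window_counts()].
#' @param ploidy Target mean copy number (>= 1).
#' @return The profile with a `copy_number` column added.
#' @export
normalize_to_ploidy <- function(profile, ploidy) {
  stopifnot(ploidy >= 1)
  use <- !profile$gap
  m <- mean(profile$ratio[use])
  if (!is.finite(m) || m <= 0) {
    abort("cannot normalize an all-zero profile: no scaling constant exists")
  }
  profile$copy_number <- profile$ratio * (ploidy / m)
  profile
}

#' Coefficient of variation of a profile against a baseline
#'
#' Computes the per-window quotient cell/baseline over windows unmasked in
#' both profiles, and returns its sample standard deviation divided by its
#' mean. Used as the noise measure of single-cell copy-number profiling; the
#' baseline is typically the mean single-cell profile or a bulk profile on
#' identical windows.
#'
#' @param profile,baseline CNV profiles with `copy_number` on identical
#'   windows.
#' @return A single non-negative number.
#' @export
compute_cv <- function(profile, baseline) {
  if (nrow(profile) != nrow(baseline) ||
      !all(profile$chrom == baseline$chrom & profile$start == baseline$start)) {
    abort("profile and baseline must be on identical windows")
  }
  use <- !profile$gap & !baseline$gap
  if (sum(use) < 2) abort("need at least 2 unmasked windows to compute CV")
  if (any(baseline$copy_number[use] <= 0)) {
    abort("baseline copy number must be positive on unmasked windows")
  }
  q <- profile$copy_number[use] / baseline$copy_number[use]
  sd(q) / mean(q)
}

#' Pearson correlation of two segmented profiles
#'
#' Correlates per-window segmented copy numbers, removing windows masked in
#' either profile.
#'
#' @param a,b CNV profiles with a `segment_mean` column (see [cbs_segment()]),
#'   or `cbs_fit` objects.
#' @return Pearson r in `[-1, 1]`.
#' @export
profile_correlation <- function(a, b) {
  if (inherits(a, "cbs_fit")) a <- a$profile
  if (inherits(b, "cbs_fit")) b <- b$profile
  if (!"segment_mean" %in% names(a) || !"segment_mean" %in% names(b)) {
    abort("profiles must carry segment_mean (run cbs_segment first)")
  }
  if (nrow(a) != nrow(b) || !all(a$chrom == b$chrom & a$start == b$start)) {
    abort("profiles must be on identical windows")
  }
  use <- !a$gap & !b$gap & !is.na(a$segment_mean) & !is.na(b$segment_mean)
  x <- a$segment_mean[use]; y <- b$segment_mean[use]
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in a segmented profile: correlation undefined")
  }
  cor(x, y)
}
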