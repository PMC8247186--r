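#' Test duplication placement along chromosome arms
#'
#' Assigns each duplication a relative position r in [0, 1) along its
#' chromosome arm — 0 at the centromere, 1 at the telomere — bins the pooled
#' positions into `n_windows` equal windows, and tests the counts against the
#' uniform multinomial with a chi-square goodness-of-fit test
#' (df = n_windows - 1). A telomeric excess of duplication events shows up as
#' inflated counts in the high-r windows and a small p-value.
#'
#' @param dup_calls SV call tibble of DUP calls (positions taken at the
#'   interval midpoint).
#' @param arms Arm annotation: tibble with `chrom`, `start`, `end`, `arm`
#'   ("p": telomere at `start`; "q": telomere at `end`), as produced by
#'   [build_reference()] or read from an arms BED.
#' @param n_windows Number of centromere-to-telomere windows (default 100).
#' @return List with `counts` (tibble `window`, `n`), `statistic`, `p_value`,
#'   and `n_used`. Duplications falling outside every arm are skipped with a
#'   warning.
#' @export
duplication_telomere_test <- function(dup_calls, arms, n_windows = 100) {
  dup <- dup_calls[dup_calls$svtype == "DUP", , drop = FALSE]
  if (!all(c("chrom", "start", "end", "arm") %in% names(arms))) {
    abort("arms must have columns chrom, start, end, arm")
  }
  pos <- (dup$start + dup$end) / 2
  r <- rep(NA_real_, nrow(dup))
  for (i in seq_len(nrow(dup))) {
    hit <- which(arms$chrom == dup$chrom[i] & arms$start <= pos[i] &
                   arms$end > pos[i])
    if (length(hit) == 0) next
    a <- arms[hit[1], ]
    cen <- if (a$arm == "p") a$end else a$start
    tel <- if (a$arm == "p") a$start else a$end
    r[i] <- (pos[i] - cen) / (tel - cen)
  }
  skipped <- sum(is.na(r))
  if (skipped > 0) {
    warn(sprintf("%d duplication(s) outside any annotated arm skipped",
                 skipped))
  }
  r <- r[!is.na(r)]
  if (length(r) == 0) abort("no duplications fall within the annotated arms")
  win <- pmin(floor(r * n_windows) + 1L, n_windows)
  counts <- tabulate(win, nbins = n_windows)
  test <- suppressWarnings(
    chisq.test(counts, p = rep(1 / n_windows, n_windows)))
  list(counts = tibble(window = seq_len(n_windows), n = counts),
       statistic = unname(test$statistic),
       p_value = unname(test$p.value),
       n_used = length(r))
}
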