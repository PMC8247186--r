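# Circular binary segmentation in its basic form: recursive splitting of each
# chromosome's window vector on the maximal circularized two-sample
# t-statistic, with a permutation test deciding whether a split is accepted.
# No pruning or undo heuristics; the target is planted-changepoint recovery,
# not equivalence with any particular production implementation.

# max over arcs (i, j] of the two-sample t statistic (arc vs complement)
max_arc_t <- function(x) {
  n <- length(x)
  if (n < 3) return(list(stat = 0, i = 0L, j = n))
  S <- c(0, cumsum(x))
  Q <- c(0, cumsum(x^2))
  idx <- which(upper.tri(matrix(TRUE, n + 1, n + 1)), arr.ind = TRUE)
  i <- idx[, 1] - 1L
  j <- idx[, 2] - 1L
  k <- j - i
  keep <- k > 0 & k < n
  i <- i[keep]; j <- j[keep]; k <- k[keep]
  sum_in <- S[j + 1] - S[i + 1]
  ss_in <- Q[j + 1] - Q[i + 1]
  m_in <- sum_in / k
  m_out <- (S[n + 1] - sum_in) / (n - k)
  ss_out <- Q[n + 1] - ss_in
  pooled <- (ss_in - k * m_in^2 + ss_out - (n - k) * m_out^2) / pmax(n - 2, 1)
  pooled <- pmax(pooled, 1e-12)
  t <- abs(m_in - m_out) / sqrt(pooled * (1 / k + 1 / (n - k)))
  best <- which.max(t)
  list(stat = t[best], i = i[best], j = j[best])
}

# The permutation stream of each recursion node is seeded from (seed, node
# offset, node length) only, so the p-value at a node is a pure function of
# its data. This makes the accepted-split set nested across alpha: lowering
# alpha can only prune splits, never add them.
segment_vector <- function(x, alpha, n_perm, seed, lo = 0L) {
  n <- length(x)
  if (n < 3 || sd(x) == 0) return(rep(1L, n))
  obs <- max_arc_t(x)
  exceed <- 0L
  with_seed((seed + lo * 7919L + n) %% .Machine$integer.max, {
    for (p in seq_len(n_perm)) {
      if (max_arc_t(sample(x))$stat >= obs$stat) exceed <- exceed + 1L
      if (exceed > alpha * n_perm) break  # significance no longer reachable
    }
  })
  pval <- (exceed + 1) / (n_perm + 1)
  if (pval >= alpha) return(rep(1L, n))
  cuts <- sort(unique(c(obs$i, obs$j)))
  cuts <- cuts[cuts > 0 & cuts < n]
  if (length(cuts) == 0) return(rep(1L, n))
  bounds <- c(0, cuts, n)
  seg <- integer(n)
  nxt <- 0L
  for (b in seq_len(length(bounds) - 1)) {
    a <- bounds[b] + 1; hi <- bounds[b + 1]
    sub <- segment_vector(x[a:hi], alpha, n_perm, seed, lo + a)
    seg[a:hi] <- sub + nxt
    nxt <- nxt + max(sub)
  }
  seg
}

#' Segment a copy-number profile by circular binary segmentation
#'
#' Recursively splits each chromosome's unmasked window vector at the arc
#' maximizing the circularized two-sample t-statistic; a split is accepted
#' when its permutation p-value is below `alpha`. Deterministic given `seed`.
#'
#' @param profile Normalized CNV profile (needs `copy_number`; see
#'   [normalize_to_ploidy()]).
#' @param seed RNG seed for the permutation test.
#' @param alpha Significance level for accepting a split.
#' @param n_perm Number of permutations.
#' @return A `cbs_fit` object: list with `profile` (input plus `segment` and
#'   `segment_mean` columns; masked windows get NA) and `segments` (one row
#'   per segment: `chrom`, `start`, `end`, `n_windows`, `mean`). Use [tidy()]
#'   for the segment table and [glance()] for fit summaries.
#' @examples
#' prof <- tibble::tibble(chrom = "chr1", start = (0:99) * 1e6,
#'   end = (1:100) * 1e6, count = 1, gap = FALSE,
#'   ratio = 1, copy_number = c(rep(3, 50), rep(2, 50)))
#' fit <- cbs_segment(prof, seed = 1, n_perm = 200)
#' tidy(fit)
#' @export
cbs_segment <- function(profile, seed = 1, alpha = 0.01, n_perm = 1000) {
  if (!"copy_number" %in% names(profile)) {
    abort("profile must be normalized (copy_number column) before segmentation")
  }
  profile$segment <- NA_integer_
  profile$segment_mean <- NA_real_
  offset <- 0L
  chroms <- unique(profile$chrom)
  for (ci in seq_along(chroms)) {
    rows <- which(profile$chrom == chroms[ci] & !profile$gap)
    if (length(rows) == 0) next
    seg <- segment_vector(profile$copy_number[rows], alpha, n_perm,
                          seed = seed + 1009L * ci)
    profile$segment[rows] <- seg + offset
    offset <- offset + max(seg)
  }
  means <- profile |>
    filter(!is.na(.data$segment)) |>
    group_by(.data$segment) |>
    mutate(segment_mean = mean(.data$copy_number)) |>
    ungroup()
  profile$segment_mean[!is.na(profile$segment)] <- means$segment_mean
  segments <- profile |>
    filter(!is.na(.data$segment)) |>
    group_by(.data$segment) |>
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), n_windows = n(),
              mean = .data$segment_mean[1], .groups = "drop")
  structure(list(profile = profile, segments = segments, alpha = alpha,
                 n_perm = n_perm, seed = seed),
            class = "cbs_fit")
}

#' @export
print.cbs_fit <- function(x, ...) {
  cat(sprintf("<cbs_fit> %d segment(s) over %d window(s) (alpha = %g, %d permutations)\n",
              nrow(x$segments), sum(!is.na(x$profile$segment)), x$alpha,
              x$n_perm))
  invisible(x)
}

#' @rdname cbs_segment
#' @param x A `cbs_fit` object.
#' @param ... Unused.
#' @export
tidy.cbs_fit <- function(x, ...) {
  x$segments
}

#' @rdname cbs_segment
#' @export
glance.cbs_fit <- function(x, ...) {
  resid <- x$profile$copy_number - x$profile$segment_mean
  tibble(n_segments = nrow(x$segments),
         n_windows = sum(!is.na(x$profile$segment)),
         sigma = sd(resid[!is.na(resid)]),
         alpha = x$alpha, n_perm = x$n_perm)
}
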