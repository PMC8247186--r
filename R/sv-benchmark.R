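# Benchmarking of SV call sets against a truth set, with the six performance
# metrics: precision, recall, F1, false-positive rate, false-negative rate,
# and the harmonic mean of FPR and FNR.

#' Compute the SV benchmarking metrics from confusion counts
#'
#' Definitions: precision = TP/(TP+FP); recall = TP/(TP+FN);
#' FPR = FP/(TP+FP); FNR = FN/(TP+FN); HM = 2*FPR*FNR/(FPR+FNR) (0 when both
#' rates are 0); F1 = 2*precision*recall/(precision+recall) (0 when both are
#' 0). A 0/0 denominator yields NA — undefined is reported explicitly, never
#' silently set to 0.
#'
#' @param tp,fp,fn Non-negative confusion counts (vectorized).
#' @return Tibble with columns `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `fpr`, `fnr`, `hm`.
#' @examples
#' compute_metrics(3, 1, 2)
#' @export
compute_metrics <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) abort("confusion counts must be non-negative")
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  fpr <- safe_div(fp, tp + fp)
  fnr <- safe_div(fn, tp + fn)
  hm <- ifelse(is.na(fpr) | is.na(fnr), NA_real_,
               ifelse(fpr + fnr == 0, 0, 2 * fpr * fnr / (fpr + fnr)))
  f1 <- ifelse(is.na(precision) | is.na(recall), NA_real_,
               ifelse(precision + recall == 0, 0,
                      2 * precision * recall / (precision + recall)))
  tibble(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
         f1 = f1, fpr = fpr, fnr = fnr, hm = hm)
}

sv_call_matches <- function(test, truth, dist = 1000, tra_dist = 50000) {
  if (nrow(test) == 0 || nrow(truth) == 0) {
    return(tibble(test = integer(), truth = integer()))
  }
  pairs <- map_dfr(seq_len(nrow(test)), function(i) {
    t <- test[i, ]
    d <- if (t$svtype == "TRA") tra_dist else dist
    cand <- which(truth$svtype == t$svtype & truth$chrom == t$chrom)
    if (t$svtype == "TRA") {
      cand <- cand[!is.na(truth$chrom2[cand]) & truth$chrom2[cand] == t$chrom2]
      hit <- cand[abs(truth$start[cand] - t$start) <= d &
                    abs(truth$pos2[cand] - t$pos2) <= d]
    } else {
      hit <- cand[abs(truth$start[cand] - t$start) <= d &
                    abs(truth$end[cand] - t$end) <= d]
    }
    if (length(hit) == 0) return(NULL)
    tibble(test = i, truth = hit)
  })
  if (nrow(pairs) == 0) tibble(test = integer(), truth = integer()) else pairs
}

#' Benchmark an SV call set against a truth set
#'
#' A test call is a true positive when at least one truth call of the same
#' type has both breakpoints within `dist` bp (`tra_dist` for translocations).
#' With `multimatch` (the default) several test calls may match the same truth
#' call; otherwise matches are assigned greedily one-to-one in canonical
#' order. FN counts truth calls matched by no test call. Indels shorter than
#' 100 bp are conventionally excluded beforehand (see the `min_len` filter in
#' the caller).
#'
#' @param test_calls,truth_calls SV call tibbles.
#' @param dist,tra_dist Breakpoint tolerances in bp.
#' @param multimatch Allow many-to-one test-truth matches?
#' @return List with `metrics` (a [compute_metrics()] row) and `pairs`
#'   (matched index pairs into the canonical orderings of both sets).
#' @export
benchmark_svs <- function(test_calls, truth_calls, dist = 1000,
                          tra_dist = 50000, multimatch = TRUE) {
  test <- canonicalize_svs(test_calls)
  truth <- canonicalize_svs(truth_calls)
  pairs <- sv_call_matches(test, truth, dist, tra_dist)
  if (!multimatch && nrow(pairs) > 0) {
    used_test <- logical(nrow(test)); used_truth <- logical(nrow(truth))
    keep <- logical(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$test[r]; j <- pairs$truth[r]
      if (!used_test[i] && !used_truth[j]) {
        keep[r] <- TRUE; used_test[i] <- TRUE; used_truth[j] <- TRUE
      }
    }
    pairs <- pairs[keep, , drop = FALSE]
  }
  tp <- length(unique(pairs$test))
  fp <- nrow(test) - tp
  fn <- nrow(truth) - length(unique(pairs$truth))
  list(metrics = compute_metrics(tp, fp, fn), pairs = pairs)
}

#' Exclude indel calls shorter than a length floor
#'
#' Long-read platforms show frequent small indel errors; deletions and
#' insertions shorter than `min_len` are removed before benchmarking while
#' other SV types pass through.
#'
#' @param calls SV call tibble.
#' @param min_len Minimum |svlen| for DEL/INS (default 100 bp).
#' @return The retained calls.
#' @export
filter_short_indels <- function(calls, min_len = 100) {
  calls |>
    filter(!(.data$svtype %in% c("DEL", "INS") & abs(.data$svlen) < min_len))
}

#' Match deletions/insertions between two call sets, NGS-comparison style
#'
#' Deletions match when their reciprocal overlap is strictly greater than
#' `min_recip` in both directions; insertions match when their positions are
#' within `ins_dist` bp. Other SV types are rejected.
#'
#' @param a_calls,b_calls SV call tibbles containing only DEL and INS.
#' @param min_recip Reciprocal-overlap threshold (strict, default 0.10).
#' @param ins_dist Insertion breakpoint distance (default 1000 bp).
#' @return Tibble of matched index pairs `a`, `b` with `svtype`.
#' @export
match_ngs_style <- function(a_calls, b_calls, min_recip = 0.10,
                            ins_dist = 1000) {
  for (x in list(a_calls, b_calls)) {
    if (nrow(x) > 0 && !all(x$svtype %in% c("DEL", "INS"))) {
      abort("match_ngs_style handles only DEL and INS calls")
    }
  }
  if (nrow(a_calls) == 0 || nrow(b_calls) == 0) {
    return(tibble(a = integer(), b = integer(), svtype = character()))
  }
  map_dfr(seq_len(nrow(a_calls)), function(i) {
    x <- a_calls[i, ]
    cand <- which(b_calls$svtype == x$svtype & b_calls$chrom == x$chrom)
    if (length(cand) == 0) return(NULL)
    if (x$svtype == "INS") {
      hit <- cand[abs(b_calls$start[cand] - x$start) <= ins_dist]
    } else {
      ov <- overlap_width(x$chrom, x$start, x$end, b_calls$chrom[cand],
                          b_calls$start[cand], b_calls$end[cand])
      recip_a <- ov / (x$end - x$start)
      recip_b <- ov / (b_calls$end[cand] - b_calls$start[cand])
      hit <- cand[recip_a > min_recip & recip_b > min_recip]
    }
    if (length(hit) == 0) return(NULL)
    tibble(a = i, b = hit, svtype = x$svtype)
  })
}
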