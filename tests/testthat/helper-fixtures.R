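# Shared fixture builders and independent oracles used across tests.

# hand-built alignment rows (one call per segment)
seg_row <- function(read_id, segment, qs, qe, chrom, start, end,
                    strand = "+", read_length = qe, cell_id = "cellA",
                    cigar = paste0(end - start, "M"), primary = segment == 1) {
  tibble::tibble(read_id = read_id, cell_id = cell_id, segment = segment,
                 query_start = qs, query_end = qe, chrom = chrom,
                 start = start, end = end, strand = strand, mapq = 60L,
                 cigar = cigar, read_length = read_length, primary = primary)
}

# small simulation used by several files
tiny_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_cells = 3, chrom_lengths = c(chr1 = 2e6),
             per_cell_coverage = 0.2, ...)
}

# random SV call sets for property tests
random_calls <- function(n, seed, cells = paste0("cell", 1:4),
                         chroms = c("chr1", "chr2"), L = 1e6,
                         types = c("DEL", "INS", "DUP", "INV", "TRA")) {
  withr::with_seed(seed, {
    svtype <- sample(types, n, replace = TRUE)
    chrom <- sample(chroms, n, replace = TRUE)
    start <- round(runif(n, 1, L))
    len <- round(runif(n, 60, 5000))
    end <- ifelse(svtype == "INS", start + 1,
                  ifelse(svtype == "TRA", start + 1, start + len))
    sv_calls(svtype, chrom, start, end,
             svlen = ifelse(svtype == "DEL", -len,
                            ifelse(svtype == "TRA", 0, len)),
             chrom2 = ifelse(svtype == "TRA",
                             sample(chroms, n, replace = TRUE), NA),
             pos2 = ifelse(svtype == "TRA", round(runif(n, 1, L)), NA),
             read_support = sample(1:20, n, replace = TRUE),
             total_depth = 40L,
             cell_id = sample(cells, n, replace = TRUE))
  })
}

# Independent matcher: plain double loop over all call pairs.
oracle_match_counts <- function(test, truth, dist = 1000, tra_dist = 50000) {
  test <- canonicalize_svs(test)
  truth <- canonicalize_svs(truth)
  matched_test <- logical(nrow(test))
  matched_truth <- logical(nrow(truth))
  for (i in seq_len(nrow(test))) {
    for (j in seq_len(nrow(truth))) {
      if (test$svtype[i] != truth$svtype[j]) next
      if (test$chrom[i] != truth$chrom[j]) next
      if (test$svtype[i] == "TRA") {
        if (is.na(truth$chrom2[j]) || test$chrom2[i] != truth$chrom2[j]) next
        if (abs(test$start[i] - truth$start[j]) <= tra_dist &&
            abs(test$pos2[i] - truth$pos2[j]) <= tra_dist) {
          matched_test[i] <- TRUE; matched_truth[j] <- TRUE
        }
      } else {
        if (abs(test$start[i] - truth$start[j]) <= dist &&
            abs(test$end[i] - truth$end[j]) <= dist) {
          matched_test[i] <- TRUE; matched_truth[j] <- TRUE
        }
      }
    }
  }
  list(tp = sum(matched_test), fp = sum(!matched_test),
       fn = sum(!matched_truth))
}

# Independent single-linkage clustering: boolean link matrix + transitive
# closure by repeated sweeps.
oracle_single_linkage <- function(calls, dist = 1000, tra_dist = 50000) {
  n <- nrow(calls)
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (calls$svtype[i] != calls$svtype[j]) next
      if (calls$chrom[i] != calls$chrom[j]) next
      if (calls$svtype[i] == "TRA") {
        if (!identical(calls$chrom2[i], calls$chrom2[j])) next
        link[i, j] <- abs(calls$start[i] - calls$start[j]) <= tra_dist &&
          abs(calls$pos2[i] - calls$pos2[j]) <= tra_dist
      } else {
        link[i, j] <- abs(calls$start[i] - calls$start[j]) <= dist &&
          abs(calls$end[i] - calls$end[j]) <= dist
      }
    }
  }
  repeat {
    closure <- (link %*% link) > 0 | link
    if (identical(closure, link)) break
    link <- closure
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[link[i, ]] <- cur
      comp[i] <- cur
    }
  }
  comp
}

# partition of row indices as a canonical set-of-sets signature
partition_signature <- function(membership) {
  unname(sort(vapply(split(seq_along(membership), membership),
                     function(ix) paste(sort(ix), collapse = ","),
                     character(1))))
}
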