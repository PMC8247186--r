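# SAM/BAM reading and writing for segment-level alignment tables.
#
# The package-wide alignment representation is one tibble row per aligned
# segment (primary or supplementary record of the same read):
#   read_id, cell_id, segment (1-based rank along the read), query_start,
#   query_end (0-based half-open offsets on the original read), chrom, start,
#   end (0-based half-open reference span), strand, mapq, cigar (clip-free,
#   reference orientation), read_length, primary (logical).

CIGAR_QUERY_OPS <- c("M", "I", "S", "=", "X")
CIGAR_REF_OPS <- c("M", "D", "N", "=", "X")

parse_cigar_ops <- function(cigar, read_id = NULL) {
  ops <- tryCatch(
    list(op = explodeCigarOps(cigar)[[1]],
         len = explodeCigarOpLengths(cigar)[[1]]),
    error = function(e) {
      abort(sprintf("malformed CIGAR %s%s", cigar,
                    if (is.null(read_id)) "" else paste0(" for read ", read_id)))
    }
  )
  ops
}

cigar_query_width <- function(cigar) {
  ops <- parse_cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "=", "X")])
}

cigar_ref_width <- function(cigar) {
  ops <- parse_cigar_ops(cigar)
  sum(ops$len[ops$op %in% CIGAR_REF_OPS])
}

# clip lengths (S or H) at either end of a record CIGAR, SAM orientation
cigar_clips <- function(cigar, read_id = NULL) {
  ops <- parse_cigar_ops(cigar, read_id)
  n <- length(ops$op)
  left <- 0
  i <- 1
  while (i <= n && ops$op[i] %in% c("S", "H")) {
    left <- left + ops$len[i]
    i <- i + 1
  }
  right <- 0
  j <- n
  while (j >= i && ops$op[j] %in% c("S", "H")) {
    right <- right + ops$len[j]
    j <- j - 1
  }
  core <- if (i > j) "" else paste0(ops$len[i:j], ops$op[i:j], collapse = "")
  list(left = left, right = right, core = core)
}

#' Read per-cell long-read alignments from SAM or BAM
#'
#' Assembles one or more aligned segments per read from primary and
#' supplementary records. Secondary and unmapped records are dropped. Segments
#' are reported in query order, with offsets on the original (pre-mapping)
#' read so that split-read geometry can be reasoned about directly.
#'
#' @param path A SAM or BAM file. SAM input is converted on the fly.
#' @param cell_id Cell label attached to every read (defaults to the file
#'   name without extension).
#' @return A tibble with one row per aligned segment; columns `read_id`,
#'   `cell_id`, `segment`, `query_start`, `query_end`, `chrom`, `start`,
#'   `end`, `strand`, `mapq`, `cigar`, `read_length`, `primary`. Coordinates
#'   are 0-based half-open.
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1, n_cells = 1,
#'   chrom_lengths = c(chr1 = 2e6), per_cell_coverage = 0.05))
#' sam <- file.path(tempdir(), "cell.sam")
#' write_sam(sim$alignments, sam, sim$reference_lengths)
#' aln <- read_alignments(sam, cell_id = "cell001")
#' dplyr::count(aln, primary)
#' @export
read_alignments <- function(path, cell_id = NULL) {
  if (!file.exists(path)) abort(paste0("no such alignment file: ", path))
  if (is.null(cell_id)) {
    cell_id <- sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  res <- scanBam(bam, param = ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand")
  ))[[1]]
  n <- length(res$qname)
  if (n == 0) return(empty_alignments())
  keep <- bitwAnd(res$flag, 4L) == 0L & bitwAnd(res$flag, 256L) == 0L
  if (!any(keep)) return(empty_alignments())

  rows <- map_dfr(which(keep), function(i) {
    cg <- res$cigar[i]
    clips <- cigar_clips(cg, res$qname[i])
    qw <- cigar_query_width(clips$core)
    rw <- cigar_ref_width(clips$core)
    read_len <- clips$left + qw + clips$right
    minus <- as.character(res$strand[i]) == "-"
    qs <- if (minus) clips$right else clips$left
    tibble(
      read_id = res$qname[i],
      query_start = qs,
      query_end = qs + qw,
      chrom = as.character(res$rname[i]),
      start = res$pos[i] - 1,
      end = res$pos[i] - 1 + rw,
      strand = if (minus) "-" else "+",
      mapq = res$mapq[i],
      cigar = clips$core,
      read_length = read_len,
      primary = bitwAnd(res$flag[i], 2048L) == 0L
    )
  })

  rows |>
    mutate(cell_id = cell_id) |>
    group_by(.data$read_id) |>
    mutate(read_length = max(.data$read_length)) |>
    arrange(.data$query_start, .by_group = TRUE) |>
    mutate(segment = row_number()) |>
    ungroup() |>
    select("read_id", "cell_id", "segment", "query_start", "query_end",
           "chrom", "start", "end", "strand", "mapq", "cigar",
           "read_length", "primary") |>
    arrange(.data$read_id, .data$segment)
}

empty_alignments <- function() {
  tibble(read_id = character(), cell_id = character(), segment = integer(),
         query_start = numeric(), query_end = numeric(), chrom = character(),
         start = numeric(), end = numeric(), strand = character(),
         mapq = integer(), cigar = character(), read_length = numeric(),
         primary = logical())
}

#' Write a segment-level alignment table as SAM
#'
#' The inverse of [read_alignments()]: one SAM record per segment, the first
#' segment of each read emitted as the primary record and the rest as
#' supplementary (flag 0x800) with SA tags cross-referencing the other
#' segments. Sequences are written as `*` unless `seqs` supplies them; the
#' downstream pipeline only consumes alignment geometry.
#'
#' @param alignments Segment-level alignment tibble (see [read_alignments()]).
#' @param path Output SAM path.
#' @param reference_lengths Named vector of chromosome lengths for the header.
#' @param seqs Optional named character vector of read sequences
#'   (original read orientation), indexed by `read_id`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, reference_lengths, seqs = NULL) {
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(reference_lengths),
            as.integer(reference_lengths))
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(alignments) == 0) return(invisible(path))

  aln <- alignments |> arrange(.data$read_id, .data$segment)
  recs <- aln |>
    mutate(
      clip_left = ifelse(.data$strand == "+", .data$query_start,
                         .data$read_length - .data$query_end),
      clip_right = ifelse(.data$strand == "+",
                          .data$read_length - .data$query_end,
                          .data$query_start),
      sam_cigar = paste0(
        ifelse(.data$clip_left > 0, paste0(.data$clip_left, "S"), ""),
        .data$cigar,
        ifelse(.data$clip_right > 0, paste0(.data$clip_right, "S"), "")
      ),
      flag = ifelse(.data$strand == "-", 16L, 0L) +
        ifelse(.data$primary, 0L, 2048L)
    )

  sa_entry <- sprintf("%s,%d,%s,%s,%d,0;", recs$chrom, as.integer(recs$start) + 1L,
                      recs$strand, recs$sam_cigar, as.integer(recs$mapq))
  sa_tags <- vapply(seq_len(nrow(recs)), function(i) {
    others <- which(recs$read_id == recs$read_id[i])
    others <- setdiff(others, i)
    if (length(others) == 0) return("")
    paste0("\tSA:Z:", paste0(sa_entry[others], collapse = ""))
  }, character(1))

  seq_field <- rep("*", nrow(recs))
  if (!is.null(seqs)) {
    has <- recs$read_id %in% names(seqs)
    fwd <- seqs[recs$read_id[has]]
    rc <- as.character(reverseComplement(DNAStringSet(fwd)))
    seq_field[has] <- ifelse(recs$strand[has] == "-", rc, fwd)
  }

  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                   recs$read_id, recs$flag, recs$chrom,
                   as.integer(recs$start) + 1L, as.integer(recs$mapq),
                   recs$sam_cigar, seq_field, sa_tags)
  writeLines(lines, con)
  invisible(path)
}
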