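# Read-level simulation.
#
# A cell's genome is a set of molecules. Each linear molecule is a list of
# "pieces": matched reference blocks (type M, with chrom/start/end/strand) and
# inserted sequence (type I, consuming read bases only). Planted SVs reshape
# the piece list; planted circles are circular molecules handled at
# fragmentation time (a single Tn5 cut linearizes the full circle). Tn5
# cutting is a homogeneous Poisson process at rate 1/mean_fragment_bp; with
# one-adaptor chemistry every fragment between consecutive cuts is
# recoverable, and fragments shorter than `min_read_bp` are dropped at the
# sequencing step. Mapping a fragment back through the piece list yields the
# aligned segments and CIGAR of its read, plus truth rows recording which
# planted junctions the read spans.

SUPPORT_MARGIN_BP <- 100   # anchor needed on both sides to count as spanning
MAX_DEL_CIGAR_BP <- 1e5    # larger reference gaps split the alignment

#' Fragment a molecule by Tn5 tagmentation
#'
#' Cut positions are drawn as a homogeneous Poisson process at `rate` cuts per
#' bp; fragments are the gaps between consecutive cuts (and the molecule
#' ends), so they tile the molecule exactly. All fragments are returned —
#' one-adaptor tagmentation loses none of them; minimum-length filtering
#' belongs to the read-emission step, not here.
#'
#' @param molecule_length Molecule length in bp.
#' @param rate Cuts per bp (e.g. `1/6000` for a 6 kb fragment mode).
#' @return Tibble with `start`, `end` (0-based half-open on the molecule).
#' @examples
#' set.seed(1)
#' frags <- fragment_tn5(60e6, 1 / 6000)
#' mean(frags$end - frags$start)
#' @export
fragment_tn5 <- function(molecule_length, rate) {
  stopifnot(molecule_length > 0, rate >= 0)
  if (rate == 0) return(tibble(start = 0, end = molecule_length))
  n <- rpois(1, molecule_length * rate)
  cuts <- sort(unique(round(runif(n, 0, molecule_length))))
  cuts <- cuts[cuts > 0 & cuts < molecule_length]
  bounds <- c(0, cuts, molecule_length)
  tibble(start = bounds[-length(bounds)], end = bounds[-1])
}

# Pieces are kept as a plain data.frame (built once per molecule from
# accumulated vectors): piece construction sits on the per-cell hot path.
new_molecule <- function(id, pieces, junctions = NULL, circular = FALSE) {
  pieces$len <- ifelse(pieces$type == "M", pieces$end - pieces$start,
                       pieces$len)
  pieces$offset <- cumsum(pieces$len) - pieces$len
  if (is.null(junctions)) {
    junctions <- data.frame(pos = numeric(), event = character())
  }
  list(id = id, pieces = pieces, circular = circular,
       donor_len = sum(pieces$len), junctions = junctions)
}

m_piece <- function(chrom, start, end, strand = "+") {
  data.frame(type = "M", chrom = chrom, start = start, end = end,
             strand = strand, len = end - start)
}

piece_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$type <- character(); env$chrom <- character()
  env$start <- numeric(); env$end <- numeric(); env$strand <- character()
  env$ilen <- numeric(); env$donor <- 0
  env$j_pos <- numeric(); env$j_event <- character()
  env
}

pb_add_m <- function(pb, chrom, start, end, strand = "+") {
  if (end <= start) return(invisible())
  pb$type <- c(pb$type, "M"); pb$chrom <- c(pb$chrom, chrom)
  pb$start <- c(pb$start, start); pb$end <- c(pb$end, end)
  pb$strand <- c(pb$strand, strand); pb$ilen <- c(pb$ilen, NA_real_)
  pb$donor <- pb$donor + (end - start)
  invisible()
}

pb_add_i <- function(pb, len) {
  pb$type <- c(pb$type, "I"); pb$chrom <- c(pb$chrom, NA_character_)
  pb$start <- c(pb$start, NA_real_); pb$end <- c(pb$end, NA_real_)
  pb$strand <- c(pb$strand, "+"); pb$ilen <- c(pb$ilen, len)
  pb$donor <- pb$donor + len
  invisible()
}

pb_add_junction <- function(pb, pos, event) {
  pb$j_pos <- c(pb$j_pos, pos)
  pb$j_event <- c(pb$j_event, event)
  invisible()
}

pb_molecule <- function(pb, id, circular = FALSE) {
  pieces <- data.frame(type = pb$type, chrom = pb$chrom, start = pb$start,
                       end = pb$end, strand = pb$strand, len = pb$ilen)
  new_molecule(id, pieces,
               data.frame(pos = pb$j_pos, event = pb$j_event),
               circular = circular)
}

# Apply non-TRA SV events (sorted, non-overlapping) to the reference interval
# [ivl_start, ivl_end) of `chrom`, returning pieces + junction table.
build_haplotype_molecule <- function(id, chrom, ivl_start, ivl_end, events) {
  pb <- piece_builder()
  pos <- ivl_start
  if (nrow(events) > 0) {
    events <- events[order(events$start), ]
    for (i in seq_len(nrow(events))) {
      ev_type <- events$svtype[i]
      ev_start <- events$start[i]; ev_end <- events$end[i]
      if (ev_start < pos || ev_end > ivl_end) next  # outside this molecule
      if (ev_type == "DEL") {
        pb_add_m(pb, chrom, pos, ev_start)
        pb_add_junction(pb, pb$donor, events$event[i])
        pos <- ev_end
      } else if (ev_type == "INS") {
        pb_add_m(pb, chrom, pos, ev_start)
        pb_add_junction(pb, pb$donor + events$svlen[i] / 2, events$event[i])
        pb_add_i(pb, events$svlen[i])
        pos <- ev_start
      } else if (ev_type == "DUP") {
        pb_add_m(pb, chrom, pos, ev_end)
        pb_add_junction(pb, pb$donor, events$event[i])
        pb_add_m(pb, chrom, ev_start, ev_end)
        pos <- ev_end
      } else if (ev_type == "INV") {
        pb_add_m(pb, chrom, pos, ev_start)
        pb_add_junction(pb, pb$donor, events$event[i])
        pb_add_m(pb, chrom, ev_start, ev_end, "-")
        pb_add_junction(pb, pb$donor, events$event[i])
        pos <- ev_end
      }
    }
  }
  pb_add_m(pb, chrom, pos, ivl_end)
  pb_molecule(pb, id)
}

# Molecules of one cell: `ploidy` haplotypes per chromosome, with copy-number
# steps realized as region presence/absence per haplotype (plus extra
# region-only molecules for gains), planted SVs applied to every haplotype of
# a carrier cell, and a short fusion molecule per carried translocation.
build_cell_molecules <- function(reference, config, svs, circles) {
  lens <- reference$lengths
  mols <- list()
  linear_svs <- svs[svs$svtype != "TRA", , drop = FALSE]
  for (ch in names(lens)) {
    L <- lens[[ch]]
    steps <- config$cnv_steps[config$cnv_steps$chrom == ch, , drop = FALSE]
    ev_ch <- linear_svs[linear_svs$chrom == ch, , drop = FALSE]
    for (h in seq_len(config$ploidy)) {
      absent <- steps[steps$copy_number < h, , drop = FALSE]
      bounds <- sort(unique(c(0, L, absent$start, absent$end)))
      ivls <- tibble(start = bounds[-length(bounds)], end = bounds[-1])
      if (nrow(absent) > 0) {
        drop <- vapply(seq_len(nrow(ivls)), function(i) {
          any(ivls$start[i] >= absent$start & ivls$end[i] <= absent$end)
        }, logical(1))
        ivls <- ivls[!drop, , drop = FALSE]
      }
      for (i in seq_len(nrow(ivls))) {
        ev_in <- ev_ch[ev_ch$start >= ivls$start[i] & ev_ch$end <= ivls$end[i], ,
                       drop = FALSE]
        mols <- c(mols, list(build_haplotype_molecule(
          sprintf("%s_h%d_%d", ch, h, i), ch, ivls$start[i], ivls$end[i], ev_in)))
      }
    }
    if (nrow(steps) > 0) {
      gains <- steps[steps$copy_number > config$ploidy, , drop = FALSE]
      for (g in seq_len(nrow(gains))) {
        for (k in seq_len(gains$copy_number[g] - config$ploidy)) {
          mols <- c(mols, list(new_molecule(
            sprintf("%s_gain%d_%d", ch, g, k),
            m_piece(ch, gains$start[g], gains$end[g]))))
        }
      }
    }
  }
  tra <- svs[svs$svtype == "TRA", , drop = FALSE]
  if (nrow(tra) > 0) {
    for (i in seq_len(nrow(tra))) {
      fl <- config$tra_flank_bp
      a0 <- max(0, tra$start[i] - fl)
      b1 <- min(lens[[tra$chrom2[i]]], tra$pos2[i] + fl)
      pieces <- bind_rows(m_piece(tra$chrom[i], a0, tra$start[i]),
                          m_piece(tra$chrom2[i], tra$pos2[i], b1))
      mols <- c(mols, list(new_molecule(
        paste0("fusion_", tra$event[i]), pieces,
        tibble(pos = tra$start[i] - a0, event = tra$event[i]))))
    }
  }
  mols
}

# Map fragment [f0, f1) of a molecule through its pieces: returns a tibble of
# aligned segments (query offsets relative to the fragment) with clip-free
# reference-orientation CIGARs.
fragment_to_segments <- function(mol, f0, f1) {
  p <- mol$pieces
  hit <- which(p$offset < f1 & p$offset + p$len > f0)
  if (length(hit) == 0) return(NULL)

  # clip pieces to the fragment, tracking query offsets (vectorized)
  a <- pmax(f0, p$offset[hit]) - p$offset[hit]   # offset within piece
  b <- pmin(f1, p$offset[hit] + p$len[hit]) - p$offset[hit]
  c_type <- p$type[hit]
  c_strand <- p$strand[hit]
  c_chrom <- p$chrom[hit]
  c_qs <- p$offset[hit] + a - f0
  c_qe <- c_qs + (b - a)
  is_m <- c_type == "M"
  c_start <- ifelse(c_strand == "+", p$start[hit] + a, p$end[hit] - b)
  c_end <- ifelse(c_strand == "+", p$start[hit] + b, p$end[hit] - a)

  # drop I pieces at the fragment edges (unaligned read ends, like soft clips)
  m_idx <- which(is_m)
  if (length(m_idx) == 0) return(NULL)
  keep <- seq(min(m_idx), max(m_idx))
  c_type <- c_type[keep]; c_strand <- c_strand[keep]; c_chrom <- c_chrom[keep]
  c_qs <- c_qs[keep]; c_qe <- c_qe[keep]
  c_start <- c_start[keep]; c_end <- c_end[keep]
  is_m <- is_m[keep]

  # split into segments at non-colinear transitions
  n <- length(c_type)
  seg_id <- integer(n)
  cur <- 1L
  last_m <- 0L
  for (i in seq_len(n)) {
    if (last_m > 0L && is_m[i]) {
      colinear <- c_chrom[i] == c_chrom[last_m] &&
        c_strand[i] == c_strand[last_m] &&
        (if (c_strand[i] == "+") {
          gap <- c_start[i] - c_end[last_m]
          gap >= 0 && gap <= MAX_DEL_CIGAR_BP
        } else {
          gap <- c_start[last_m] - c_end[i]
          gap >= 0 && gap <= MAX_DEL_CIGAR_BP
        })
      if (!colinear) cur <- cur + 1L
    }
    seg_id[i] <- cur
    if (is_m[i]) last_m <- i
  }

  segs <- lapply(unique(seg_id), function(s) {
    idx <- which(seg_id == s)
    midx <- idx[is_m[idx]]
    strand <- c_strand[midx[1]]
    ops <- character(0)
    lens <- numeric(0)
    prev_m <- 0L
    for (i in idx) {
      if (!is_m[i]) {
        ops <- c(ops, "I"); lens <- c(lens, c_qe[i] - c_qs[i])
      } else {
        if (prev_m > 0L) {
          gap <- if (strand == "+") c_start[i] - c_end[prev_m]
                 else c_start[prev_m] - c_end[i]
          if (gap > 0) { ops <- c(ops, "D"); lens <- c(lens, gap) }
        }
        ops <- c(ops, "M"); lens <- c(lens, c_end[i] - c_start[i])
        prev_m <- i
      }
    }
    if (strand == "-") { ops <- rev(ops); lens <- rev(lens) }
    # merge adjacent equal ops
    keep <- c(TRUE, ops[-1] != ops[-length(ops)])
    grp <- cumsum(keep)
    lens <- vapply(split(lens, grp), sum, numeric(1))
    ops <- ops[keep]
    data.frame(query_start = min(c_qs[idx]), query_end = max(c_qe[idx]),
               chrom = c_chrom[midx[1]], start = min(c_start[midx]),
               end = max(c_end[midx]), strand = strand,
               cigar = paste0(as.integer(lens), ops, collapse = ""))
  })
  as_tibble(do.call(rbind, segs))
}

#' Simulate the reads of one cell
#'
#' Fragments every molecule of the cell's genome with Tn5 cuts, keeps
#' fragments of at least `config$min_read_bp`, and samples fragments in random
#' order until the target per-cell coverage is reached. Reads spanning planted
#' junctions emit split or gapped alignments forced by the rearrangement
#' geometry; a circle molecule that received exactly one cut emits a
#' full-length read whose two same-strand segments are in chiastic order and
#' whose length equals the circle length.
#'
#' @param reference A [build_reference()] result.
#' @param config A [sim_config()].
#' @param cell_id Cell label.
#' @param svs,circles The planted variants carried by this cell (tibbles with
#'   an `event` id column; defaults to all configured, with ids `sv1..`,
#'   `circle1..`).
#' @return List with `alignments` (segment tibble, see [read_alignments()])
#'   and `origin` (one row per read: `read_id`, `cell_id`, `molecule`,
#'   `frag_start`, `frag_end`, `read_length`, `circular`, `full_length`,
#'   `events` list-column of spanned junction ids).
#' @export
simulate_cell <- function(reference, config, cell_id,
                          svs = NULL, circles = NULL) {
  svs <- svs %||% tag_events(config$svs, "sv")
  circles <- circles %||% tag_events(config$circles, "circle")
  rate <- 1 / config$mean_fragment_bp
  mols <- build_cell_molecules(reference, config, svs, circles)

  frag_list <- vector("list", length(mols))
  for (i in seq_along(mols)) {
    f <- fragment_tn5(mols[[i]]$donor_len, rate)
    f$mol <- i
    frag_list[[i]] <- f
  }

  # circles: linearize per copy at the first cut; k cuts give k fragments
  # (the wrap fragment spans the junction), one cut gives the full circle
  circ_mols <- list()
  if (nrow(circles) > 0) {
    for (i in seq_len(nrow(circles))) {
      L <- circles$end[i] - circles$start[i]
      for (copy in seq_len(circles$copies[i])) {
        k <- rpois(1, L * rate)
        if (k == 0) next
        cuts <- sort(round(runif(k, 0, L - 1)))
        c1 <- cuts[1]
        pieces <- if (c1 == 0) m_piece(circles$chrom[i], circles$start[i], circles$end[i])
          else bind_rows(
            m_piece(circles$chrom[i], circles$start[i] + c1, circles$end[i]),
            m_piece(circles$chrom[i], circles$start[i], circles$start[i] + c1))
        junc <- if (c1 == 0) NULL else tibble(pos = L - c1,
                                              event = circles$event[i])
        mol <- new_molecule(sprintf("%s_copy%d", circles$event[i], copy),
                            pieces, junc, circular = TRUE)
        circ_mols <- c(circ_mols, list(mol))
        idx <- length(mols) + length(circ_mols)
        bounds <- unique(c(0, cuts - c1, L))
        f <- tibble(start = bounds[-length(bounds)], end = bounds[-1],
                    mol = idx)
        frag_list[[length(frag_list) + 1]] <- f
      }
    }
  }
  mols <- c(mols, circ_mols)

  frags <- bind_rows(frag_list)
  frags <- frags[frags$end - frags$start >= config$min_read_bp, , drop = FALSE]
  target <- config$per_cell_coverage * sum(reference$lengths)
  if (nrow(frags) == 0 || sum(frags$end - frags$start) < target) {
    abort("per-cell coverage unreachable: not enough fragments pass the length filter")
  }
  frags <- frags[sample.int(nrow(frags)), , drop = FALSE]
  n_take <- which(cumsum(frags$end - frags$start) >= target)[1]
  frags <- frags[seq_len(n_take), , drop = FALSE]

  n_frag <- nrow(frags)
  frags$read_id <- sprintf("%s_r%05d", cell_id, seq_len(n_frag))

  # Fast path: a fragment wholly inside one matched piece maps to a single
  # gapless segment (and can span no planted junction). Only the rare
  # junction-crossing fragments need the general piece walk.
  single <- logical(n_frag)
  piece_idx <- integer(n_frag)
  for (m in unique(frags$mol)) {
    rows <- which(frags$mol == m)
    p <- mols[[m]]$pieces
    if (nrow(p) == 1 && p$type[1] == "M") {
      single[rows] <- TRUE
      piece_idx[rows] <- 1L
      next
    }
    i0 <- findInterval(frags$start[rows], p$offset)
    ok <- frags$end[rows] <= p$offset[i0] + p$len[i0] & p$type[i0] == "M"
    single[rows] <- ok
    piece_idx[rows] <- i0
  }

  fast <- NULL
  if (any(single)) {
    idx <- which(single)
    pc <- map_dfr(unique(frags$mol[idx]), function(m) {
      rows <- idx[frags$mol[idx] == m]
      mols[[m]]$pieces[piece_idx[rows], ]
    })
    idx <- idx[order(match(frags$mol[idx], unique(frags$mol[idx])))]
    f0 <- frags$start[idx]; f1 <- frags$end[idx]
    a <- f0 - pc$offset; b <- f1 - pc$offset
    fast <- tibble(
      read_id = frags$read_id[idx], cell_id = cell_id, segment = 1L,
      query_start = 0, query_end = f1 - f0,
      chrom = pc$chrom,
      start = ifelse(pc$strand == "+", pc$start + a, pc$end - b),
      end = ifelse(pc$strand == "+", pc$start + b, pc$end - a),
      strand = pc$strand, mapq = 60L,
      cigar = paste0(as.integer(f1 - f0), "M"),
      read_length = f1 - f0, primary = TRUE)
  }

  slow_idx <- which(!single)
  aln_list <- vector("list", length(slow_idx))
  for (k in seq_along(slow_idx)) {
    i <- slow_idx[k]
    mol <- mols[[frags$mol[i]]]
    segs <- fragment_to_segments(mol, frags$start[i], frags$end[i])
    if (is.null(segs) || nrow(segs) == 0) next
    segs$read_id <- frags$read_id[i]
    segs$cell_id <- cell_id
    segs$read_length <- frags$end[i] - frags$start[i]
    segs$mapq <- 60L
    segs <- segs |> arrange(.data$query_start) |>
      mutate(segment = row_number(),
             primary = row_number() ==
               which.max(.data$query_end - .data$query_start))
    aln_list[[k]] <- segs
  }

  alignments <- bind_rows(c(list(fast), aln_list))
  emitted <- unique(alignments$read_id)
  frags <- frags[frags$read_id %in% emitted, , drop = FALSE]

  # spanned planted junctions, scanned per molecule (few junctions each)
  events <- rep(list(character(0)), nrow(frags))
  for (m in unique(frags$mol)) {
    jn <- mols[[m]]$junctions
    if (nrow(jn) == 0) next
    rows <- which(frags$mol == m)
    for (j in seq_len(nrow(jn))) {
      hit <- rows[frags$start[rows] + SUPPORT_MARGIN_BP <= jn$pos[j] &
                    frags$end[rows] - SUPPORT_MARGIN_BP >= jn$pos[j]]
      for (r in hit) events[[r]] <- c(events[[r]], jn$event[j])
    }
  }
  mol_circ <- vapply(mols, `[[`, logical(1), "circular")
  mol_len <- vapply(mols, `[[`, numeric(1), "donor_len")
  mol_id <- vapply(mols, `[[`, character(1), "id")
  origin <- tibble(
    read_id = frags$read_id, cell_id = cell_id, molecule = mol_id[frags$mol],
    frag_start = frags$start, frag_end = frags$end,
    read_length = frags$end - frags$start,
    circular = mol_circ[frags$mol],
    full_length = mol_circ[frags$mol] & frags$start == 0 &
      frags$end == mol_len[frags$mol],
    events = map(events, unique))

  if (nrow(alignments) > 0) {
    alignments <- alignments |>
      arrange(.data$read_id, .data$segment) |>
      select("read_id", "cell_id", "segment", "query_start", "query_end",
             "chrom", "start", "end", "strand", "mapq", "cigar",
             "read_length", "primary")
  } else {
    alignments <- empty_alignments()
  }
  list(alignments = alignments, origin = origin)
}

tag_events <- function(x, prefix) {
  if (nrow(x) == 0) {
    x$event <- character(0)
  } else if (!"event" %in% names(x)) {
    x$event <- paste0(prefix, seq_len(nrow(x)))
  }
  x
}
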