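# A deliberately narrow VCF 4.2 dialect for structural-variant call sets:
# symbolic ALTs <DEL>/<INS>/<DUP>/<INV>, translocations as paired BND records
# reunited through MATEID, INFO keys SVTYPE/SVLEN/END/SUPPORT/DEPTH/CELL/
# SUPP_CELLS, FILTER values PASS/IMPRECISE/SHADOWED. Internally a call set is
# a tibble with 0-based half-open coordinates; POS/END are converted at this
# boundary only.

#' Construct a structural-variant call tibble
#'
#' One row per call. `svtype` is one of DEL, INS, DUP, INV, TRA. For TRA,
#' (`chrom`, `start`) is breakpoint 1 and (`chrom2`, `pos2`) breakpoint 2
#' (canonical order: breakpoint 1 sorts first); for the others `start`/`end`
#' span the affected reference interval (INS: `end = start + 1`). `svlen` is
#' signed (negative for DEL, 0 for TRA). `filter` is a semicolon-joined flag
#' string; `cells` a list-column of supporting cell ids (filled by
#' [merge_across_cells()]).
#'
#' @param svtype,chrom,start,end,chrom2,pos2,svlen,read_support,total_depth,filter,cell_id,cells
#'   Field vectors, recycled as in [tibble::tibble()].
#' @return A tibble with the call-set schema.
#' @export
sv_calls <- function(svtype, chrom, start, end, svlen = NA_real_,
                     chrom2 = NA_character_, pos2 = NA_real_,
                     read_support = NA_integer_, total_depth = NA_integer_,
                     filter = "PASS", cell_id = NA_character_, cells = NULL) {
  out <- tibble(svtype = as.character(svtype), chrom = as.character(chrom),
                start = as.numeric(start), end = as.numeric(end),
                chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
                svlen = as.numeric(svlen),
                read_support = as.integer(read_support),
                total_depth = as.integer(total_depth),
                filter = as.character(filter),
                cell_id = as.character(cell_id))
  if (is.null(cells)) {
    cells <- ifelse(is.na(out$cell_id), list(character(0)),
                    as.list(out$cell_id))
  }
  out$cells <- cells
  out$n_cells <- lengths(out$cells)
  bad <- !out$svtype %in% c("DEL", "INS", "DUP", "INV", "TRA")
  if (any(bad)) abort(paste0("unknown svtype: ", out$svtype[which(bad)[1]]))
  validate_intervals(out, "sv call")
  out
}

empty_sv_calls <- function() {
  sv_calls(character(), character(), numeric(), numeric())
}

#' Canonical ordering of an SV call set
#'
#' Orders TRA breakpoints so that breakpoint 1 sorts first, then sorts rows by
#' type, chromosome and position. Two call sets are "equal under canonical
#' ordering" when `canonicalize_svs()` of both are identical.
#'
#' @param calls SV call tibble.
#' @return The reordered tibble.
#' @export
canonicalize_svs <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  is_tra <- calls$svtype == "TRA"
  flip <- is_tra & (calls$chrom2 < calls$chrom |
                      (calls$chrom2 == calls$chrom & calls$pos2 < calls$start))
  flip[is.na(flip)] <- FALSE
  if (any(flip)) {
    tmp_c <- calls$chrom[flip]; tmp_p <- calls$start[flip]
    calls$chrom[flip] <- calls$chrom2[flip]
    calls$start[flip] <- calls$pos2[flip]
    calls$end[flip] <- calls$pos2[flip] + 1
    calls$chrom2[flip] <- tmp_c
    calls$pos2[flip] <- tmp_p
  }
  calls |> arrange(.data$svtype, .data$chrom, .data$start, .data$end,
                   .data$chrom2, .data$pos2, .data$cell_id)
}

sv_vcf_header <- function(reference_lengths = NULL) {
  c("##fileformat=VCFv4.2",
    if (!is.null(reference_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(reference_lengths),
              as.integer(reference_lengths))
    },
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed length of the variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"1-based inclusive end position\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting read count\">",
    "##INFO=<ID=DEPTH,Number=1,Type=Integer,Description=\"Read depth at the locus\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of the mate breakend\">",
    "##INFO=<ID=CELL,Number=1,Type=String,Description=\"Cell of origin\">",
    "##INFO=<ID=SUPP_CELLS,Number=.,Type=String,Description=\"Supporting cells after merging\">",
    "##FILTER=<ID=IMPRECISE,Description=\"Imprecise structural variation\">",
    "##FILTER=<ID=SHADOWED,Description=\"CNV overlaps with or is encapsulated by deletion\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

fmt_info <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, function(x) is.null(x) || (length(x) == 1 && is.na(x)),
                   logical(1))]
  paste0(names(kv), "=", vapply(kv, as.character, character(1)),
         collapse = ";")
}

#' Write an SV call set as VCF
#'
#' @param calls SV call tibble (see [sv_calls()]).
#' @param path Output path.
#' @param reference_lengths Optional named vector for `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path, reference_lengths = NULL) {
  lines <- sv_vcf_header(reference_lengths)
  calls <- canonicalize_svs(calls)
  if (nrow(calls) > 0) {
    body <- map_chr(seq_len(nrow(calls)), function(i) {
      x <- calls[i, ]
      cells <- x$cells[[1]]
      supp_cells <- if (length(cells) > 0) paste(cells, collapse = ",") else NA
      id <- sprintf("sv%05d", i)
      if (x$svtype == "TRA") {
        info1 <- fmt_info(SVTYPE = "BND", MATEID = paste0(id, "_2"),
                          SUPPORT = x$read_support, DEPTH = x$total_depth,
                          CELL = x$cell_id, SUPP_CELLS = supp_cells)
        info2 <- fmt_info(SVTYPE = "BND", MATEID = paste0(id, "_1"),
                          SUPPORT = x$read_support, DEPTH = x$total_depth,
                          CELL = x$cell_id, SUPP_CELLS = supp_cells)
        alt1 <- sprintf("N[%s:%d[", x$chrom2, as.integer(x$pos2) + 1L)
        alt2 <- sprintf("]%s:%d]N", x$chrom, as.integer(x$start) + 1L)
        paste(
          sprintf("%s\t%d\t%s_1\tN\t%s\t.\t%s\t%s", x$chrom,
                  as.integer(x$start) + 1L, id, alt1, x$filter, info1),
          sprintf("%s\t%d\t%s_2\tN\t%s\t.\t%s\t%s", x$chrom2,
                  as.integer(x$pos2) + 1L, id, alt2, x$filter, info2),
          sep = "\n")
      } else {
        info <- fmt_info(SVTYPE = x$svtype, SVLEN = as.integer(x$svlen),
                         END = as.integer(x$end), SUPPORT = x$read_support,
                         DEPTH = x$total_depth, CELL = x$cell_id,
                         SUPP_CELLS = supp_cells)
        sprintf("%s\t%d\t%s\tN\t<%s>\t.\t%s\t%s", x$chrom,
                as.integer(x$start) + 1L, id, x$svtype, x$filter, info)
      }
    })
    lines <- c(lines, unlist(strsplit(body, "\n", fixed = TRUE)))
  }
  writeLines(lines, path)
  invisible(path)
}

parse_info <- function(info) {
  if (info == "." || info == "") return(list())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, function(p) if (length(p) > 1) p[2] else TRUE)
  names(out) <- vapply(kv, `[`, character(1), 1)
  out
}

info_num <- function(info, key) {
  v <- info[[key]]
  if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
}

#' Read an SV call set from VCF
#'
#' Accepts the subset written by [write_sv_vcf()] (and pbsv-shaped files using
#' the same INFO keys). Paired BND records are reunited into single TRA calls
#' via MATEID; a BND without a resolvable mate is dropped with a warning. If
#' INFO/SUPPORT is absent, read support falls back to the alt depth of a
#' FORMAT `AD` field when one is present.
#'
#' @param path VCF path.
#' @return An SV call tibble in canonical order (see [sv_calls()]).
#' @export
read_sv_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such VCF: ", path))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) return(empty_sv_calls())
  fields <- str_split(body, "\t")

  recs <- map(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 8) abort(sprintf("truncated VCF record at line %d", i))
    info <- parse_info(f[8])
    svtype <- info[["SVTYPE"]]
    if (is.null(svtype)) {
      abort(sprintf("VCF record %s:%s lacks SVTYPE", f[1], f[2]))
    }
    support <- info_num(info, "SUPPORT")
    depth <- info_num(info, "DEPTH")
    if (is.na(support) && length(f) >= 10 && grepl("AD", f[9])) {
      keys <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      vals <- strsplit(f[10], ":", fixed = TRUE)[[1]]
      ad <- suppressWarnings(as.numeric(
        strsplit(vals[match("AD", keys)], ",", fixed = TRUE)[[1]]))
      if (length(ad) >= 2 && !anyNA(ad)) {
        support <- ad[2]
        if (is.na(depth)) depth <- sum(ad)
      }
    }
    cells <- info[["SUPP_CELLS"]]
    cells <- if (is.null(cells)) character(0) else
      strsplit(cells, ",", fixed = TRUE)[[1]]
    list(id = f[3], chrom = f[1], pos = as.numeric(f[2]) - 1,
         alt = f[5], filter = if (f[7] %in% c(".", "")) "PASS" else f[7],
         svtype = svtype, svlen = info_num(info, "SVLEN"),
         end = info_num(info, "END"), support = support, depth = depth,
         cell = info[["CELL"]] %||% NA_character_,
         mateid = info[["MATEID"]] %||% NA_character_, cells = cells)
  })

  is_bnd <- vapply(recs, function(r) r$svtype %in% c("BND", "TRA") &&
                     !is.na(r$mateid), logical(1))
  simple <- recs[!is_bnd]
  bnd <- recs[is_bnd]

  out <- list()
  if (length(simple) > 0) {
    out$simple <- map_dfr(simple, function(r) {
      sv_calls(r$svtype, r$chrom, r$pos,
               end = if (!is.na(r$end)) r$end else r$pos + 1,
               svlen = r$svlen, read_support = r$support,
               total_depth = r$depth, filter = r$filter, cell_id = r$cell,
               cells = list(r$cells))
    })
  }
  if (length(bnd) > 0) {
    ids <- vapply(bnd, `[[`, character(1), "id")
    done <- rep(FALSE, length(bnd))
    rows <- list()
    for (i in seq_along(bnd)) {
      if (done[i]) next
      j <- match(bnd[[i]]$mateid, ids)
      if (is.na(j) || done[j] || bnd[[j]]$mateid != ids[i]) {
        warn(sprintf("BND %s has no mate; dropped", ids[i]))
        done[i] <- TRUE
        next
      }
      a <- bnd[[i]]; b <- bnd[[j]]
      rows[[length(rows) + 1]] <- sv_calls(
        "TRA", a$chrom, a$pos, a$pos + 1, svlen = 0,
        chrom2 = b$chrom, pos2 = b$pos, read_support = a$support,
        total_depth = a$depth, filter = a$filter, cell_id = a$cell,
        cells = list(a$cells))
      done[i] <- TRUE; done[j] <- TRUE
    }
    if (length(rows) > 0) out$tra <- bind_rows(rows)
  }
  canonicalize_svs(bind_rows(out) %||% empty_sv_calls())
}

#' Construct an SNV call tibble
#'
#' @param chrom,pos,ref,alt,cell_id Field vectors; `pos` is 1-based. `ref` and
#'   `alt` are single bases and must differ.
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `cell_id`.
#' @export
snv_calls <- function(chrom, pos, ref, alt, cell_id = NA_character_) {
  out <- tibble(chrom = as.character(chrom), pos = as.numeric(pos),
                ref = toupper(as.character(ref)),
                alt = toupper(as.character(alt)),
                cell_id = as.character(cell_id))
  if (nrow(out) > 0) {
    ok <- out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T") &
      out$ref != out$alt
    if (!all(ok)) abort("SNVs must have single distinct bases in {A,C,G,T}")
  }
  out
}

#' Read / write a minimal SNV VCF
#'
#' @param path File path.
#' @return `read_snv_vcf()` returns an SNV tibble (see [snv_calls()]).
#' @export
read_snv_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) return(snv_calls(character(), numeric(), character(), character()))
  f <- do.call(rbind, str_split(body, "\t"))
  info <- lapply(f[, 8], parse_info)
  cells <- vapply(info, function(x) x[["CELL"]] %||% NA_character_, character(1))
  snv_calls(f[, 1], as.numeric(f[, 2]), f[, 4], f[, 5], cells)
}

#' @rdname read_snv_vcf
#' @param snvs SNV tibble.
#' @export
write_snv_vcf <- function(snvs, path) {
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=CELL,Number=1,Type=String,Description=\"Cell of origin\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(snvs) > 0) {
    snvs <- snvs |> arrange(.data$chrom, .data$pos, .data$alt)
    info <- ifelse(is.na(snvs$cell_id), ".", paste0("CELL=", snvs$cell_id))
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", snvs$chrom,
                              as.integer(snvs$pos), snvs$ref, snvs$alt, info))
  }
  writeLines(lines, path)
  invisible(path)
}
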