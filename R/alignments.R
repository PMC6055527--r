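# Spliced-alignment handling. Alignments live in a plain tibble with one
# row per SAM record and 0-based `pos`; all junction logic reads CIGAR N
# operations directly from that table.

SAM_COLS <- c("qname", "flag", "chrom", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq", "qual")

new_alignments <- function(df, seqinfo = NULL) {
  out <- tibble::as_tibble(df)
  attr(out, "seqinfo") <- seqinfo
  class(out) <- c("scm_alignments", class(tibble::tibble()))
  out
}

#' Read spliced RNA-seq alignments
#'
#' Reads SAM text (or BAM, via Rsamtools when installed) into an alignment
#' tibble with columns `qname, flag, chrom, pos, mapq, cigar, rnext, pnext,
#' tlen, seq, qual`. `pos` is converted to the package's 0-based convention.
#' Unmapped records are dropped.
#'
#' @param path A SAM (`.sam`) or BAM (`.bam`) file.
#' @return An alignment tibble; `attr(x, "seqinfo")` holds contig lengths
#'   when the header declares them.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("BAM input requires the Rsamtools package", call. = FALSE)
    }
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
               "mrnm", "mpos", "isize", "seq", "qual"))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    df <- tibble::tibble(
      qname = b$qname, flag = as.integer(b$flag),
      chrom = as.character(b$rname), pos = as.integer(b$pos) - 1L,
      mapq = as.integer(b$mapq), cigar = b$cigar,
      rnext = as.character(b$mrnm), pnext = as.integer(b$mpos),
      tlen = as.integer(b$isize),
      seq = as.character(b$seq), qual = as.character(b$qual))
    df <- df[!is.na(df$pos), , drop = FALSE]
    return(new_alignments(df))
  }
  ln <- readr::read_lines(path, progress = FALSE)
  hdr <- ln[startsWith(ln, "@")]
  body <- ln[!startsWith(ln, "@") & nzchar(ln)]
  seqinfo <- NULL
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq) > 0) {
    sn <- stringr::str_match(sq, "SN:([^\t]+)")[, 2]
    lnth <- as.integer(stringr::str_match(sq, "LN:([0-9]+)")[, 2])
    seqinfo <- tibble::tibble(chrom = sn, length = lnth)
  }
  if (length(body) == 0) {
    return(new_alignments(
      tibble::tibble(qname = character(), flag = integer(),
                     chrom = character(), pos = integer(), mapq = integer(),
                     cigar = character(), rnext = character(),
                     pnext = integer(), tlen = integer(), seq = character(),
                     qual = character()),
      seqinfo))
  }
  f <- stringr::str_split_fixed(body, "\t", 12)
  df <- tibble::tibble(
    qname = f[, 1], flag = as.integer(f[, 2]), chrom = f[, 3],
    pos = as.integer(f[, 4]) - 1L, mapq = as.integer(f[, 5]), cigar = f[, 6],
    rnext = f[, 7], pnext = as.integer(f[, 8]), tlen = as.integer(f[, 9]),
    seq = f[, 10], qual = f[, 11])
  df <- df[!bitwAnd(df$flag, 4L), , drop = FALSE]  # unmapped
  new_alignments(df, seqinfo)
}

#' Write an alignment tibble as coordinate-sorted SAM text
#'
#' @param alignments Alignment tibble (see [read_alignments()]).
#' @param path Output file.
#' @param genome Optional genome (`DNAStringSet`) supplying `@SQ` header
#'   lines; falls back to `attr(alignments, "seqinfo")`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, genome = NULL) {
  seqinfo <- attr(alignments, "seqinfo")
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    seqinfo <- tibble::tibble(chrom = names(genome),
                              length = Biostrings::width(genome))
  }
  hdr <- "@HD\tVN:1.6\tSO:coordinate"
  if (!is.null(seqinfo)) {
    hdr <- c(hdr, paste0("@SQ\tSN:", seqinfo$chrom, "\tLN:", seqinfo$length))
  }
  a <- dplyr::arrange(alignments, .data$chrom, .data$pos, .data$qname)
  rec <- paste(a$qname, a$flag, a$chrom, a$pos + 1L, a$mapq, a$cigar,
               a$rnext, a$pnext, a$tlen, a$seq, a$qual, sep = "\t")
  readr::write_lines(c(hdr, rec), path)
  invisible(path)
}

# Resolve a user-supplied alignment source (tibble or file path).
as_alignments <- function(x) {
  if (inherits(x, "scm_alignments")) return(x)
  if (is.character(x) && length(x) == 1) return(read_alignments(x))
  if (is.data.frame(x)) return(new_alignments(x))
  stop("cannot interpret alignment source", call. = FALSE)
}

# flag predicates -------------------------------------------------------------

flag_secondary <- function(flag) bitwAnd(flag, 256L) > 0L
flag_supplementary <- function(flag) bitwAnd(flag, 2048L) > 0L
flag_duplicate <- function(flag) bitwAnd(flag, 1024L) > 0L

#' Filter alignments to those usable for junction evidence
#'
#' Drops secondary and supplementary records, duplicate-marked records
#' (unless `include_duplicates`), and records below the mapping-quality
#' floor.
#'
#' @param alignments Alignment tibble.
#' @param min_mapq Minimum mapping quality (default 0: keep all).
#' @param include_duplicates Keep duplicate-marked records?
#' @return Filtered alignment tibble.
#' @export
usable_alignments <- function(alignments, min_mapq = 0,
                              include_duplicates = FALSE) {
  a <- alignments
  keep <- !flag_secondary(a$flag) & !flag_supplementary(a$flag) &
    a$mapq >= min_mapq
  if (!include_duplicates) keep <- keep & !flag_duplicate(a$flag)
  a[keep, , drop = FALSE]
}

# CIGAR ------------------------------------------------------------------------

REF_OPS <- c("M", "D", "N", "=", "X")
QUERY_OPS <- c("M", "I", "S", "=", "X")

# Long form: one row per CIGAR op with the 0-based reference interval it
# covers (width 0 for non-reference-consuming ops).
cigar_long <- function(alignments) {
  if (nrow(alignments) == 0) {
    return(tibble::tibble(row = integer(), op = character(), len = integer(),
                          ref_start = integer(), ref_end = integer()))
  }
  m <- stringr::str_match_all(alignments$cigar, "(\\d+)([MIDNSHP=X])")
  n_ops <- vapply(m, nrow, 0L)
  len <- as.integer(unlist(lapply(m, function(x) x[, 2]), use.names = FALSE))
  op <- unlist(lapply(m, function(x) x[, 3]), use.names = FALSE)
  row <- rep(seq_len(nrow(alignments)), n_ops)
  ref_len <- ifelse(op %in% REF_OPS, len, 0L)
  # per-row cumulative reference offset
  cum <- cumsum(ref_len)
  first_of_row <- !duplicated(row)
  base <- rep(c(0, cum[which(first_of_row)[-1] - 1L]), n_ops)
  ref_end_off <- cum - base
  ref_start_off <- ref_end_off - ref_len
  tibble::tibble(
    row = row, op = op, len = len,
    ref_start = alignments$pos[row] + as.integer(ref_start_off),
    ref_end = alignments$pos[row] + as.integer(ref_end_off))
}

#' Extract splice junctions (CIGAR N spans) from alignments
#'
#' @param alignments Alignment tibble.
#' @return Tibble with one row per N operation: `qname, flag, chrom, start,
#'   end, mapq` where `[start, end)` is the intron in 0-based half-open
#'   coordinates (first intronic base, last intronic base + 1).
#' @export
alignment_junctions <- function(alignments) {
  ops <- cigar_long(alignments)
  n <- ops[ops$op == "N", , drop = FALSE]
  tibble::tibble(
    qname = alignments$qname[n$row],
    flag = alignments$flag[n$row],
    chrom = alignments$chrom[n$row],
    start = n$ref_start,
    end = n$ref_end,
    mapq = alignments$mapq[n$row])
}

#' Tally unique-fragment support for every junction in a sample
#'
#' Fragments (read pairs sharing a name) are counted once even when both
#' mates span the junction.
#'
#' @param alignments Alignment tibble or SAM/BAM path.
#' @param min_mapq Minimum mapping quality per record.
#' @param include_duplicates Count duplicate-marked records?
#' @return Tibble `chrom, start, end, unique_read_support` sorted by
#'   coordinate.
#' @export
junction_support <- function(alignments, min_mapq = 20,
                             include_duplicates = FALSE) {
  a <- usable_alignments(as_alignments(alignments), min_mapq,
                         include_duplicates)
  j <- alignment_junctions(a)
  j %>%
    dplyr::distinct(.data$chrom, .data$start, .data$end, .data$qname) %>%
    dplyr::count(.data$chrom, .data$start, .data$end,
                 name = "unique_read_support") %>%
    dplyr::arrange(.data$chrom, .data$start, .data$end)
}

# Fragments whose alignment covers `pos` on `chrom`. M-type ops always
# count; N ops count when `include_gap` (a spliced read "spans" the base).
fragments_covering <- function(alignments, chrom, pos, include_gap = TRUE) {
  a <- alignments[alignments$chrom == chrom, , drop = FALSE]
  if (nrow(a) == 0) return(character(0))
  # cheap prefilter on full reference span
  ops <- cigar_long(a)
  keep_ops <- if (include_gap) c("M", "=", "X", "N") else c("M", "=", "X")
  hit <- ops$op %in% keep_ops & ops$ref_start <= pos & pos < ops$ref_end
  unique(a$qname[ops$row[hit]])
}

# Base call of each record at reference position `pos` (NA when the record
# does not align a query base there). Returns a character vector parallel
# to `alignments` rows.
base_at <- function(alignments, chrom, pos) {
  out <- rep(NA_character_, nrow(alignments))
  if (nrow(alignments) == 0) return(out)
  on_chrom <- alignments$chrom == chrom
  if (!any(on_chrom)) return(out)
  a <- alignments[on_chrom, , drop = FALSE]
  ops <- cigar_long(a)
  qlen <- ifelse(ops$op %in% QUERY_OPS, ops$len, 0L)
  cum <- cumsum(qlen)
  first <- !duplicated(ops$row)
  base <- rep(c(0, cum[which(first)[-1] - 1L]), rle(ops$row)$lengths)
  q_off_start <- (cum - qlen) - base
  hit <- ops$op %in% c("M", "=", "X") & ops$ref_start <= pos &
    pos < ops$ref_end
  idx <- which(hit)
  vals <- rep(NA_character_, nrow(a))
  if (length(idx) > 0) {
    rows <- ops$row[idx]
    qpos <- q_off_start[idx] + (pos - ops$ref_start[idx]) + 1L
    vals[rows] <- toupper(substr(a$seq[rows], qpos, qpos))
  }
  out[on_chrom] <- vals
  out
}
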