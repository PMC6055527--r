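#' Default column mapping for MAF-like mutation tables
#'
#' Maps the fields used by the pipeline to the column names of the common
#' MC3-style mutation annotation format. Override entries to read other
#' dialects, e.g. `maf_columns(sample_id = "sample")`.
#'
#' @param sample_id,gene,chrom,pos,ref_allele,alt_allele,variant_class,t_ref_count,t_alt_count
#'   Column names in the input file.
#' @return Named character vector mapping internal field -> file column.
#' @export
maf_columns <- function(sample_id = "Tumor_Sample_Barcode",
                        gene = "Hugo_Symbol",
                        chrom = "Chromosome",
                        pos = "Start_Position",
                        ref_allele = "Reference_Allele",
                        alt_allele = "Tumor_Seq_Allele2",
                        variant_class = "Variant_Classification",
                        t_ref_count = "t_ref_count",
                        t_alt_count = "t_alt_count") {
  c(sample_id = sample_id, gene = gene, chrom = chrom, pos = pos,
    ref_allele = ref_allele, alt_allele = alt_allele,
    variant_class = variant_class,
    t_ref_count = t_ref_count, t_alt_count = t_alt_count)
}

# Collapse the many MAF Variant_Classification spellings onto the
# pipeline's conventional-annotation classes.
normalize_variant_class <- function(x) {
  x0 <- tolower(gsub("[ _]", "", as.character(x)))
  dplyr::case_when(
    x0 %in% c("missense", "missensemutation") ~ "missense",
    x0 %in% c("silent", "synonymous") ~ "silent",
    x0 %in% c("splicesite", "spliceregion", "splicedonor",
              "spliceacceptor") ~ "splice_site",
    x0 %in% c("nonsense", "nonsensemutation", "nonstopmutation") ~ "nonsense",
    x0 %in% c("indel", "frameshiftdel", "frameshiftins", "inframedel",
              "inframeins", "frameshiftdeletion", "frameshiftinsertion",
              "inframedeletion", "inframeinsertion", "del", "ins") ~ "indel",
    x0 %in% c("noncoding", "intron", "3'utr", "5'utr", "3utr", "5utr",
              "igr", "rna", "5'flank", "3'flank", "5flank", "3flank",
              "noncodingregion") ~ "noncoding",
    TRUE ~ "other"
  )
}

validate_mutation_rows <- function(df) {
  allele_ok <- function(a) !is.na(a) & grepl("^[ACGTN-]+$", a)
  pos <- suppressWarnings(as.integer(df$pos))
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(pos) | pos < 1L] <- "position not a positive integer"
  bad_allele <- !allele_ok(df$ref_allele) | !allele_ok(df$alt_allele)
  reason[is.na(reason) & bad_allele] <- "allele not matching [ACGTN-]+"
  same <- !is.na(df$ref_allele) & !is.na(df$alt_allele) &
    df$ref_allele == df$alt_allele
  reason[is.na(reason) & same] <- "ref and alt alleles identical"
  cnt_bad <- (!is.na(df$t_ref_count) & df$t_ref_count < 0) |
    (!is.na(df$t_alt_count) & df$t_alt_count < 0)
  reason[is.na(reason) & cnt_bad] <- "negative allele count"
  reason
}

as_mutation_tbl <- function(df) {
  out <- tibble::as_tibble(df)
  out$pos <- as.integer(out$pos)
  out$pos0 <- out$pos - 1L
  out$t_ref_count <- as.integer(out$t_ref_count)
  out$t_alt_count <- as.integer(out$t_alt_count)
  out$variant_class <- normalize_variant_class(out$variant_class)
  dplyr::relocate(out, "sample_id", "gene", "chrom", "pos", "pos0",
                  "ref_allele", "alt_allele", "variant_class")
}

#' Read a MAF-like somatic mutation table
#'
#' Reads a tab-separated mutation table, validates each row, and returns a
#' tibble of mutation records. Positions are kept 1-based (`pos`, MAF
#' convention) alongside the 0-based `pos0` used by all interval arithmetic
#' in the package. Rows violating the record invariants are dropped with a
#' per-row diagnostic (kept in the `"rejected"` attribute); the read only
#' fails if every row is invalid or a required column is missing.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param columns Mapping from internal field names to file column names,
#'   see [maf_columns()]. `t_ref_count`/`t_alt_count` are optional.
#' @param batch_size If not `NULL`, return a list of tibbles each holding at
#'   most `batch_size` records (chunked processing of large tables).
#' @return A tibble of mutation records (or a list of tibbles when
#'   `batch_size` is given), with rejected rows in `attr(x, "rejected")`.
#' @export
read_mutations <- function(path, columns = maf_columns(), batch_size = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- setdiff(names(columns), c("t_ref_count", "t_alt_count"))
  missing <- required[!columns[required] %in% names(raw)]
  if (length(missing) > 0) {
    stop("mutation table is missing required column(s): ",
         paste(columns[missing], collapse = ", "), call. = FALSE)
  }
  df <- tibble::tibble(
    sample_id = raw[[columns[["sample_id"]]]],
    gene = raw[[columns[["gene"]]]],
    chrom = as.character(raw[[columns[["chrom"]]]]),
    pos = raw[[columns[["pos"]]]],
    ref_allele = toupper(raw[[columns[["ref_allele"]]]]),
    alt_allele = toupper(raw[[columns[["alt_allele"]]]]),
    variant_class = raw[[columns[["variant_class"]]]],
    t_ref_count = if (columns[["t_ref_count"]] %in% names(raw)) {
      suppressWarnings(as.integer(raw[[columns[["t_ref_count"]]]]))
    } else {
      NA_integer_
    },
    t_alt_count = if (columns[["t_alt_count"]] %in% names(raw)) {
      suppressWarnings(as.integer(raw[[columns[["t_alt_count"]]]]))
    } else {
      NA_integer_
    }
  )
  reason <- validate_mutation_rows(df)
  rejected <- df[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  kept <- df[is.na(reason), , drop = FALSE]
  if (nrow(kept) == 0) {
    stop("no valid mutation records in ", path, call. = FALSE)
  }
  if (nrow(rejected) > 0) {
    message(nrow(rejected), " mutation row(s) rejected; see attr(x, 'rejected')")
  }
  out <- as_mutation_tbl(kept)
  attr(out, "rejected") <- tibble::as_tibble(rejected)
  if (!is.null(batch_size)) {
    return(mutation_batches(out, batch_size))
  }
  out
}

#' Split mutation records into bounded batches
#'
#' @param mutations A mutation tibble.
#' @param batch_size Maximum records per batch (default 200).
#' @return List of tibbles, each with at most `batch_size` rows.
#' @export
mutation_batches <- function(mutations, batch_size = 200) {
  stopifnot(batch_size >= 1)
  n <- nrow(mutations)
  idx <- ceiling(seq_len(n) / batch_size)
  lapply(split(seq_len(n), idx), function(i) mutations[i, , drop = FALSE])
}

#' Write a mutation table back to MAF-like TSV
#'
#' Inverse of [read_mutations()]: writing then re-reading reproduces the
#' same records.
#'
#' @param mutations Mutation tibble.
#' @param path Output path.
#' @param columns Column mapping used for output headers.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mutations, path, columns = maf_columns()) {
  out <- tibble::tibble(
    a = mutations$sample_id, b = mutations$gene, c = mutations$chrom,
    d = mutations$pos, e = mutations$ref_allele, f = mutations$alt_allele,
    g = mutations$variant_class, h = mutations$t_ref_count,
    i = mutations$t_alt_count
  )
  names(out) <- unname(columns[c("sample_id", "gene", "chrom", "pos",
                                 "ref_allele", "alt_allele", "variant_class",
                                 "t_ref_count", "t_alt_count")])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Load a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet]; names are truncated at the
#'   first whitespace as aligners do.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

as_genome <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    return(read_genome(x))
  }
  if (is.character(x)) {
    return(Biostrings::DNAStringSet(x))
  }
  stopifnot(methods::is(x, "DNAStringSet"))
  x
}

#' Fetch genomic sequence for an interval
#'
#' Coordinates are 0-based half-open throughout the package; the minus
#' strand returns the reverse complement.
#'
#' @param genome Named `DNAStringSet` (or named character vector).
#' @param chrom Contig name.
#' @param start,end 0-based half-open interval, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return Uppercase sequence string.
#' @export
fetch_sequence <- function(genome, chrom, start, end, strand = "+") {
  genome <- as_genome(genome)
  if (!chrom %in% names(genome)) {
    stop("unknown contig: ", chrom, call. = FALSE)
  }
  if (!(start >= 0 && start < end)) {
    stop("invalid interval [", start, ", ", end, ")", call. = FALSE)
  }
  width <- length(genome[[chrom]])
  if (end > width) {
    stop("interval [", start, ", ", end, ") out of bounds for ", chrom,
         " (length ", width, ")", call. = FALSE)
  }
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

# ---- annotation / junction index -------------------------------------------

read_gtf_exons <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gtf")
    df <- tibble::as_tibble(as.data.frame(gr))
    df <- df[df$type == "exon", , drop = FALSE]
    return(tibble::tibble(
      chrom = as.character(df$seqnames),
      start = as.integer(df$start) - 1L,  # to 0-based half-open
      end = as.integer(df$end),
      strand = as.character(df$strand),
      gene = as.character(df$gene_name),
      transcript_id = as.character(df$transcript_id)
    ))
  }
  # fallback: minimal Ensembl-dialect GTF reader
  ln <- readr::read_lines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- stringr::str_split_fixed(ln, "\t", 9)
  keep <- f[, 3] == "exon"
  f <- f[keep, , drop = FALSE]
  attr_field <- function(attrs, key) {
    m <- stringr::str_match(attrs, paste0(key, ' "([^"]*)"'))
    m[, 2]
  }
  tibble::tibble(
    chrom = f[, 1],
    start = as.integer(f[, 4]) - 1L,
    end = as.integer(f[, 5]),
    strand = f[, 7],
    gene = attr_field(f[, 9], "gene_name"),
    transcript_id = attr_field(f[, 9], "transcript_id")
  )
}

#' Build a canonical-junction index from transcript annotation
#'
#' For every transcript, each gap between consecutive exons becomes one
#' canonical intron; introns shared between transcripts are stored once.
#' Genes whose symbol matches `hla_pattern` populate the HLA interval set
#' used to exclude cryptic sites in HLA loci.
#'
#' @param annotation Path to a GTF file (Ensembl attribute dialect:
#'   `gene_name`, `transcript_id`) or a tibble of exons with columns
#'   `chrom, start, end, strand, gene, transcript_id` (0-based half-open).
#' @param hla_pattern Regular expression on gene symbols defining HLA loci.
#' @return A `junction_index` object with elements `canonical_introns`,
#'   `gene_intervals` and `hla_intervals` (all tibbles, 0-based half-open).
#' @export
build_junction_index <- function(annotation, hla_pattern = "^HLA-") {
  exons <- if (is.character(annotation)) {
    read_gtf_exons(annotation)
  } else {
    tibble::as_tibble(annotation)
  }
  if (nrow(exons) == 0) stop("empty annotation", call. = FALSE)

  exons <- dplyr::arrange(exons, .data$transcript_id, .data$chrom, .data$start)
  by_tx <- split(exons, exons$transcript_id)
  intron_list <- list()
  skipped <- character(0)
  for (tx in names(by_tx)) {
    e <- by_tx[[tx]]
    if (nrow(e) < 2) next
    if (any(e$start[-1] < e$end[-nrow(e)])) {
      skipped <- c(skipped, tx)
      next
    }
    intron_list[[tx]] <- tibble::tibble(
      chrom = e$chrom[-1],
      start = e$end[-nrow(e)],
      end = e$start[-1],
      strand = e$strand[-1],
      gene = e$gene[-1]
    )
  }
  if (length(skipped) > 0) {
    warning("skipped transcript(s) with overlapping exons: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  canonical <- if (length(intron_list) > 0) {
    dplyr::distinct(dplyr::bind_rows(intron_list),
                    .data$chrom, .data$start, .data$end, .data$strand,
                    .keep_all = TRUE)
  } else {
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   strand = character(), gene = character())
  }
  canonical <- dplyr::arrange(canonical, .data$chrom, .data$start, .data$end)

  gene_intervals <- exons %>%
    dplyr::group_by(.data$gene, .data$chrom, .data$strand) %>%
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") %>%
    dplyr::select("gene", "chrom", "start", "end", "strand")

  hla_intervals <- gene_intervals[grepl(hla_pattern, gene_intervals$gene), ,
                                  drop = FALSE]
  structure(
    list(canonical_introns = canonical,
         gene_intervals = gene_intervals,
         hla_intervals = hla_intervals,
         hla_pattern = hla_pattern),
    class = "junction_index"
  )
}

#' @export
print.junction_index <- function(x, ...) {
  cat("<junction_index>", nrow(x$canonical_introns), "canonical introns,",
      nrow(x$gene_intervals), "genes,",
      nrow(x$hla_intervals), "HLA interval(s)\n")
  invisible(x)
}

#' @describeIn build_junction_index Tidy the canonical intron set of an
#'   index into a tibble.
#' @param x A `junction_index`.
#' @param ... Unused.
#' @export
tidy.junction_index <- function(x, ...) x$canonical_introns

#' Write alternative junctions as BED12
#'
#' One record per junction in the style of junction browsers: two anchor
#' blocks flanking the intron, score column carrying the unique supporting
#' read count.
#'
#' @param junctions Tibble with `chrom`, `start`, `end`,
#'   `unique_read_support` (0-based half-open intron coordinates).
#' @param path Output file.
#' @param flank Anchor block size in bp.
#' @return `path`, invisibly.
#' @export
write_junctions_bed <- function(junctions, path, flank = 20) {
  j <- junctions
  chrom_start <- pmax(j$start - flank, 0)
  chrom_end <- j$end + flank
  block1 <- j$start - chrom_start
  lines <- paste(
    j$chrom, chrom_start, chrom_end,
    paste0("JUNC", seq_len(nrow(j))),
    j$unique_read_support, ".",
    chrom_start, chrom_end, "255,0,0", 2,
    paste0(block1, ",", flank),
    paste0(0, ",", j$end - chrom_start),
    sep = "\t"
  )
  readr::write_lines(lines, path)
  invisible(path)
}
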