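# Mutant-protein reconstruction and neoepitope enumeration. The altered
# transcript is built by replacing the canonical intron with the
# alternative one, translating from the annotated start codon to the first
# stop, and windowing the mutant protein into 8-11-mers absent from the
# wild type. Binding affinity is consumed from a precomputed external
# predictor table, never computed here.

#' Construct a transcript model
#'
#' @param exons Tibble of exon intervals (`chrom, start, end`, 0-based
#'   half-open) in genomic order, non-overlapping.
#' @param strand `"+"` or `"-"`.
#' @param cds_start Genomic 0-based position of the first base of the
#'   start codon (on the plus strand of the reference).
#' @param protein_id Identifier for the translated product.
#' @return A `transcript_model` object.
#' @export
transcript_model <- function(exons, strand = "+", cds_start, protein_id = "p1") {
  exons <- dplyr::arrange(tibble::as_tibble(exons), .data$start)
  stopifnot(all(exons$start < exons$end),
            all(exons$start[-1] >= exons$end[-nrow(exons)]))
  structure(list(exons = exons, strand = strand,
                 cds_start = as.integer(cds_start),
                 protein_id = protein_id),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model>", x$protein_id, nrow(x$exons), "exons,",
      x$strand, "strand\n")
  invisible(x)
}

# Genomic exon set of the transcript after splicing at `junction` instead
# of the canonical intron it replaces (tibble of 0-based half-open
# intervals). Uses interval arithmetic: merge the replaced canonical
# gap(s) back into the transcribed region, then subtract the alternative
# intron.
mutant_exon_set <- function(tm, junction) {
  ex <- IRanges::IRanges(start = tm$exons$start + 1L, end = tm$exons$end)
  tx_span <- range(ex)
  if (junction$start + 1L < IRanges::start(tx_span) ||
      junction$end > IRanges::end(tx_span)) {
    stop("alternative junction lies outside the transcript", call. = FALSE)
  }
  alt <- IRanges::IRanges(start = junction$start + 1L, end = junction$end)
  gaps <- IRanges::gaps(ex, start = IRanges::start(tx_span),
                        end = IRanges::end(tx_span))
  replaced <- IRanges::subsetByOverlaps(gaps, alt)
  region <- IRanges::reduce(c(ex, replaced))
  new_ex <- IRanges::setdiff(region, alt)
  tibble::tibble(chrom = tm$exons$chrom[1],
                 start = IRanges::start(new_ex) - 1L,
                 end = IRanges::end(new_ex))
}

# Spliced transcript sequence over an exon set, with an optional
# substitution applied where the mutation falls inside an exon.
spliced_sequence <- function(genome, chrom, exons, strand, mutation = NULL) {
  parts <- vapply(seq_len(nrow(exons)), function(i) {
    p <- fetch_sequence(genome, chrom, exons$start[i], exons$end[i], "+")
    if (!is.null(mutation) && mutation_is_snv(mutation)) {
      m <- mutation_pos0(mutation)
      if (m >= exons$start[i] && m < exons$end[i]) {
        idx <- m - exons$start[i] + 1L
        substr(p, idx, idx) <- toupper(mutation$alt_allele)
      }
    }
    p
  }, character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

# Transcript coordinate (1-based) of a genomic position within an exon
# set, or NA when the position is spliced out.
transcript_coord <- function(exons, strand, pos0) {
  widths <- exons$end - exons$start
  hit <- which(pos0 >= exons$start & pos0 < exons$end)
  if (length(hit) == 0) return(NA_integer_)
  before <- if (hit > 1) sum(widths[seq_len(hit - 1)]) else 0L
  plus_coord <- before + (pos0 - exons$start[hit]) + 1L
  if (strand == "+") {
    as.integer(plus_coord)
  } else {
    as.integer(sum(widths) - plus_coord + 1L)
  }
}

translate_cds <- function(tx_seq, cds_pos) {
  cds <- substr(tx_seq, cds_pos, nchar(tx_seq))
  cds <- substr(cds, 1, (nchar(cds) %/% 3) * 3)
  if (nchar(cds) < 3) return("")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  sub("\\*.*$", "", aa)
}

#' Translate the wild-type transcript
#'
#' @param genome Genome.
#' @param tm A [transcript_model()].
#' @param mutation Optional substitution applied to the exonic sequence.
#' @return Protein string (start codon to first stop).
#' @export
translate_transcript <- function(genome, tm, mutation = NULL) {
  s <- spliced_sequence(genome, tm$exons$chrom[1], tm$exons, tm$strand,
                        mutation)
  cds_pos <- transcript_coord(tm$exons, tm$strand, tm$cds_start)
  if (is.na(cds_pos)) return("")
  translate_cds(s, cds_pos)
}

#' Translate the mutant protein implied by an alternative junction
#'
#' The alternative intron replaces the canonical intron it overlaps in
#' the spliced transcript (an alternative junction identical to a
#' canonical one reproduces the wild type); splice-in substitutions are
#' applied to the exonic sequence; translation runs from the annotated
#' start codon to the first in-frame stop. In-frame deletions shorten the
#' protein with intact flanks; frame shifts produce a novel C-terminus.
#'
#' @param genome Genome.
#' @param tm A [transcript_model()].
#' @param junction One-row alternative junction (`start`, `end`).
#' @param mutation Optional one-row mutation record.
#' @return Protein string; empty with `attr(, "reason")` when the start
#'   codon is lost.
#' @export
translate_mutant <- function(genome, tm, junction, mutation = NULL) {
  new_exons <- mutant_exon_set(tm, junction)
  s <- spliced_sequence(genome, tm$exons$chrom[1], new_exons, tm$strand,
                        mutation)
  cds_pos <- transcript_coord(new_exons, tm$strand, tm$cds_start)
  if (is.na(cds_pos)) {
    out <- ""
    attr(out, "reason") <- "start codon spliced out"
    return(out)
  }
  translate_cds(s, cds_pos)
}

#' Enumerate candidate neoepitopes from a mutant protein
#'
#' All windows of the requested lengths are taken from the mutant
#' protein; windows occurring as substrings of the wild-type protein are
#' removed (`novel_only`). When an external predictor's affinity table is
#' supplied, peptides above the binding threshold are dropped; peptides
#' missing from the table are retained with unknown affinity.
#'
#' @param mut_protein,wt_protein Protein strings.
#' @param lengths Peptide lengths (default 8:11).
#' @param affinity_table Optional tibble with columns `peptide`,
#'   `affinity_nM` (and optionally `allele`), e.g. parsed external
#'   predictor output.
#' @param threshold Maximum binding affinity in nM (default 500).
#' @param novel_only Drop peptides present in the wild type (default TRUE).
#' @return Tibble `peptide, length, position, affinity_nM` (plus `allele`
#'   when the affinity table carries one); `position` is 1-based within
#'   the mutant protein.
#' @export
enumerate_novel_epitopes <- function(mut_protein, wt_protein,
                                     lengths = 8:11, affinity_table = NULL,
                                     threshold = 500, novel_only = TRUE) {
  stopifnot(nchar(mut_protein) > 0, nchar(wt_protein) > 0)
  wins <- purrr::map_dfr(lengths, function(L) {
    n <- nchar(mut_protein) - L + 1L
    if (n < 1) return(NULL)
    tibble::tibble(
      peptide = substring(mut_protein, seq_len(n), seq_len(n) + L - 1L),
      length = L, position = seq_len(n))
  })
  if (novel_only && nrow(wins) > 0) {
    wins <- wins[!stringr::str_detect(wt_protein,
                                      stringr::fixed(wins$peptide)), ,
                 drop = FALSE]
  }
  wins <- dplyr::distinct(wins, .data$peptide, .data$length, .data$position)
  if (!is.null(affinity_table)) {
    if (!all(c("peptide", "affinity_nM") %in% names(affinity_table))) {
      stop("affinity table must have columns 'peptide' and 'affinity_nM'",
           call. = FALSE)
    }
    aff <- dplyr::as_tibble(affinity_table)
    best <- aff %>%
      dplyr::group_by(.data$peptide) %>%
      dplyr::slice_min(.data$affinity_nM, n = 1, with_ties = FALSE) %>%
      dplyr::ungroup()
    wins <- dplyr::left_join(wins, best, by = "peptide")
    wins <- wins[is.na(wins$affinity_nM) | wins$affinity_nM <= threshold, ,
                 drop = FALSE]
  } else {
    wins$affinity_nM <- NA_real_
  }
  dplyr::arrange(wins, .data$length, .data$position)
}
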