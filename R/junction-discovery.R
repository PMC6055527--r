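# Candidate alternative junction discovery near somatic mutations.

#' Discover candidate alternative junctions near a mutation
#'
#' Scans spliced alignments of the mutated sample for introns (CIGAR N
#' spans) whose nearer boundary lies within `window` bp of the mutation,
#' counting support as unique fragments (mate pairs counted once) with
#' mapping quality at or above `min_mapq`. Junctions with fewer than
#' `min_reads` unique supporting fragments are not emitted.
#'
#' @param alignments Alignment tibble or SAM/BAM path for the case sample.
#' @param mutation A one-row mutation tibble (or list) with at least
#'   `chrom` and `pos` (1-based) or `pos0` (0-based).
#' @param window Maximum distance (bp) from the mutation to the nearer
#'   intron boundary (default 20, the span of the splice region).
#' @param min_reads Minimum unique supporting fragments (default 5).
#' @param min_mapq Minimum mapping quality (default 20).
#' @param include_duplicates Count duplicate-marked records?
#' @return Tibble of candidate junctions sorted by `(chrom, start, end)`:
#'   `chrom, start, end, unique_read_support, distance_to_mutation,
#'   supporting_fragments` (list column of fragment names).
#' @export
discover_candidate_junctions <- function(alignments, mutation, window = 20,
                                         min_reads = 5, min_mapq = 20,
                                         include_duplicates = FALSE) {
  a <- as_alignments(alignments)
  mut_pos0 <- mutation_pos0(mutation)
  chrom <- as.character(mutation$chrom)
  if (nrow(a) > 0 && !chrom %in% unique(a$chrom)) {
    stop("mutation contig ", chrom, " absent from alignments", call. = FALSE)
  }
  a <- usable_alignments(a[a$chrom == chrom, , drop = FALSE], min_mapq,
                         include_duplicates)
  j <- alignment_junctions(a)
  candidate_table(j, chrom, mut_pos0, window, min_reads)
}

mutation_pos0 <- function(mutation) {
  if (!is.null(mutation$pos0)) return(as.integer(mutation$pos0))
  as.integer(mutation$pos) - 1L
}

# Shared tail of discovery: aggregate N spans into candidates.
candidate_table <- function(junctions, chrom, mut_pos0, window, min_reads) {
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    unique_read_support = integer(), distance_to_mutation = integer(),
    supporting_fragments = list())
  if (nrow(junctions) == 0) return(empty)
  out <- junctions %>%
    dplyr::filter(.data$chrom == !!chrom) %>%
    dplyr::distinct(.data$chrom, .data$start, .data$end, .data$qname) %>%
    dplyr::group_by(.data$chrom, .data$start, .data$end) %>%
    dplyr::summarise(unique_read_support = dplyr::n(),
                     supporting_fragments = list(sort(.data$qname)),
                     .groups = "drop") %>%
    dplyr::mutate(distance_to_mutation = pmin(abs(mut_pos0 - .data$start),
                                              abs(mut_pos0 - .data$end))) %>%
    dplyr::filter(.data$distance_to_mutation <= window,
                  .data$unique_read_support >= min_reads) %>%
    dplyr::arrange(.data$chrom, .data$start, .data$end) %>%
    dplyr::select("chrom", "start", "end", "unique_read_support",
                  "distance_to_mutation", "supporting_fragments")
  if (nrow(out) == 0) empty else out
}

#' Remove canonical and HLA-locus junctions, annotate the nearest canonical
#'
#' Candidates exactly matching an annotated intron are removed, as are
#' candidates overlapping an HLA gene interval. Survivors are annotated
#' with the nearest canonical intron: preferably one of the same gene
#' sharing a boundary with the candidate (the cryptic-site geometry), else
#' the canonical intron with the smallest boundary distance on the same
#' contig.
#'
#' @param candidates Output of [discover_candidate_junctions()].
#' @param index A [build_junction_index()] object.
#' @param mutation Optional one-row mutation record; when given, canonical
#'   introns of the mutation's gene are preferred for the nearest-canonical
#'   annotation.
#' @return Filtered candidate tibble with `nearest_canonical_start`,
#'   `nearest_canonical_end`, `nearest_canonical_strand` columns.
#' @export
filter_canonical_and_hla <- function(candidates, index, mutation = NULL) {
  out <- candidates
  canon <- index$canonical_introns
  if (nrow(out) > 0 && nrow(canon) > 0) {
    out <- dplyr::anti_join(out, canon, by = c("chrom", "start", "end"))
  }
  hla <- index$hla_intervals
  if (nrow(out) > 0 && nrow(hla) > 0) {
    in_hla <- vapply(seq_len(nrow(out)), function(i) {
      any(hla$chrom == out$chrom[i] &
            hla$start < out$end[i] & out$start[i] < hla$end)
    }, logical(1))
    out <- out[!in_hla, , drop = FALSE]
  }
  ann <- lapply(seq_len(nrow(out)), function(i) {
    nearest_canonical(out[i, ], canon, index,
                      gene = if (is.null(mutation)) NULL else mutation$gene)
  })
  out$nearest_canonical_start <- vapply(ann, function(x) x$start, integer(1))
  out$nearest_canonical_end <- vapply(ann, function(x) x$end, integer(1))
  out$nearest_canonical_strand <- vapply(ann, function(x) x$strand,
                                         character(1))
  out
}

nearest_canonical <- function(candidate, canon, index, gene = NULL) {
  none <- list(start = NA_integer_, end = NA_integer_,
               strand = NA_character_)
  cc <- canon[canon$chrom == candidate$chrom, , drop = FALSE]
  if (nrow(cc) == 0) return(none)
  pool <- cc
  if (!is.null(gene)) {
    same_gene <- cc[!is.na(cc$gene) & cc$gene == gene, , drop = FALSE]
    if (nrow(same_gene) > 0) pool <- same_gene
  }
  shared <- pool[pool$start == candidate$start | pool$end == candidate$end, ,
                 drop = FALSE]
  if (nrow(shared) > 0) pool <- shared
  d <- pmin(abs(pool$start - candidate$start), abs(pool$end - candidate$end),
            abs(pool$start - candidate$end), abs(pool$end - candidate$start))
  best <- pool[which.min(d), , drop = FALSE]
  list(start = as.integer(best$start), end = as.integer(best$end),
       strand = as.character(best$strand))
}
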