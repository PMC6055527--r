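# Junction usage quantification: junction allele fraction (JAF), spliced-in
# JAF, and the splice-in / splice-out classification.

#' Classify a mutation as splice-in or splice-out
#'
#' Splice-in mutations are contained in the newly created exon(s);
#' splice-out mutations fall inside the newly created intron. With
#' half-open intron coordinates the boundaries are exact: the first
#' intronic base is splice-out, the flanking exonic bases are splice-in.
#'
#' @param junction One-row tibble/list with `start`, `end` (0-based
#'   half-open alternative intron).
#' @param mutation One-row mutation record (`pos` 1-based or `pos0`).
#' @return `"splice_in"` or `"splice_out"`.
#' @export
classify_in_out <- function(junction, mutation) {
  p <- mutation_pos0(mutation)
  if (p >= junction$start && p < junction$end) "splice_out" else "splice_in"
}

# Anchor base for the JAF denominator: the exonic base immediately adjacent
# to the junction boundary nearer the mutation.
junction_anchor <- function(junction, mutation) {
  p <- mutation_pos0(mutation)
  if (abs(p - junction$start) <= abs(p - junction$end)) {
    junction$start - 1L
  } else {
    as.integer(junction$end)
  }
}

#' Compute the junction allele fraction (JAF)
#'
#' JAF is the fraction of fragments at the junction locus that span the
#' alternative junction. The locus is anchored at the exonic base adjacent
#' to the intron boundary nearer the mutation; the denominator counts
#' deduplicated fragments with an aligned base at the anchor or an N span
#' covering it, the numerator counts fragments whose N span matches the
#' intron exactly. Events below `jaf_min` are marked filtered.
#'
#' @param alignments Case-sample alignments (tibble or path).
#' @param junction One-row alternative junction (`chrom,start,end`).
#' @param mutation One-row mutation record (fixes the anchor side).
#' @param min_mapq Minimum mapping quality.
#' @param jaf_min Reporting threshold on JAF (default 0.05).
#' @param include_duplicates Count duplicate-marked records?
#' @return One-row tibble: `alt_junction_reads, locus_depth, jaf, anchor,
#'   jaf_filtered, jaf_filter_reason`.
#' @export
compute_jaf <- function(alignments, junction, mutation, min_mapq = 20,
                        jaf_min = 0.05, include_duplicates = FALSE) {
  a <- usable_alignments(as_alignments(alignments), min_mapq,
                         include_duplicates)
  anchor <- junction_anchor(junction, mutation)
  depth_frags <- fragments_covering(a, junction$chrom, anchor,
                                    include_gap = TRUE)
  j <- alignment_junctions(a)
  alt_frags <- unique(j$qname[j$chrom == junction$chrom &
                                j$start == junction$start &
                                j$end == junction$end])
  depth <- length(depth_frags)
  alt <- length(alt_frags)
  jaf <- if (depth > 0) alt / depth else NA_real_
  filtered <- is.na(jaf) || jaf < jaf_min
  reason <- if (depth == 0) {
    "no coverage at junction anchor"
  } else if (filtered) {
    sprintf("JAF %.3f below threshold %.3f", jaf, jaf_min)
  } else {
    NA_character_
  }
  tibble::tibble(alt_junction_reads = alt, locus_depth = depth, jaf = jaf,
                 anchor = anchor, jaf_filtered = filtered,
                 jaf_filter_reason = reason)
}

#' Compute the spliced-in JAF
#'
#' Among fragments supporting the alternative junction, the fraction whose
#' alignment covers the mutation position with the alternate allele. Only
#' defined for splice-in mutations whose position is covered by the exonic
#' portion of at least one junction-supporting fragment; otherwise the
#' fraction is reported as undefined (`NA`) rather than zero.
#'
#' @inheritParams compute_jaf
#' @return One-row tibble: `spliced_in_reads_with_mut, junction_reads_covering_mut,
#'   spliced_in_jaf`.
#' @export
spliced_in_jaf <- function(alignments, junction, mutation, min_mapq = 20,
                           include_duplicates = FALSE) {
  a <- usable_alignments(as_alignments(alignments), min_mapq,
                         include_duplicates)
  j <- alignment_junctions(a)
  alt_frags <- unique(j$qname[j$chrom == junction$chrom &
                                j$start == junction$start &
                                j$end == junction$end])
  undefined <- tibble::tibble(spliced_in_reads_with_mut = NA_integer_,
                              junction_reads_covering_mut = 0L,
                              spliced_in_jaf = NA_real_)
  if (length(alt_frags) == 0) return(undefined)
  sup <- a[a$qname %in% alt_frags, , drop = FALSE]
  base <- base_at(sup, as.character(mutation$chrom), mutation_pos0(mutation))
  cov <- tibble::tibble(qname = sup$qname, base = base) %>%
    dplyr::filter(!is.na(.data$base)) %>%
    dplyr::distinct(.data$qname, .data$base)
  if (nrow(cov) == 0) return(undefined)
  with_mut <- cov %>%
    dplyr::filter(.data$base == toupper(mutation$alt_allele)) %>%
    dplyr::distinct(.data$qname) %>%
    nrow()
  tibble::tibble(
    spliced_in_reads_with_mut = as.integer(with_mut),
    junction_reads_covering_mut = dplyr::n_distinct(cov$qname),
    spliced_in_jaf = with_mut / length(alt_frags))
}

#' Quantify one mutation-junction pairing
#'
#' Combines [classify_in_out()], [compute_jaf()] and (for splice-in
#' substitutions) [spliced_in_jaf()] into a single quantification row.
#'
#' @inheritParams compute_jaf
#' @return One-row tibble with the JAF fields, `in_out`, and the
#'   spliced-in fields (`NA` for splice-out events).
#' @export
quantify_junction <- function(alignments, junction, mutation, min_mapq = 20,
                              jaf_min = 0.05, include_duplicates = FALSE) {
  a <- as_alignments(alignments)
  q <- compute_jaf(a, junction, mutation, min_mapq, jaf_min,
                   include_duplicates)
  q$in_out <- classify_in_out(junction, mutation)
  if (q$in_out == "splice_in" && mutation_is_snv(mutation)) {
    s <- spliced_in_jaf(a, junction, mutation, min_mapq, include_duplicates)
  } else {
    s <- tibble::tibble(spliced_in_reads_with_mut = NA_integer_,
                        junction_reads_covering_mut = NA_integer_,
                        spliced_in_jaf = NA_real_)
  }
  dplyr::bind_cols(q, s)
}
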