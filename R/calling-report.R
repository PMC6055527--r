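# Per-mutation orchestration of the full pipeline: discovery -> canonical/
# HLA filter -> JAF filter -> control filter -> scoring -> review status,
# with an audit trail carrying the first failing filter for every mutation
# that produced no call.

#' Pipeline configuration
#'
#' @param window Discovery window around the mutation in bp.
#' @param min_reads Minimum unique supporting fragments per junction.
#' @param min_mapq Minimum mapping quality.
#' @param jaf_min Minimum junction allele fraction for reporting.
#' @param top_quantile Control-cohort quantile the case support must
#'   exceed.
#' @param batch_size Mutations per processing batch.
#' @param control_scope `"gene"`: controls must lack any mutation in the
#'   gene of interest; `"site"`: only the same mutation disqualifies.
#' @param include_duplicates Count duplicate-marked alignments?
#' @return An `scm_config` list.
#' @export
scm_config <- function(window = 20, min_reads = 5, min_mapq = 20,
                       jaf_min = 0.05, top_quantile = 0.95,
                       batch_size = 200,
                       control_scope = c("gene", "site"),
                       include_duplicates = FALSE) {
  structure(list(window = window, min_reads = min_reads,
                 min_mapq = min_mapq, jaf_min = jaf_min,
                 top_quantile = top_quantile, batch_size = batch_size,
                 control_scope = match.arg(control_scope),
                 include_duplicates = include_duplicates),
            class = "scm_config")
}

# samples disqualified as controls for a mutation
mutated_control_samples <- function(mutations, mutation, scope) {
  if (scope == "site") {
    unique(mutations$sample_id[
      mutations$gene == mutation$gene &
        mutations$chrom == mutation$chrom &
        mutations$pos == mutation$pos &
        mutations$alt_allele == mutation$alt_allele])
  } else {
    unique(mutations$sample_id[mutations$gene == mutation$gene])
  }
}

gene_strand <- function(index, gene) {
  g <- index$gene_intervals
  hit <- which(g$gene == gene)
  if (length(hit) == 0) return("+")
  as.character(g$strand[hit[1]])
}

# side of the alternative site: the intron boundary nearer the mutation,
# interpreted on the gene strand
alt_site_side <- function(junction, mutation, strand) {
  p <- mutation_pos0(mutation)
  at_start <- abs(p - junction$start) <= abs(p - junction$end)
  if (at_start == (strand == "+")) "donor" else "acceptor"
}

score_candidate <- function(genome, models, index, junction, mutation) {
  na_scores <- tibble::tibble(
    side = NA_character_,
    alt_ref_score = NA_real_, alt_mut_score = NA_real_,
    alt_delta = NA_real_,
    canonical_ref_score = NA_real_, canonical_mut_score = NA_real_,
    canonical_delta = NA_real_, preference_class = NA_character_,
    canonical_offset = NA_integer_,
    minus3_context = NA_character_, minus3_substitution = NA_character_)
  if (is.null(genome) || is.null(models)) return(na_scores)
  strand <- gene_strand(index, mutation$gene)
  p <- mutation_pos0(mutation)
  at_start <- abs(p - junction$start) <= abs(p - junction$end)
  side <- alt_site_side(junction, mutation, strand)
  alt_b <- if (at_start) junction$start else as.integer(junction$end)
  can_b <- if (at_start) junction$nearest_canonical_start
           else junction$nearest_canonical_end
  if (is.na(can_b)) return(na_scores)
  cmp <- compare_scores(genome, as.character(junction$chrom), side, alt_b,
                        can_b, strand, mutation, models[[side]])
  sc <- cmp$scores
  m3_context <- NA_character_
  m3_label <- NA_character_
  if (side == "acceptor") {
    km <- extract_site_kmers(genome, as.character(junction$chrom),
                             "acceptor", alt_b, strand, mutation)
    ra <- toupper(mutation$ref_allele)
    aa <- toupper(mutation$alt_allele)
    if (strand == "-" && ra %in% DNA_BASES && aa %in% DNA_BASES) {
      ra <- COMPLEMENT[[ra]]
      aa <- COMPLEMENT[[aa]]
    }
    m3 <- classify_minus3_context(km$ref_kmer, ra, aa)
    if (isTRUE(m3$applicable)) {
      m3_context <- m3$context
      m3_label <- m3$substitution_label
    }
  }
  tibble::tibble(
    side = side,
    alt_ref_score = sc$ref_score[1], alt_mut_score = sc$mut_score[1],
    alt_delta = sc$delta[1],
    canonical_ref_score = sc$ref_score[2],
    canonical_mut_score = sc$mut_score[2],
    canonical_delta = sc$delta[2],
    preference_class = cmp$preference_class,
    canonical_offset = as.integer(alt_b - can_b),
    minus3_context = m3_context, minus3_substitution = m3_label)
}

#' Call splice-site-creating mutations across a cohort
#'
#' Runs the full pipeline for every mutation: candidate junction discovery
#' in the mutated sample, canonical/HLA filtering, junction allele
#' fraction filtering, control-cohort filtering (controls are samples
#' without a mutation in the gene of interest), optional splice-site
#' scoring, and rule-based review: `Pass` when exactly one junction
#' survives all filters, `Complex` when more than one alternatively
#' spliced product survives, `NoSupport` otherwise (with the first failing
#' filter recorded in the audit trail). Per-mutation failures are isolated
#' and logged; global input errors abort.
#'
#' @param mutations Mutation tibble (see [read_mutations()]).
#' @param case_alignments Named list (by `sample_id`) of alignment sources
#'   for the mutated samples.
#' @param control_alignments Named list (by sample id) of alignment
#'   sources for the control cohort.
#' @param index A [build_junction_index()].
#' @param genome Optional genome for splice-site scoring.
#' @param models Optional list with `donor` and `acceptor`
#'   [splice_model()]s.
#' @param config An [scm_config()].
#' @return An `scm_calls` object: `calls` (one row per surviving
#'   mutation-junction pairing), `audit` (one row per mutation without a
#'   call), `config`.
#' @export
call_scms <- function(mutations, case_alignments, control_alignments,
                      index, genome = NULL, models = NULL,
                      config = scm_config()) {
  stopifnot(inherits(config, "scm_config"))
  if (length(control_alignments) == 0) {
    stop("control cohort is empty", call. = FALSE)
  }
  case_aln <- lapply(case_alignments, as_alignments)
  ctrl_tables <- lapply(control_alignments, function(x) {
    junction_support(as_alignments(x), config$min_mapq,
                     config$include_duplicates)
  })

  res <- lapply(seq_len(nrow(mutations)), function(i) {
    mut <- mutations[i, , drop = FALSE]
    tryCatch(
      call_one_mutation(mut, case_aln, ctrl_tables, mutations, index,
                        genome, models, config),
      error = function(e) {
        list(calls = NULL,
             audit = audit_row(mut, "NoSupport",
                               paste("error:", conditionMessage(e))))
      })
  })
  calls <- dplyr::bind_rows(purrr::map(res, "calls"))
  audit <- dplyr::bind_rows(purrr::map(res, "audit"))
  if (nrow(calls) > 0) {
    calls <- dplyr::arrange(calls, .data$sample_id, .data$chrom, .data$pos,
                            .data$junction_start, .data$junction_end)
  }
  structure(list(calls = calls, audit = audit, config = config,
                 n_mutations = nrow(mutations)),
            class = "scm_calls")
}

audit_row <- function(mut, status, reason) {
  tibble::tibble(sample_id = mut$sample_id, gene = mut$gene,
                 chrom = mut$chrom, pos = mut$pos,
                 variant_class = mut$variant_class,
                 status = status, reason = reason)
}

call_one_mutation <- function(mut, case_aln, ctrl_tables, mutations, index,
                              genome, models, config) {
  aln <- case_aln[[mut$sample_id]]
  if (is.null(aln)) {
    return(list(calls = NULL,
                audit = audit_row(mut, "NoSupport",
                                  "no alignments for sample")))
  }
  cands <- discover_candidate_junctions(
    aln, mut, window = config$window, min_reads = config$min_reads,
    min_mapq = config$min_mapq,
    include_duplicates = config$include_duplicates)
  if (nrow(cands) == 0) {
    return(list(calls = NULL,
                audit = audit_row(mut, "NoSupport", "no candidate junction")))
  }
  filt <- filter_canonical_and_hla(cands, index, mut)
  if (nrow(filt) == 0) {
    return(list(calls = NULL,
                audit = audit_row(mut, "NoSupport",
                                  "all candidate junctions canonical or in HLA loci")))
  }
  excluded <- mutated_control_samples(mutations, mut, config$control_scope)
  eligible <- ctrl_tables[setdiff(names(ctrl_tables), excluded)]

  evaluated <- lapply(seq_len(nrow(filt)), function(k) {
    junc <- filt[k, , drop = FALSE]
    quant <- quantify_junction(aln, junc, mut, config$min_mapq,
                               config$jaf_min, config$include_duplicates)
    stats <- control_support_counts(junc, eligible, config$min_mapq,
                                    config$include_duplicates)
    support <- junc$unique_read_support
    control_pass <- case_passes_top5(support, stats, config$min_reads,
                                     config$top_quantile)
    verdict <- expression_verdict(support, stats)
    fail_reason <- if (quant$jaf_filtered) {
      quant$jaf_filter_reason
    } else if (!control_pass) {
      "junction support not in top 5% of control cohort"
    } else {
      NA_character_
    }
    list(junc = junc, quant = quant, stats = stats,
         control_pass = control_pass, verdict = verdict,
         passed = !quant$jaf_filtered && control_pass,
         fail_reason = fail_reason)
  })
  passed <- purrr::keep(evaluated, "passed")
  if (length(passed) == 0) {
    # report the candidate that progressed furthest (control failures rank
    # past JAF failures)
    stage <- vapply(evaluated, function(x) {
      if (x$quant$jaf_filtered) 1L else 2L
    }, integer(1))
    best <- evaluated[[which.max(stage)]]
    return(list(calls = NULL,
                audit = audit_row(mut, "NoSupport", best$fail_reason)))
  }
  review <- if (length(passed) == 1) "Pass" else "Complex"
  rows <- lapply(passed, function(x) {
    junc <- x$junc
    sc <- score_candidate(genome, models, index, junc, mut)
    dplyr::bind_cols(
      tibble::tibble(
        sample_id = mut$sample_id, gene = mut$gene, chrom = mut$chrom,
        pos = mut$pos, pos0 = mut$pos0, ref_allele = mut$ref_allele,
        alt_allele = mut$alt_allele, variant_class = mut$variant_class,
        junction_start = junc$start, junction_end = junc$end,
        unique_read_support = junc$unique_read_support,
        distance_to_mutation = junc$distance_to_mutation,
        nearest_canonical_start = junc$nearest_canonical_start,
        nearest_canonical_end = junc$nearest_canonical_end,
        review = review),
      dplyr::select(x$quant, -"jaf_filtered", -"jaf_filter_reason"),
      tibble::tibble(
        n_controls = x$stats$n_controls, control_q05 = x$stats$q05,
        control_q95 = x$stats$q95,
        control_max = max(x$stats$counts),
        expression_verdict = x$verdict),
      sc)
  })
  list(calls = dplyr::bind_rows(rows), audit = NULL)
}

#' @export
print.scm_calls <- function(x, ...) {
  g <- glance(x)
  cat("<scm_calls>", g$n_mutations, "mutations:", g$n_pass, "Pass,",
      g$n_complex, "Complex,", g$n_nosupport, "NoSupport\n")
  invisible(x)
}

#' @describeIn call_scms One row per surviving mutation-junction pairing.
#' @param x An `scm_calls` object.
#' @param ... Unused.
#' @export
tidy.scm_calls <- function(x, ...) x$calls

#' @describeIn call_scms One-row summary of the calling run.
#' @export
glance.scm_calls <- function(x, ...) {
  calls <- x$calls
  pass_mut <- if (nrow(calls) > 0) {
    dplyr::distinct(calls[calls$review == "Pass", ],
                    .data$sample_id, .data$chrom, .data$pos)
  } else {
    calls
  }
  complex_mut <- if (nrow(calls) > 0) {
    dplyr::distinct(calls[calls$review == "Complex", ],
                    .data$sample_id, .data$chrom, .data$pos)
  } else {
    calls
  }
  tibble::tibble(
    n_mutations = x$n_mutations,
    n_pass = nrow(pass_mut),
    n_complex = nrow(complex_mut),
    n_nosupport = nrow(x$audit),
    median_jaf = if (nrow(calls) > 0) stats::median(calls$jaf) else NA_real_)
}

#' Audit trail of a calling run
#'
#' @param x An `scm_calls` object.
#' @return Tibble with one row per mutation that produced no call, with
#'   the first failing filter as `reason`.
#' @export
scm_audit <- function(x) x$audit

# ---- aggregation -------------------------------------------------------------

#' Aggregate calls into recurrence tables
#'
#' Summarises Pass calls per gene, breaks them down by conventional
#' annotation class, finds clusters of nearby mutations (within +/- 5 bp
#' of each other) creating the same alternative junction, and, when
#' sample metadata is given, tabulates genes by cancer type.
#'
#' @param x An `scm_calls` object or its `calls` tibble.
#' @param sample_metadata Optional tibble `sample_id, cancer_type`.
#' @return An `scm_recurrence` object.
#' @export
review_and_aggregate <- function(x, sample_metadata = NULL) {
  calls <- if (inherits(x, "scm_calls")) x$calls else tibble::as_tibble(x)
  pass <- calls[calls$review == "Pass", , drop = FALSE]
  gene_counts <- pass %>%
    dplyr::count(.data$gene, name = "n_calls") %>%
    dplyr::arrange(dplyr::desc(.data$n_calls), .data$gene)
  annotation_breakdown <- pass %>%
    dplyr::count(.data$variant_class, name = "n") %>%
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  clusters <- cluster_recurrent(pass)
  by_cancer_type <- NULL
  if (!is.null(sample_metadata)) {
    by_cancer_type <- pass %>%
      dplyr::left_join(tibble::as_tibble(sample_metadata),
                       by = "sample_id") %>%
      dplyr::count(.data$gene, .data$cancer_type, name = "n_calls")
  }
  structure(list(gene_counts = gene_counts,
                 annotation_breakdown = annotation_breakdown,
                 clusters = clusters, by_cancer_type = by_cancer_type,
                 n_pass = nrow(pass)),
            class = "scm_recurrence")
}

# clusters of mutations within +/-5 bp creating the identical intron
cluster_recurrent <- function(pass, max_gap = 5) {
  empty <- tibble::tibble(chrom = character(), junction_start = integer(),
                          junction_end = integer(), gene = character(),
                          n_mutations = integer(), positions = list())
  if (nrow(pass) == 0) return(empty)
  grp <- pass %>%
    dplyr::distinct(.data$chrom, .data$junction_start, .data$junction_end,
                    .data$gene, .data$pos) %>%
    dplyr::group_by(.data$chrom, .data$junction_start, .data$junction_end,
                    .data$gene)
  out <- grp %>%
    dplyr::group_map(function(d, key) {
      p <- sort(d$pos)
      runs <- split(p, cumsum(c(0, diff(p) > max_gap)))
      purrr::map_dfr(runs, function(r) {
        if (length(r) < 2) return(NULL)
        dplyr::bind_cols(key, tibble::tibble(n_mutations = length(r),
                                             positions = list(r)))
      })
    }) %>%
    dplyr::bind_rows()
  if (nrow(out) == 0) empty else out
}

#' @export
print.scm_recurrence <- function(x, ...) {
  cat("<scm_recurrence>", x$n_pass, "Pass calls over",
      nrow(x$gene_counts), "genes;", nrow(x$clusters),
      "recurrent junction cluster(s)\n")
  invisible(x)
}

#' @describeIn review_and_aggregate Per-gene call counts.
#' @param ... Unused.
#' @export
tidy.scm_recurrence <- function(x, ...) x$gene_counts

#' @describeIn review_and_aggregate One-row summary.
#' @export
glance.scm_recurrence <- function(x, ...) {
  multi <- sum(x$gene_counts$n_calls >= 2)
  tibble::tibble(
    n_pass = x$n_pass,
    n_genes = nrow(x$gene_counts),
    n_genes_multiple = multi,
    n_clusters = nrow(x$clusters))
}

#' Write calling outputs to a directory
#'
#' Emits `calls.tsv`, `audit.tsv`, `junctions.bed` (alternative junctions
#' of Pass calls, score = supporting reads) and `recurrence.tsv`.
#'
#' @param x An `scm_calls` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scm_calls <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(x$calls, file.path(dir, "calls.tsv"), progress = FALSE)
  readr::write_tsv(x$audit, file.path(dir, "audit.tsv"), progress = FALSE)
  pass <- x$calls[x$calls$review == "Pass", , drop = FALSE]
  if (nrow(pass) > 0) {
    j <- pass %>%
      dplyr::transmute(chrom = .data$chrom, start = .data$junction_start,
                       end = .data$junction_end,
                       unique_read_support = .data$unique_read_support) %>%
      dplyr::distinct()
    write_junctions_bed(j, file.path(dir, "junctions.bed"))
  }
  rec <- review_and_aggregate(x)
  readr::write_tsv(rec$gene_counts, file.path(dir, "recurrence.tsv"),
                   progress = FALSE)
  invisible(dir)
}
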