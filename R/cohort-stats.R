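# Control-cohort read-count statistics: empirical 5%/95% thresholds for a
# junction's support across mutation-free control samples, the top-5% case
# filter, and per-sample expression verdicts.

#' Nearest-rank empirical quantile
#'
#' Quantiles of small integer count distributions are taken without
#' interpolation: the value returned is the smallest element `v` of the
#' multiset with strictly more than `p * n` elements `<= v` (the
#' left-continuous inverse of the empirical CDF), i.e.
#' `sort(x)[floor(p * n) + 1]`. The result is always a member of the
#' multiset, so thresholds stay integral.
#'
#' @param x Numeric vector (counts).
#' @param p Probability in `[0, 1)`.
#' @return One element of `x`.
#' @export
nearest_rank_quantile <- function(x, p) {
  stopifnot(length(x) >= 1, p >= 0, p < 1)
  s <- sort(x)
  s[min(floor(p * length(x)) + 1L, length(x))]
}

new_control_stats <- function(counts) {
  counts <- as.integer(counts)
  structure(
    list(counts = counts,
         n_controls = length(counts),
         q05 = nearest_rank_quantile(counts, 0.05),
         q95 = nearest_rank_quantile(counts, 0.95)),
    class = "control_stats")
}

#' @export
print.control_stats <- function(x, ...) {
  cat("<control_stats> n =", x$n_controls, " q05 =", x$q05,
      " q95 =", x$q95, "\n")
  invisible(x)
}

#' @describeIn control_support_counts One-row tibble of the control summary.
#' @param x A `control_stats` object.
#' @param ... Unused.
#' @export
tidy.control_stats <- function(x, ...) {
  tibble::tibble(n_controls = x$n_controls, q05 = x$q05, q95 = x$q95,
                 max_count = max(x$counts), mean_count = mean(x$counts))
}

#' Count a junction's support across control samples
#'
#' Counts unique supporting fragments for one junction in every control
#' sample, using the same counting rules as case discovery (fragment-level
#' deduplication, mapping-quality floor, no secondary/supplementary/
#' duplicate records), and summarises the distribution with nearest-rank
#' 5%/95% thresholds.
#'
#' Control samples must already be restricted to samples lacking a
#' mutation in the junction's gene; [call_scms()] performs that exclusion.
#'
#' @param junction A one-row tibble (or list) with `chrom`, `start`, `end`
#'   (0-based half-open intron).
#' @param controls Named list of control alignment sources (tibbles or
#'   SAM/BAM paths), one per control sample.
#' @param min_mapq Minimum mapping quality.
#' @param include_duplicates Count duplicate-marked records?
#' @return A `control_stats` object: per-sample `counts`, `n_controls`,
#'   `q05`, `q95`.
#' @export
control_support_counts <- function(junction, controls, min_mapq = 20,
                                   include_duplicates = FALSE) {
  if (length(controls) == 0) {
    stop("empty control set: the control filter cannot be evaluated",
         call. = FALSE)
  }
  counts <- vapply(controls, function(ctrl) {
    tab <- if (is.data.frame(ctrl) &&
               all(c("unique_read_support", "start") %in% names(ctrl)) &&
               !"cigar" %in% names(ctrl)) {
      ctrl  # precomputed junction_support() table
    } else {
      junction_support(as_alignments(ctrl), min_mapq, include_duplicates)
    }
    hit <- tab$chrom == junction$chrom & tab$start == junction$start &
      tab$end == junction$end
    if (any(hit)) as.integer(tab$unique_read_support[hit][1]) else 0L
  }, integer(1))
  stats <- new_control_stats(counts)
  stats$counts <- stats::setNames(stats$counts, names(controls))
  stats
}

#' Does the case sample sit in the top 5% of the control distribution?
#'
#' The case's junction support must strictly exceed the control 95%
#' threshold. When the junction is unseen in every control (all counts
#' zero) the threshold is degenerate; the case then passes iff its support
#' meets the discovery floor `min_reads` — the pattern of a cryptic
#' junction expressed only in the mutated sample.
#'
#' @param case_count Unique supporting fragments in the case sample.
#' @param stats A `control_stats` object.
#' @param min_reads Discovery support floor (default 5).
#' @param top_quantile Control quantile the case must exceed (default 0.95).
#' @return `TRUE`/`FALSE`.
#' @export
case_passes_top5 <- function(case_count, stats, min_reads = 5,
                             top_quantile = 0.95) {
  stopifnot(case_count >= 0)
  if (all(stats$counts == 0)) {
    return(case_count >= min_reads)
  }
  case_count > nearest_rank_quantile(stats$counts, top_quantile)
}

#' Expression verdict for a junction in one sample
#'
#' Verdicts partition the outcome space: `no_expression` when both control
#' thresholds are zero and the sample shows no reads; `high`/`low` when
#' the count lies outside the 95%/5% thresholds; `average` otherwise.
#'
#' @param count Unique supporting fragments in the sample.
#' @param stats A `control_stats` object.
#' @return One of `"no_expression"`, `"low"`, `"average"`, `"high"`.
#' @export
expression_verdict <- function(count, stats) {
  if (stats$q05 == 0 && stats$q95 == 0 && count == 0) return("no_expression")
  if (count > stats$q95) return("high")
  if (count < stats$q05) return("low")
  "average"
}
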