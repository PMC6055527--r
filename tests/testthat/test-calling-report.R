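# a minimal hand-built cohort: one gene with canonical intron (500,600),
# the case sample expressing one or two novel junctions near a mutation,
# controls expressing nothing
toy_index <- function() {
  build_junction_index(tibble::tibble(
    chrom = "ctg", start = c(400L, 600L), end = c(500L, 700L),
    strand = "+", gene = "GENE01", transcript_id = "t1"))
}

toy_controls <- function(n = 6) {
  ctl <- lapply(seq_len(n), function(i) {
    aln_tbl(paste0("c", 1:10), 430, "70M100N5M")  # canonical splicing only
  })
  names(ctl) <- paste0("ctrl_", seq_len(n))
  ctl
}

# `n_junc` novel junctions supported near the mutation at 519
toy_case <- function(n_junc) {
  rows <- list(aln_tbl(paste0("bg", 1:10), 470, "75M"))
  if (n_junc >= 1) {
    rows <- c(rows, list(aln_tbl(paste0("j1_", 1:8), 480, "40M80N35M")))
  }
  if (n_junc >= 2) {
    rows <- c(rows, list(aln_tbl(paste0("j2_", 1:8), 485, "40M90N35M")))
  }
  dplyr::bind_rows(rows)
}

test_that("review assigns Pass, Complex and NoSupport by surviving junctions", {
  idx <- toy_index()
  mut <- mut_rec(pos0 = 519)
  cfg <- scm_config()

  one <- call_scms(mut, list(case_01 = toy_case(1)), toy_controls(), idx,
                   config = cfg)
  expect_equal(one$calls$review, "Pass")
  expect_equal(nrow(scm_audit(one)), 0)

  two <- call_scms(mut, list(case_01 = toy_case(2)), toy_controls(), idx,
                   config = cfg)
  expect_equal(unique(two$calls$review), "Complex")
  expect_equal(nrow(two$calls), 2)

  none <- call_scms(mut, list(case_01 = toy_case(0)), toy_controls(), idx,
                    config = cfg)
  expect_equal(nrow(none$calls), 0)
  expect_equal(scm_audit(none)$status, "NoSupport")
  expect_equal(scm_audit(none)$reason, "no candidate junction")
})

test_that("the synthetic cohort reproduces the zero-control case pattern", {
  # a silent mutation creating a donor: high case support, junction absent
  # from every control, JAF near 0.5
  w <- generate_truth_set(n_events = 1, event_types = "donor_del30",
                          true_jaf = 0.5, depth = 164, n_cases = 1,
                          n_controls = 20, seed = 42)
  aln <- simulate_alignments(w, seed = 42)
  idx <- build_junction_index(w$annotation)
  models <- splice_models_from_annotation(w$genome, idx)
  res <- call_scms(w$mutations, aln[w$samples$cases], aln[w$samples$controls],
                   idx, genome = w$genome, models = models)
  call <- res$calls
  expect_equal(nrow(call), 1)
  expect_equal(call$review, "Pass")
  expect_equal(call$variant_class, "silent")
  expect_gt(call$unique_read_support, 50)
  expect_equal(call$control_max, 0L)
  expect_equal(call$expression_verdict, "high")
  ci <- stats::qbinom(c(0.005, 0.995), call$locus_depth, 0.5) /
    call$locus_depth
  expect_gte(call$jaf, ci[1])
  expect_lte(call$jaf, ci[2])
  expect_equal(call$junction_start, w$truth$alt_start)
  expect_equal(call$junction_end, w$truth$alt_end)
  # scoring annotations are attached
  expect_gt(call$alt_delta, 0)
  expect_equal(call$side, "donor")
})

test_that("every mutation lands exactly once in calls or the audit trail", {
  sw <- small_world()
  w <- sw$world
  models <- splice_models_from_annotation(w$genome, sw$index)
  res <- call_scms(w$mutations, sw$aln[w$samples$cases],
                   sw$aln[w$samples$controls], sw$index,
                   genome = w$genome, models = models)
  called <- dplyr::distinct(res$calls, sample_id, chrom, pos)
  audited <- dplyr::distinct(scm_audit(res), sample_id, chrom, pos)
  expect_equal(nrow(called) + nrow(audited), nrow(w$mutations))
  expect_equal(nrow(dplyr::inner_join(called, audited,
                                      by = c("sample_id", "chrom", "pos"))),
               0)
  # the JAF and control predicates hold for every Pass call
  pass <- res$calls[res$calls$review == "Pass", ]
  expect_true(all(pass$jaf >= res$config$jaf_min))
  expect_true(all(pass$unique_read_support > pass$control_q95 |
                    pass$control_max == 0))
})

test_that("recurrence aggregation clusters nearby same-junction mutations", {
  mk_call <- function(gene, pos, js, je, sample = "s1",
                      variant_class = "missense") {
    tibble::tibble(sample_id = sample, gene = gene, chrom = "ctg",
                   pos = pos, variant_class = variant_class,
                   junction_start = js, junction_end = je, jaf = 0.3,
                   review = "Pass")
  }
  # 3 calls in one gene, 2 within 4 bp creating the identical intron
  calls <- dplyr::bind_rows(
    mk_call("G1", 100L, 200L, 300L, "s1"),
    mk_call("G1", 104L, 200L, 300L, "s2"),
    mk_call("G1", 150L, 200L, 300L, "s3"))
  rec <- review_and_aggregate(calls)
  expect_equal(rec$gene_counts$n_calls, 3L)
  expect_equal(nrow(rec$clusters), 1)
  expect_equal(rec$clusters$n_mutations, 2L)
  expect_equal(rec$clusters$positions[[1]], c(100L, 104L))

  # one call in each of two genes: rows sum to 2, no clusters
  calls2 <- dplyr::bind_rows(mk_call("G1", 100L, 200L, 300L),
                             mk_call("G2", 900L, 950L, 990L))
  rec2 <- review_and_aggregate(calls2)
  expect_equal(sum(rec2$gene_counts$n_calls), 2L)
  expect_equal(nrow(rec2$clusters), 0)

  # adjacent mutations creating different junctions never cluster
  calls3 <- dplyr::bind_rows(mk_call("G1", 100L, 200L, 300L),
                             mk_call("G1", 102L, 205L, 300L))
  expect_equal(nrow(review_and_aggregate(calls3)$clusters), 0)

  # annotation breakdown fractions sum to one
  expect_equal(sum(review_and_aggregate(calls)$annotation_breakdown$fraction),
               1)
})

test_that("calling outputs are written as tabular files", {
  sw <- small_world()
  w <- sw$world
  res <- call_scms(w$mutations, sw$aln[w$samples$cases],
                   sw$aln[w$samples$controls], sw$index)
  dir <- withr::local_tempdir()
  write_scm_calls(res, dir)
  expect_true(file.exists(file.path(dir, "calls.tsv")))
  expect_true(file.exists(file.path(dir, "audit.tsv")))
  expect_true(file.exists(file.path(dir, "junctions.bed")))
  bed <- readr::read_tsv(file.path(dir, "junctions.bed"),
                         col_names = FALSE, show_col_types = FALSE)
  expect_equal(ncol(bed), 12)
  g <- glance(res)
  expect_equal(g$n_pass, 4)
  expect_equal(g$n_nosupport, 10)
})
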