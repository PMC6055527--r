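write_maf <- function(df, path) {
  names(df) <- unname(maf_columns()[names(df)])
  readr::write_tsv(df, path, progress = FALSE)
  path
}

test_that("mutation tables are read, validated and batched", {
  f <- withr::local_tempfile(fileext = ".maf")
  write_maf(tibble::tibble(
    sample_id = c("sampleA", "sampleB", "sampleC"),
    gene = c("GATA3", "TP53", "PTEN"),
    chrom = c("chr10", "chr17", "chr10"),
    pos = c("8111433", "NA", "89624230"),
    ref_allele = c("CA", "G", "C"),
    alt_allele = c("-", "T", "T"),
    variant_class = c("indel", "missense", "Silent"),
    t_ref_count = c("10", "5", "7"),
    t_alt_count = c("12", "4", "3")), f)
  m <- read_mutations(f)
  expect_equal(nrow(m), 2)  # the NA-position row is rejected, others kept
  expect_equal(m$variant_class, c("indel", "silent"))
  expect_equal(m$pos0, m$pos - 1L)
  expect_equal(m$sample_id[1], "sampleA")
  expect_equal(m$ref_allele[1], "CA")
  expect_equal(m$alt_allele[1], "-")
  rej <- attr(m, "rejected")
  expect_equal(nrow(rej), 1)
  expect_match(rej$reason, "position")

  # one-row file maps fields directly
  f1 <- withr::local_tempfile(fileext = ".maf")
  write_maf(tibble::tibble(sample_id = "sampleA", gene = "GATA3",
                           chrom = "chr10", pos = "8111433",
                           ref_allele = "CA", alt_allele = "-",
                           variant_class = "indel",
                           t_ref_count = "1", t_alt_count = "1"), f1)
  m1 <- read_mutations(f1)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$variant_class, "indel")

  # missing required column is a format error
  f2 <- withr::local_tempfile(fileext = ".maf")
  readr::write_tsv(tibble::tibble(Hugo_Symbol = "X"), f2, progress = FALSE)
  expect_error(read_mutations(f2), "missing required column")

  # 450 rows with batch_size 200 -> batches of 200, 200, 50
  f3 <- withr::local_tempfile(fileext = ".maf")
  write_maf(tibble::tibble(
    sample_id = paste0("s", 1:450), gene = "G", chrom = "1",
    pos = as.character(1:450), ref_allele = "A", alt_allele = "G",
    variant_class = "missense", t_ref_count = "1", t_alt_count = "1"), f3)
  b <- read_mutations(f3, batch_size = 200)
  expect_equal(vapply(b, nrow, 0L), c(`1` = 200L, `2` = 200L, `3` = 50L))
})

test_that("mutation tables round-trip through write and read", {
  sw <- small_world()
  f <- withr::local_tempfile(fileext = ".maf")
  write_mutations(sw$world$mutations, f)
  back <- read_mutations(f)
  cols <- c("sample_id", "gene", "chrom", "pos", "pos0", "ref_allele",
            "alt_allele", "variant_class", "t_ref_count", "t_alt_count")
  attr(back, "rejected") <- NULL
  expect_equal(as.data.frame(back[cols]),
               as.data.frame(sw$world$mutations[cols]))
})

test_that("junction index derives canonical introns from exon gaps", {
  ann <- tibble::tibble(
    chrom = "chr1", start = c(100L, 300L), end = c(200L, 400L),
    strand = "+", gene = "G1", transcript_id = "tx1")
  idx <- build_junction_index(ann)
  expect_equal(nrow(idx$canonical_introns), 1)
  expect_equal(idx$canonical_introns$start, 200L)
  expect_equal(idx$canonical_introns$end, 300L)
  expect_equal(idx$canonical_introns$strand, "+")

  # a second transcript sharing the intron adds no entry
  ann2 <- dplyr::bind_rows(ann, dplyr::mutate(ann, transcript_id = "tx2"))
  expect_equal(nrow(build_junction_index(ann2)$canonical_introns), 1)

  # HLA gene-name pattern: HLA-A is an HLA locus, HLAX is not
  ann3 <- dplyr::bind_rows(
    ann,
    tibble::tibble(chrom = "chr6", start = c(10L, 120L), end = c(100L, 200L),
                   strand = "+", gene = "HLA-A", transcript_id = "hla1"),
    tibble::tibble(chrom = "chr6", start = c(300L, 420L), end = c(400L, 500L),
                   strand = "+", gene = "HLAX", transcript_id = "hlax1"))
  idx3 <- build_junction_index(ann3)
  expect_equal(idx3$hla_intervals$gene, "HLA-A")

  # overlapping exons: transcript skipped with a warning
  bad <- tibble::tibble(chrom = "chr1", start = c(100L, 150L),
                        end = c(200L, 400L), strand = "+", gene = "G1",
                        transcript_id = "bad")
  expect_warning(idx4 <- build_junction_index(dplyr::bind_rows(ann, bad)),
                 "overlapping exons")
  expect_equal(nrow(idx4$canonical_introns), 1)
  expect_error(build_junction_index(ann[0, ]), "empty annotation")
})

test_that("index built from the synthetic GTF equals the simulator truth", {
  sw <- small_world()
  dir <- withr::local_tempdir()
  write_world(sw$world, dir)
  idx <- build_junction_index(file.path(dir, "annotation.gtf"))
  expect_equal(
    as.data.frame(idx$canonical_introns[c("chrom", "start", "end", "strand")]),
    as.data.frame(sw$index$canonical_introns[c("chrom", "start", "end",
                                               "strand")]))
  # every declared canonical intron of the truth set is in the index
  tr <- sw$world$truth
  for (i in seq_len(nrow(tr))) {
    expect_true(any(idx$canonical_introns$chrom == tr$chrom[i] &
                      idx$canonical_introns$start == tr$canonical_start[i] &
                      idx$canonical_introns$end == tr$canonical_end[i]))
  }
})

test_that("fetch_sequence honours bounds, strand, and revcomp symmetry", {
  g <- Biostrings::DNAStringSet(c(ctg = "ACGTACGT"))
  expect_equal(fetch_sequence(g, "ctg", 2, 5, "+"), "GTA")
  expect_equal(fetch_sequence(g, "ctg", 2, 5, "-"), "TAC")
  expect_error(fetch_sequence(g, "ctg", 6, 10), "out of bounds")
  expect_error(fetch_sequence(g, "nope", 0, 2), "unknown contig")
  expect_error(fetch_sequence(g, "ctg", 5, 5), "invalid interval")

  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  set.seed(42)
  big <- Biostrings::DNAStringSet(c(c1 = paste(
    sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")))
  for (k in 1:25) {
    st <- sample(0:480, 1); en <- st + sample(1:20, 1)
    expect_equal(fetch_sequence(big, "c1", st, en, "+"),
                 revcomp(fetch_sequence(big, "c1", st, en, "-")))
  }
})

test_that("SAM text round-trips through write_sam and read_alignments", {
  sw <- small_world()
  a <- sw$aln$case_01
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(a, f, genome = sw$world$genome)
  back <- read_alignments(f)
  sorted <- dplyr::arrange(tibble::as_tibble(a), chrom, pos, qname)
  expect_equal(as.data.frame(tibble::as_tibble(back)), as.data.frame(sorted))
  si <- attr(back, "seqinfo")
  expect_equal(si$chrom, names(sw$world$genome))
})
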