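# intron (1000,1100) spanned by 40M100N35M reads starting at 960
spanning_reads <- function(n, qprefix = "frag", pos = 960, mapq = 60,
                           flag = 99L) {
  aln_tbl(qname = paste0(qprefix, seq_len(n)), pos = pos,
          cigar = "40M100N35M", mapq = mapq, flag = flag)
}

test_that("junctions near the mutation are discovered with fragment support", {
  a <- spanning_reads(7)
  mut <- mut_rec(pos0 = 995)  # distance 5 to the intron start
  cand <- discover_candidate_junctions(a, mut)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 1000L)
  expect_equal(cand$end, 1100L)
  expect_equal(cand$unique_read_support, 7L)
  expect_equal(cand$distance_to_mutation, 5L)
  expect_equal(sort(cand$supporting_fragments[[1]]), sort(a$qname))

  # support boundary: 4 fragments is below the 5-read floor
  expect_equal(nrow(discover_candidate_junctions(spanning_reads(4), mut)), 0)
  expect_equal(nrow(discover_candidate_junctions(spanning_reads(5), mut)), 1)

  # window boundary: distance 50 is outside +/-20 bp
  far <- mut_rec(pos0 = 950)
  expect_equal(nrow(discover_candidate_junctions(spanning_reads(7), far)), 0)

  # contig mismatch errors
  expect_error(discover_candidate_junctions(a, mut_rec(chrom = "chrX",
                                                       pos0 = 995)),
               "absent from alignments")
})

test_that("mapping quality, duplicates, and mates are handled per fragment", {
  mut <- mut_rec(pos0 = 995)
  # reads below Q20 are ignored
  low <- spanning_reads(7, mapq = 19)
  expect_equal(nrow(discover_candidate_junctions(low, mut)), 0)
  expect_equal(nrow(discover_candidate_junctions(
    spanning_reads(7, mapq = 20), mut)), 1)

  # both mates spanning the junction count once
  mates <- dplyr::bind_rows(spanning_reads(5, flag = 99L),
                            spanning_reads(5, flag = 147L))
  cand <- discover_candidate_junctions(mates, mut)
  expect_equal(cand$unique_read_support, 5L)

  # duplicate-marked fragments are excluded by default, kept on request
  dup <- spanning_reads(8)
  dup$flag[1:3] <- bitwOr(dup$flag[1:3], 1024L)
  expect_equal(discover_candidate_junctions(dup, mut)$unique_read_support,
               5L)
  expect_equal(discover_candidate_junctions(
    dup, mut, include_duplicates = TRUE)$unique_read_support, 8L)

  # secondary/supplementary records never count
  sec <- spanning_reads(8)
  sec$flag[1:3] <- bitwOr(sec$flag[1:3], 256L)
  expect_equal(discover_candidate_junctions(sec, mut)$unique_read_support,
               5L)
})

test_that("discovery equals the brute-force CIGAR reparse on simulated data", {
  sw <- small_world()
  for (smp in sw$world$samples$cases) {
    a <- sw$aln[[smp]]
    muts <- sw$world$mutations[sw$world$mutations$sample_id == smp, ]
    for (i in seq_len(nrow(muts))) {
      mine <- discover_candidate_junctions(a, muts[i, ])
      ora <- oracle_discover(a, muts$chrom[i], muts$pos0[i])
      expect_equal(mine$start, ora$start)
      expect_equal(mine$end, ora$end)
      expect_equal(mine$unique_read_support, ora$support)
    }
  }
})

test_that("discovery is monotone in its thresholds and deterministic", {
  sw <- small_world()
  a <- sw$aln$case_01
  muts <- sw$world$mutations[sw$world$mutations$sample_id == "case_01", ]
  key <- function(x) paste(x$chrom, x$start, x$end)
  for (i in seq_len(nrow(muts))) {
    base <- discover_candidate_junctions(a, muts[i, ], window = 20,
                                         min_reads = 5, min_mapq = 20)
    looser <- discover_candidate_junctions(a, muts[i, ], window = 30,
                                           min_reads = 2, min_mapq = 0)
    expect_true(all(key(base) %in% key(looser)))
    # identical inputs give identical, coordinate-sorted output
    again <- discover_candidate_junctions(a, muts[i, ])
    expect_identical(base, again)
    expect_false(is.unsorted(base$start))
  }
})

test_that("canonical and HLA junctions are filtered, survivors annotated", {
  # exons [400,500), [600,1200), [1300,1400): introns (500,600), (1200,1300)
  idx <- build_junction_index(tibble::tibble(
    chrom = "ctg",
    start = c(400L, 600L, 1300L),
    end = c(500L, 1200L, 1400L),
    strand = "+",
    gene = "GENE01",
    transcript_id = "t1"))
  # exact canonical match is removed
  cand <- tibble::tibble(chrom = "ctg", start = 500L, end = 600L,
                         unique_read_support = 9L,
                         distance_to_mutation = 3L,
                         supporting_fragments = list("f"))
  expect_equal(nrow(filter_canonical_and_hla(cand, idx)), 0)

  # cryptic acceptor: shares the donor boundary only -> retained and
  # annotated with the canonical intron it shares the boundary with
  cryptic <- dplyr::mutate(cand, end = 590L)
  kept <- filter_canonical_and_hla(cryptic, idx,
                                   mutation = mut_rec(pos0 = 588))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$nearest_canonical_start, 500L)
  expect_equal(kept$nearest_canonical_end, 600L)

  # candidate inside an HLA interval is removed
  idx_hla <- build_junction_index(tibble::tibble(
    chrom = "ctg", start = c(100L, 350L), end = c(250L, 500L),
    strand = "+", gene = "HLA-A", transcript_id = "h1"))
  inside <- tibble::tibble(chrom = "ctg", start = 260L, end = 340L,
                           unique_read_support = 8L,
                           distance_to_mutation = 1L,
                           supporting_fragments = list("f"))
  expect_equal(nrow(filter_canonical_and_hla(inside, idx_hla)), 0)
  # empty in, empty out
  expect_equal(nrow(filter_canonical_and_hla(cand[0, ], idx)), 0)
})
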