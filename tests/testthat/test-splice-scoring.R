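# a deterministic random per-position model plus one joint block, used to
# exercise both factorization shapes
toy_donor_model <- function(seed = 5, joint = FALSE) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0, 4, 9, dimnames = list(bases, NULL))
  for (p in 1:9) {
    w <- stats::runif(4)
    mat[, p] <- w / sum(w)
  }
  if (!joint) return(splice_model_independent("donor", mat))
  # joint table over exonic positions 1:3, independent elsewhere
  trip <- crypticsplice:::all_kmers(3)
  w <- stats::runif(length(trip))
  joint_block <- list(positions = 1:3, exponent = 1,
                      probs = stats::setNames(w / sum(w), trip))
  ind <- splice_model_independent("donor", mat)
  blocks <- c(list(joint_block),
              purrr::keep(ind$blocks, ~ .x$positions > 3))
  splice_model("donor", blocks, ind$background, ind$consensus)
}

test_that("donor and acceptor k-mers are cut at the documented coordinates", {
  set.seed(31)
  contig <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
  g <- Biostrings::DNAStringSet(c(ctg = contig))

  # plus-strand donor at exon end E: k-mer = ref[E-3, E+6)
  E <- 100L
  km <- extract_site_kmers(g, "ctg", "donor", E, "+")
  expect_equal(km$ref_kmer, substr(contig, E - 2, E + 6))
  expect_equal(nchar(km$ref_kmer), 9)

  # plus-strand acceptor at intron end: 20 intronic + 3 exonic
  km2 <- extract_site_kmers(g, "ctg", "acceptor", E, "+")
  expect_equal(km2$ref_kmer, substr(contig, E - 19, E + 3))
  expect_equal(nchar(km2$ref_kmer), 23)

  # minus strand is the reverse complement reading exon -> intron
  km3 <- extract_site_kmers(g, "ctg", "donor", E, "-")
  expect_equal(km3$ref_kmer, fetch_sequence(g, "ctg", E - 6L, E + 3L, "-"))

  # acceptor -3 mutation changes exactly k-mer index 18
  m3pos <- E - 3L  # intronic -3 relative to the boundary at E
  ref_base <- substr(contig, m3pos + 1, m3pos + 1)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  mk <- extract_site_kmers(g, "ctg", "acceptor", E, "+",
                           mutation = mut_rec(chrom = "ctg", pos0 = m3pos,
                                              ref = ref_base, alt = alt_base))
  diff_at <- which(strsplit(mk$ref_kmer, "")[[1]] !=
                     strsplit(mk$mut_kmer, "")[[1]])
  expect_equal(diff_at, 18L)
  expect_equal(mk$mut_index, 18L)

  # a deletion inside the footprint is unscoreable
  del <- extract_site_kmers(g, "ctg", "donor", E, "+",
                            mutation = mut_rec(chrom = "ctg", pos0 = E + 1L,
                                               ref = "GT", alt = "-"))
  expect_false(del$scoreable)

  # a mutation outside the footprint leaves only the reference k-mer
  outside <- extract_site_kmers(g, "ctg", "donor", E, "+",
                                mutation = mut_rec(chrom = "ctg",
                                                   pos0 = E + 50L))
  expect_true(is.na(outside$mut_kmer))
  expect_true(outside$scoreable)
})

test_that("scores equal brute-force table arithmetic and handle edge cases", {
  model <- toy_donor_model(joint = TRUE)
  set.seed(17)
  kmers <- crypticsplice:::all_kmers(9)[sample(4^9, 500)]
  expect_equal(score_site(kmers, model), oracle_score(kmers, model),
               tolerance = 1e-12)

  # model identical to background scores 0 everywhere
  flat <- splice_model_independent(
    "donor", matrix(0.25, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_equal(score_site(kmers[1:50], flat), rep(0, 50))

  # N-containing k-mers are unscoreable; wrong length errors
  expect_true(is.na(score_site("CAGGTANGT", model)))
  expect_error(score_site("CAGGT", model), "length")

  # positional neutrality: a position whose model and background columns
  # agree cannot change the score
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0.25, 4, 9, dimnames = list(bases, NULL))
  mat[, 6] <- c(0.7, 0.1, 0.1, 0.1)
  m <- splice_model_independent("donor", mat)
  # differs only at position 1, where model equals background
  expect_equal(score_site("AAAAAAAAA", m), score_site("CAAAAAAAA", m))
  # differing at the informative position 6 changes the score
  expect_false(isTRUE(all.equal(score_site("AAAAAAAAA", m),
                                score_site("AAAAACAAA", m))))

  # scoring depends only on the k-mer string, never on genomic position
  sw <- small_world()
  g <- sw$world$genome
  k1 <- extract_site_kmers(g, "ctg01", "donor", 350L, "+")$ref_kmer
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">copy", paste0(strrep("T", 40), k1, strrep("T", 40))), f)
  k2 <- extract_site_kmers(read_genome(f), "copy", "donor", 43L, "+")$ref_kmer
  expect_equal(k1, k2)
  expect_equal(score_site(k1, model), score_site(k2, model))
})

test_that("the model text format round-trips", {
  model <- toy_donor_model(joint = TRUE)
  f <- withr::local_tempfile(fileext = ".txt")
  write_splice_model(model, f)
  back <- read_splice_model(f)
  expect_equal(back$site_kind, "donor")
  expect_equal(back$kmer_length, 9L)
  set.seed(23)
  kmers <- crypticsplice:::all_kmers(9)[sample(4^9, 200)]
  expect_equal(score_site(kmers, back), score_site(kmers, model),
               tolerance = 1e-9)
})

test_that("alternative-vs-canonical preference follows the trichotomy", {
  expect_equal(score_preference_class(1, 8.1, 3.0, 3.0), "alt_stronger")
  expect_equal(score_preference_class(2, 4, 9, 9), "gap_narrowed")
  expect_equal(score_preference_class(5, 5, 5, 5), "no_evidence")
  expect_equal(score_preference_class(NA, 1, 2, 3), "unscoreable")

  # full path through compare_scores on a synthetic donor event
  sw <- small_world()
  tr <- sw$world$truth[sw$world$truth$event_type == "donor_out", ][1, ]
  models <- splice_models_from_annotation(sw$world$genome, sw$index)
  mut <- sw$world$mutations[!is.na(sw$world$mutations$event_id) &
                             sw$world$mutations$event_id == tr$event_id, ]
  cmp <- compare_scores(sw$world$genome, tr$chrom, "donor", tr$alt_start,
                        tr$canonical_start, "+", mut, models$donor)
  expect_equal(cmp$scores$site_role, c("alternative", "canonical"))
  # the A>G donor creation strengthens the alternative site
  expect_gt(cmp$scores$delta[1], 0)
  # the canonical 9-mer is untouched by the mutation
  expect_equal(cmp$scores$delta[2], 0)
  expect_true(cmp$preference_class %in% c("alt_stronger", "gap_narrowed"))
})

test_that("a model trained on canonical acceptors rewards the -3 G context", {
  sw <- small_world()
  models <- splice_models_from_annotation(sw$world$genome, sw$index)
  # canonical acceptor tails in the synthetic world end AGAGAG, so G is
  # the consensus at -3 (k-mer index 18): an a->G there must gain score
  km_a <- "TTTTTTTTTTTTTTTTTAAGTTT"
  km_g <- km_a
  substr(km_g, 18, 18) <- "G"
  expect_gt(score_site(km_g, models$acceptor),
            score_site(km_a, models$acceptor))
})

test_that("-3 acceptor contexts are classified from the reference k-mer", {
  base <- strrep("T", 15)
  # reference ...aGag| : aGag context, G>C transversion
  km <- paste0(base, "AGAGTTT")  # indices 16..20 = A G A G before exon
  expect_equal(substr(km, 17, 20), "GAGT")  # sanity on construction
  km_aGag <- paste0(strrep("T", 16), "AGAG", "TTT")
  r <- classify_minus3_context(km_aGag, "G", "C")
  expect_true(r$applicable)
  expect_equal(r$context, "aGag")
  expect_equal(r$substitution_label, "G>C transversion")

  # agGag context: indices 16..20 = A G G A G
  km_agGag <- paste0(strrep("T", 15), "AGGAG", "TTT")
  r2 <- classify_minus3_context(km_agGag, "G", "A")
  expect_equal(r2$context, "agGag")
  expect_equal(r2$substitution_label, "G>A transition")

  # non-matching context
  km_other <- paste0(strrep("T", 16), "TGAG", "TTT")
  r3 <- classify_minus3_context(km_other, "G", "C")
  expect_equal(r3$context, "other")

  # precondition unmet: no AG at -2,-1 or ref mismatch
  km_noAG <- paste0(strrep("T", 16), "AGTT", "TTT")
  expect_false(classify_minus3_context(km_noAG, "G", "C")$applicable)
  expect_false(classify_minus3_context(km_aGag, "A", "C")$applicable)
})
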