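# Shared fixtures built in code.

# hand-written alignment rows with sane defaults
aln_tbl <- function(qname, pos, cigar, chrom = "ctg", flag = 99L,
                    mapq = 60L, seq = NULL) {
  n <- max(length(qname), length(pos), length(cigar))
  qname <- rep_len(qname, n); pos <- rep_len(as.integer(pos), n)
  cigar <- rep_len(cigar, n); flag <- rep_len(as.integer(flag), n)
  mapq <- rep_len(as.integer(mapq), n)
  if (is.null(seq)) {
    seq <- vapply(cigar, function(cg) {
      ops <- regmatches(cg, gregexpr("\\d+[MIS=X]", cg))[[1]]
      strrep("A", sum(as.integer(sub("[MIS=X]", "", ops))))
    }, character(1))
  }
  tibble::tibble(qname = qname, flag = flag, chrom = rep_len(chrom, n),
                 pos = pos, mapq = mapq, cigar = cigar, rnext = "=",
                 pnext = 1L, tlen = 0L, seq = rep_len(seq, n),
                 qual = vapply(seq, function(s) strrep("I", nchar(s)),
                               character(1)))
}

mut_rec <- function(chrom = "ctg", pos0, ref = "A", alt = "G",
                    gene = "GENE01", sample_id = "case_01",
                    variant_class = "missense") {
  tibble::tibble(sample_id = sample_id, gene = gene, chrom = chrom,
                 pos = pos0 + 1L, pos0 = as.integer(pos0),
                 ref_allele = ref, alt_allele = alt,
                 variant_class = variant_class,
                 t_ref_count = NA_integer_, t_alt_count = NA_integer_)
}

# one small world + alignments, memoised across tests in a file
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- generate_truth_set(n_events = 4, n_cases = 2, n_controls = 10,
                              n_decoys = 10, true_jaf = 0.5, depth = 80,
                              seed = 7)
      a <- simulate_alignments(w, seed = 7)
      cache <<- list(world = w, aln = a,
                     index = build_junction_index(w$annotation))
    }
    cache
  }
})
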