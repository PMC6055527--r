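# Maximum-entropy-style splice-site scoring. A site model scores a fixed-
# length k-mer (donor: 3 exonic + 6 intronic = 9 nt; acceptor: 20 intronic
# + 3 exonic = 23 nt) as log2(P_model / P_background) in bits. The model
# probability factorizes over position subsets ("blocks", each a
# probability table over the sub-k-mer with an exponent of +1 or -1 so
# that products and ratios of overlapping sub-models can be expressed);
# the intronic consensus dinucleotide (donor +1,+2; acceptor -2,-1) is
# scored separately by consensus-frequency ratios.

DNA_BASES <- c("A", "C", "G", "T")

donor_consensus_positions <- function() 4:5     # intron +1, +2 of the 9-mer
acceptor_consensus_positions <- function() 19:20 # intron -2, -1 of the 23-mer

site_kmer_length <- function(site_kind) {
  switch(site_kind, donor = 9L, acceptor = 23L,
         stop("site_kind must be 'donor' or 'acceptor'", call. = FALSE))
}

site_consensus_positions <- function(site_kind) {
  switch(site_kind, donor = donor_consensus_positions(),
         acceptor = acceptor_consensus_positions())
}

#' Construct a splice-site scoring model
#'
#' @param site_kind `"donor"` (9-mer) or `"acceptor"` (23-mer).
#' @param blocks List of model blocks; each block is a list with
#'   `positions` (integer positions within the k-mer, excluding consensus
#'   positions), `exponent` (+1 or -1) and `probs` (named probability
#'   vector over all sub-k-mers of those positions, summing to 1).
#' @param background Background blocks in the same form.
#' @param consensus List with one entry per consensus position:
#'   `position`, `model` (named ACGT frequencies) and `background`.
#' @param pseudocount Added to every table lookup so all scores stay
#'   finite (default 1e-6).
#' @return A `splice_model` object.
#' @export
splice_model <- function(site_kind, blocks, background, consensus,
                         pseudocount = 1e-6) {
  k <- site_kmer_length(site_kind)
  cons_pos <- vapply(consensus, function(x) as.integer(x$position),
                     integer(1))
  check_block <- function(b, label) {
    stopifnot(all(b$positions >= 1), all(b$positions <= k))
    if (any(b$positions %in% cons_pos)) {
      stop(label, " block overlaps consensus positions", call. = FALSE)
    }
    if (abs(sum(b$probs) - 1) > 1e-9) {
      stop(label, " block probabilities do not sum to 1", call. = FALSE)
    }
    if (is.null(b$exponent)) b$exponent <- 1
    b
  }
  blocks <- lapply(blocks, check_block, label = "model")
  background <- lapply(background, check_block, label = "background")
  consensus <- lapply(consensus, function(x) {
    stopifnot(abs(sum(x$model) - 1) < 1e-9,
              abs(sum(x$background) - 1) < 1e-9)
    x
  })
  structure(
    list(site_kind = site_kind, kmer_length = k, blocks = blocks,
         background = background, consensus = consensus,
         pseudocount = pseudocount),
    class = "splice_model")
}

#' @export
print.splice_model <- function(x, ...) {
  cat("<splice_model>", x$site_kind, "k =", x$kmer_length,
      "blocks =", length(x$blocks), "\n")
  invisible(x)
}

#' Build a splice model with independent positions
#'
#' Convenience constructor for a fully factorized (position-independent)
#' model: one block per non-consensus position.
#'
#' @param site_kind `"donor"` or `"acceptor"`.
#' @param prob_matrix 4 x k matrix of per-position base probabilities
#'   (rows named A, C, G, T), columns summing to 1.
#' @param background_matrix Optional background of the same shape; default
#'   uniform 0.25.
#' @param pseudocount See [splice_model()].
#' @return A `splice_model`.
#' @export
splice_model_independent <- function(site_kind, prob_matrix,
                                     background_matrix = NULL,
                                     pseudocount = 1e-6) {
  k <- site_kmer_length(site_kind)
  stopifnot(nrow(prob_matrix) == 4, ncol(prob_matrix) == k)
  rownames(prob_matrix) <- DNA_BASES
  if (is.null(background_matrix)) {
    background_matrix <- matrix(0.25, 4, k, dimnames = list(DNA_BASES, NULL))
  }
  cons_pos <- site_consensus_positions(site_kind)
  other <- setdiff(seq_len(k), cons_pos)
  one_pos_block <- function(mat, p) {
    list(positions = p, exponent = 1,
         probs = stats::setNames(mat[, p], DNA_BASES))
  }
  splice_model(
    site_kind,
    blocks = lapply(other, function(p) one_pos_block(prob_matrix, p)),
    background = lapply(other, function(p) one_pos_block(background_matrix, p)),
    consensus = lapply(cons_pos, function(p) {
      list(position = p,
           model = stats::setNames(prob_matrix[, p], DNA_BASES),
           background = stats::setNames(background_matrix[, p], DNA_BASES))
    }),
    pseudocount = pseudocount)
}

#' Estimate a splice model from aligned example sites
#'
#' Builds a position-independent model from the per-position base
#' frequencies of a set of k-mers (e.g. all annotated canonical sites of a
#' genome), with uniform background.
#'
#' @param kmers Character vector of site k-mers, all of the length implied
#'   by `site_kind`.
#' @param site_kind `"donor"` or `"acceptor"`.
#' @param alpha Dirichlet smoothing added to each base count (default 0.5).
#' @param pseudocount See [splice_model()].
#' @return A `splice_model`.
#' @export
splice_model_from_sites <- function(kmers, site_kind, alpha = 0.5,
                                    pseudocount = 1e-6) {
  k <- site_kmer_length(site_kind)
  stopifnot(all(nchar(kmers) == k))
  ch <- do.call(rbind, strsplit(toupper(kmers), "", fixed = TRUE))
  freq <- vapply(seq_len(k), function(p) {
    n <- table(factor(ch[, p], levels = DNA_BASES))
    as.numeric(n + alpha) / (sum(n) + 4 * alpha)
  }, numeric(4))
  rownames(freq) <- DNA_BASES
  splice_model_independent(site_kind, freq, pseudocount = pseudocount)
}

# All k-mers over ACGT, lexicographic.
all_kmers <- function(k) {
  g <- do.call(expand.grid,
               c(rep(list(DNA_BASES), k), KEEP.OUT.ATTRS = FALSE,
                 stringsAsFactors = FALSE))
  # expand.grid varies the first column fastest; flip for lexicographic order
  do.call(paste0, rev(g))
}

#' Score k-mers under a splice model
#'
#' Deterministic score in bits: consensus positions contribute
#' `log2((f_model + pc) / (f_background + pc))` of their base frequencies;
#' the remaining positions contribute the factorized model-vs-background
#' probability ratio. Scoring depends only on the k-mer string. K-mers
#' containing characters outside ACGT (e.g. N) are unscoreable and return
#' `NA`.
#'
#' @param kmers Character vector of k-mers, length matching the model.
#' @param model A [splice_model()].
#' @return Numeric vector of scores in bits (`NA` where unscoreable).
#' @export
score_site <- function(kmers, model) {
  stopifnot(inherits(model, "splice_model"))
  kmers <- toupper(kmers)
  if (length(kmers) == 0) return(numeric(0))
  if (any(nchar(kmers) != model$kmer_length)) {
    stop("k-mer length must be ", model$kmer_length, " for a ",
         model$site_kind, " model", call. = FALSE)
  }
  valid <- !grepl("[^ACGT]", kmers)
  out <- rep(NA_real_, length(kmers))
  if (!any(valid)) return(out)
  km <- kmers[valid]
  ch <- do.call(rbind, strsplit(km, "", fixed = TRUE))
  pc <- model$pseudocount
  lookup <- function(block) {
    sub <- if (length(block$positions) == 1) {
      ch[, block$positions]
    } else {
      do.call(paste0, lapply(block$positions, function(p) ch[, p]))
    }
    p <- unname(block$probs[sub])
    p[is.na(p)] <- 0
    p
  }
  s <- numeric(length(km))
  for (b in model$blocks) s <- s + b$exponent * log2(lookup(b) + pc)
  for (b in model$background) s <- s - b$exponent * log2(lookup(b) + pc)
  for (cs in model$consensus) {
    base <- ch[, cs$position]
    s <- s + log2((unname(cs$model[base]) + pc) /
                    (unname(cs$background[base]) + pc))
  }
  out[valid] <- s
  out
}

# ---- k-mer extraction --------------------------------------------------------

mutation_is_snv <- function(mutation) {
  !is.null(mutation) &&
    nchar(mutation$ref_allele) == 1 && nchar(mutation$alt_allele) == 1 &&
    mutation$ref_allele %in% DNA_BASES && mutation$alt_allele %in% DNA_BASES
}

mutation_ref_span <- function(mutation) {
  p <- mutation_pos0(mutation)
  w <- if (mutation$ref_allele == "-") 1L else nchar(mutation$ref_allele)
  c(p, p + w)
}

COMPLEMENT <- stats::setNames(c("T", "G", "C", "A"), c("A", "C", "G", "T"))

#' Extract reference and mutant splice-site k-mers
#'
#' The donor 9-mer covers 3 exonic + 6 intronic bases around the
#' exon/intron boundary; the acceptor 23-mer covers 20 intronic + 3 exonic
#' bases. `boundary` is the genomic coordinate (0-based) of the
#' exon/intron transition: for a plus-strand donor (or minus-strand
#' acceptor) pass the intron's `start`; for a plus-strand acceptor (or
#' minus-strand donor) pass the intron's `end`. Minus-strand k-mers are
#' reverse complemented so the returned string always reads
#' exon -> intron (donor) or intron -> exon (acceptor).
#'
#' Substitutions inside the footprint yield a mutant k-mer; indels inside
#' the footprint flag the site unscoreable; mutations outside the
#' footprint leave `mut_kmer` as `NA`.
#'
#' @param genome Genome (`DNAStringSet` or named character).
#' @param chrom Contig.
#' @param side `"donor"` or `"acceptor"`.
#' @param boundary 0-based boundary coordinate (see above).
#' @param strand `"+"` or `"-"` (gene strand).
#' @param mutation Optional one-row mutation record.
#' @return List with `ref_kmer`, `mut_kmer`, `scoreable`, `mut_index`
#'   (1-based position within the k-mer that differs, or `NA`).
#' @export
extract_site_kmers <- function(genome, chrom, side, boundary, strand = "+",
                               mutation = NULL) {
  stopifnot(side %in% c("donor", "acceptor"), strand %in% c("+", "-"))
  span <- if (side == "donor") {
    if (strand == "+") c(boundary - 3L, boundary + 6L)
    else c(boundary - 6L, boundary + 3L)
  } else {
    if (strand == "+") c(boundary - 20L, boundary + 3L)
    else c(boundary - 3L, boundary + 20L)
  }
  ref_kmer <- fetch_sequence(genome, chrom, span[1], span[2], strand)
  out <- list(ref_kmer = ref_kmer, mut_kmer = NA_character_,
              scoreable = TRUE, mut_index = NA_integer_)
  if (is.null(mutation) || is.na(mutation$chrom) ||
      mutation$chrom != chrom) {
    return(out)
  }
  mspan <- mutation_ref_span(mutation)
  overlaps <- mspan[1] < span[2] && span[1] < mspan[2]
  if (!overlaps) return(out)
  if (!mutation_is_snv(mutation)) {
    out$scoreable <- FALSE
    return(out)
  }
  pos0 <- mutation_pos0(mutation)
  if (strand == "+") {
    idx <- pos0 - span[1] + 1L
    alt <- toupper(mutation$alt_allele)
  } else {
    idx <- span[2] - pos0
    alt <- COMPLEMENT[[toupper(mutation$alt_allele)]]
  }
  mut <- ref_kmer
  substr(mut, idx, idx) <- alt
  out$mut_kmer <- mut
  out$mut_index <- idx
  out
}

# ---- score comparison --------------------------------------------------------

#' Classify the alternative-vs-canonical score relationship
#'
#' Pure-score version of the trichotomy used in reporting:
#' `alt_stronger` when the post-mutation alternative site outscores the
#' post-mutation canonical site; `gap_narrowed` when it does not but the
#' (alternative - canonical) difference increased after mutation;
#' `no_evidence` otherwise; `unscoreable` when any input is `NA`.
#'
#' @param alt_ref,alt_mut Alternative-site scores before/after mutation.
#' @param canonical_ref,canonical_mut Canonical-site scores before/after.
#' @return Character class.
#' @export
score_preference_class <- function(alt_ref, alt_mut, canonical_ref,
                                   canonical_mut) {
  if (any(is.na(c(alt_ref, alt_mut, canonical_ref, canonical_mut)))) {
    return("unscoreable")
  }
  if (alt_mut > canonical_mut) return("alt_stronger")
  if ((alt_mut - canonical_mut) > (alt_ref - canonical_ref)) {
    return("gap_narrowed")
  }
  "no_evidence"
}

#' Score alternative and canonical sites for reference and mutant alleles
#'
#' Extracts the site k-mers at the alternative and nearest canonical
#' boundaries, scores reference and mutant contexts, and classifies the
#' relationship. A site whose k-mer does not contain the mutation keeps
#' its reference score as the mutant score (the mutation does not change
#' that context).
#'
#' @inheritParams extract_site_kmers
#' @param alt_boundary,canonical_boundary 0-based boundary coordinates of
#'   the alternative and canonical sites (same side, same convention as
#'   [extract_site_kmers()]).
#' @param model A [splice_model()] matching `side`.
#' @return List with `scores` (tibble with one row per `site_role`:
#'   `ref_score`, `mut_score`, `delta`) and `preference_class`.
#' @export
compare_scores <- function(genome, chrom, side, alt_boundary,
                           canonical_boundary, strand = "+", mutation = NULL,
                           model) {
  one_site <- function(boundary, role) {
    km <- extract_site_kmers(genome, chrom, side, boundary, strand, mutation)
    if (!km$scoreable) {
      return(tibble::tibble(site_role = role, ref_score = NA_real_,
                            mut_score = NA_real_, delta = NA_real_))
    }
    ref <- score_site(km$ref_kmer, model)
    mut <- if (is.na(km$mut_kmer)) ref else score_site(km$mut_kmer, model)
    tibble::tibble(site_role = role, ref_score = ref, mut_score = mut,
                   delta = mut - ref)
  }
  scores <- dplyr::bind_rows(one_site(alt_boundary, "alternative"),
                             one_site(canonical_boundary, "canonical"))
  list(scores = scores,
       preference_class = score_preference_class(
         scores$ref_score[1], scores$mut_score[1],
         scores$ref_score[2], scores$mut_score[2]))
}

#' Classify the -3 acceptor context of a mutation
#'
#' For a mutation at intronic position -3 of an alternative acceptor
#' (k-mer index 18 of the 23-mer) with the -2,-1 consensus AG in place,
#' decides whether the reference context matches the aGag or agGag repeat
#' pattern (capitalised base = mutated position) and labels the
#' substitution as a transition or transversion.
#'
#' @param acceptor_kmer_ref Reference acceptor 23-mer.
#' @param ref_allele,alt_allele Mutation alleles on the k-mer strand.
#' @return List with `applicable`, `context` (`"aGag"`, `"agGag"` or
#'   `"other"`), and `substitution_label`.
#' @export
classify_minus3_context <- function(acceptor_kmer_ref, ref_allele,
                                    alt_allele) {
  km <- toupper(acceptor_kmer_ref)
  ref_allele <- toupper(ref_allele)
  alt_allele <- toupper(alt_allele)
  at <- function(i) substr(km, i, i)
  ok <- nchar(km) == 23 && at(19) == "A" && at(20) == "G" &&
    at(18) == ref_allele
  if (!ok) {
    return(list(applicable = FALSE, context = NA_character_,
                substitution_label = NA_character_))
  }
  context <- if (at(16) == "A" && at(17) == "G" && at(18) == "G") {
    "agGag"
  } else if (at(17) == "A" && at(18) == "G") {
    "aGag"
  } else {
    "other"
  }
  transition <- paste0(ref_allele, alt_allele) %in% c("AG", "GA", "CT", "TC")
  list(applicable = TRUE, context = context,
       substitution_label = paste0(ref_allele, ">", alt_allele, " ",
                                   if (transition) "transition"
                                   else "transversion"))
}

# ---- model text format -------------------------------------------------------

#' Write a splice model to its plain-text format
#'
#' One block per section. Sections start with `>consensus position=P`,
#' `>block positions=P1,P2,... exponent=E` or `>background positions=...
#' exponent=E`; consensus rows are `base<TAB>model_freq<TAB>background_freq`,
#' block rows are `subkmer<TAB>probability`.
#'
#' @param model A [splice_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_splice_model <- function(model, path) {
  ln <- c("#%crypticsplice splice model v1",
          paste0("site_kind\t", model$site_kind),
          paste0("kmer_length\t", model$kmer_length),
          paste0("pseudocount\t", format(model$pseudocount, digits = 15)))
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  for (cs in model$consensus) {
    ln <- c(ln, paste0(">consensus\tposition=", cs$position),
            paste(DNA_BASES, fmt(cs$model[DNA_BASES]),
                  fmt(cs$background[DNA_BASES]), sep = "\t"))
  }
  emit_block <- function(b, tag) {
    c(paste0(">", tag, "\tpositions=", paste(b$positions, collapse = ","),
             "\texponent=", b$exponent),
      paste(names(b$probs), fmt(b$probs), sep = "\t"))
  }
  for (b in model$blocks) ln <- c(ln, emit_block(b, "block"))
  for (b in model$background) ln <- c(ln, emit_block(b, "background"))
  readr::write_lines(ln, path)
  invisible(path)
}

#' Read a splice model from its plain-text format
#'
#' @param path File written by [write_splice_model()] (or converted from
#'   other maximum-entropy model tables).
#' @return A [splice_model()].
#' @export
read_splice_model <- function(path) {
  ln <- readr::read_lines(path, progress = FALSE)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  kv <- stringr::str_split_fixed(ln[!startsWith(ln, ">")][1:3], "\t", 2)
  hdr <- stats::setNames(kv[, 2], kv[, 1])
  section_starts <- which(startsWith(ln, ">"))
  section_ends <- c(section_starts[-1] - 1L, length(ln))
  consensus <- list()
  blocks <- list()
  background <- list()
  for (i in seq_along(section_starts)) {
    head_ln <- ln[section_starts[i]]
    body <- ln[(section_starts[i] + 1L):section_ends[i]]
    f <- stringr::str_split_fixed(body, "\t", 3)
    if (startsWith(head_ln, ">consensus")) {
      pos <- as.integer(stringr::str_match(head_ln, "position=(\\d+)")[, 2])
      consensus[[length(consensus) + 1]] <- list(
        position = pos,
        model = stats::setNames(as.numeric(f[, 2]), f[, 1])[DNA_BASES],
        background = stats::setNames(as.numeric(f[, 3]), f[, 1])[DNA_BASES])
    } else {
      pos <- as.integer(strsplit(
        stringr::str_match(head_ln, "positions=([0-9,]+)")[, 2], ",")[[1]])
      expn <- as.numeric(stringr::str_match(head_ln, "exponent=(-?\\d+)")[, 2])
      blk <- list(positions = pos, exponent = expn,
                  probs = stats::setNames(as.numeric(f[, 2]), f[, 1]))
      if (startsWith(head_ln, ">background")) {
        background[[length(background) + 1]] <- blk
      } else {
        blocks[[length(blocks) + 1]] <- blk
      }
    }
  }
  splice_model(hdr[["site_kind"]], blocks, background, consensus,
               pseudocount = as.numeric(hdr[["pseudocount"]]))
}

#' Estimate donor and acceptor models from a genome's annotated sites
#'
#' Extracts the canonical donor and acceptor k-mers of every annotated
#' intron and estimates position-independent models from their base
#' frequencies — the standard way to obtain a sensible scoring model for a
#' synthetic world or a small annotation.
#'
#' @param genome Genome.
#' @param index A [build_junction_index()] object.
#' @param pseudocount See [splice_model()].
#' @return List with `donor` and `acceptor` models.
#' @export
splice_models_from_annotation <- function(genome, index,
                                          pseudocount = 1e-6) {
  introns <- index$canonical_introns
  donor_kmers <- vapply(seq_len(nrow(introns)), function(i) {
    b <- if (introns$strand[i] == "-") introns$end[i] else introns$start[i]
    extract_site_kmers(genome, introns$chrom[i], "donor", b,
                       introns$strand[i])$ref_kmer
  }, character(1))
  acceptor_kmers <- vapply(seq_len(nrow(introns)), function(i) {
    b <- if (introns$strand[i] == "-") introns$start[i] else introns$end[i]
    extract_site_kmers(genome, introns$chrom[i], "acceptor", b,
                       introns$strand[i])$ref_kmer
  }, character(1))
  list(donor = splice_model_from_sites(donor_kmers, "donor",
                                       pseudocount = pseudocount),
       acceptor = splice_model_from_sites(acceptor_kmers, "acceptor",
                                          pseudocount = pseudocount))
}
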