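# Self-contained synthetic test worlds: a mini-genome of multi-exon genes
# with consensus splice sites, a mutation table mixing true splice-site-
# creating events with decoys, and spliced paired-end alignments for a case
# cohort plus a mutation-free control cohort, all deterministic per seed.

GENE_FLANK <- 200L
EXON_LEN <- 150L
INTRON_LEN <- 120L
CDS_UTR5 <- 30L

# per-contig layout (0-based half-open)
gene_layout <- function() {
  ex1 <- c(GENE_FLANK, GENE_FLANK + EXON_LEN)                    # [200,350)
  in1 <- c(ex1[2], ex1[2] + INTRON_LEN)                          # [350,470)
  ex2 <- c(in1[2], in1[2] + EXON_LEN)                            # [470,620)
  in2 <- c(ex2[2], ex2[2] + INTRON_LEN)                          # [620,740)
  ex3 <- c(in2[2], in2[2] + EXON_LEN)                            # [740,890)
  list(ex1 = ex1, in1 = in1, ex2 = ex2, in2 = in2, ex3 = ex3,
       contig_len = ex3[2] + GENE_FLANK)
}

NONSTOP_CODONS <- {
  all3 <- do.call(paste0, expand.grid(DNA_BASES, DNA_BASES, DNA_BASES,
                                      stringsAsFactors = FALSE))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

random_codons <- function(n) {
  paste(sample(NONSTOP_CODONS, n, replace = TRUE), collapse = "")
}

# Build one gene contig: random sequence with consensus GT..AG introns,
# a stop-free coding sequence, and an AGAGAG acceptor tail (acceptor -3
# consensus G, the context exploited by the -3 events).
build_gene_contig <- function() {
  ly <- gene_layout()
  s <- sample(DNA_BASES, ly$contig_len, replace = TRUE)
  put <- function(at0, str) {
    s[(at0 + 1):(at0 + nchar(str))] <<- strsplit(str, "")[[1]]
  }
  cds_start <- ly$ex1[1] + CDS_UTR5
  put(cds_start, paste0("ATG", random_codons((EXON_LEN - CDS_UTR5 - 3) / 3)))
  put(ly$ex2[1], random_codons(EXON_LEN / 3))
  put(ly$ex3[1], paste0(random_codons((EXON_LEN - CDS_UTR5) / 3 - 1), "TAA"))
  put(ly$in1[1], "GTAAGT")
  put(ly$in2[1], "GTAAGT")
  put(ly$in1[2] - 6L, "AGAGAG")
  put(ly$in2[2] - 6L, "AGAGAG")
  list(seq = s, layout = ly, cds_start = cds_start)
}

# Plant one event into a gene contig; returns modified sequence plus the
# event geometry (mutation + canonical/alternative introns).
plant_event <- function(contig, event_type) {
  ly <- contig$layout
  s <- contig$seq
  put <- function(at0, str) {
    s[(at0 + 1):(at0 + nchar(str))] <<- strsplit(str, "")[[1]]
  }
  if (event_type == "donor_out") {
    d <- sample(c(9L, 12L, 15L, 18L), 1)
    a <- ly$in2[1] - d
    put(a, "AT")  # mutation A>G creates the GT donor dinucleotide
    geom <- list(mut_pos0 = a, ref_allele = "A", alt_allele = "G",
                 variant_class = "silent",
                 canonical = ly$in2, alt_intron = c(a, ly$in2[2]),
                 side = "donor", in_out = "splice_out")
  } else if (event_type == "donor_in") {
    d <- sample(c(9L, 12L, 15L, 18L), 1)
    a <- ly$in2[1] - d
    put(a - 1L, "CGT")  # GT already present; exonic C>G strengthens the site
    geom <- list(mut_pos0 = a - 1L, ref_allele = "C", alt_allele = "G",
                 variant_class = "missense",
                 canonical = ly$in2, alt_intron = c(a, ly$in2[2]),
                 side = "donor", in_out = "splice_in")
  } else if (event_type == "acceptor_minus3") {
    # reference AGAGAG tail: alternative acceptor 2 nt upstream of the
    # canonical one, mutated at its -3 position (aGag context), G>C
    e <- ly$in1[2]
    geom <- list(mut_pos0 = e - 5L, ref_allele = "G", alt_allele = "C",
                 variant_class = "noncoding",
                 canonical = ly$in1, alt_intron = c(ly$in1[1], e - 2L),
                 side = "acceptor", in_out = "splice_out")
  } else if (event_type == "donor_del30") {
    a <- ly$in2[1] - 30L  # codon-aligned: removes exactly 10 codons
    put(a, "AT")
    geom <- list(mut_pos0 = a, ref_allele = "A", alt_allele = "G",
                 variant_class = "silent",
                 canonical = ly$in2, alt_intron = c(a, ly$in2[2]),
                 side = "donor", in_out = "splice_out")
  } else {
    stop("unknown event type: ", event_type, call. = FALSE)
  }
  if (geom$alt_intron[2] - geom$alt_intron[1] < 20) {
    stop("alternative intron shorter than 20 nt cannot be embedded",
         call. = FALSE)
  }
  contig$seq <- s
  contig$geom <- geom
  contig
}

# Exonic positions available for decoy mutations: mid-exon-2, at least 25 bp
# from every canonical or alternative junction boundary.
DECOY_SLOTS <- function(ly) (ly$ex2[1] + 40L):(ly$ex2[1] + 79L)

#' Generate a synthetic truth world
#'
#' Builds a deterministic mini-genome of multi-exon genes (consensus
#' GT..AG introns, stop-free coding sequence), embeds splice-site-creating
#' events of the requested types, adds decoy mutations with no splicing
#' effect, and declares the full truth needed by tests: per event the
#' mutation, the canonical and alternative introns, the target junction
#' allele fraction and depth, and which control samples are contaminated.
#'
#' Event types: `donor_out` (intronic substitution creating a GT donor
#' upstream of the canonical one), `donor_in` (exonic substitution
#' strengthening an existing upstream GT; the mutation stays in the new
#' exon), `acceptor_minus3` (G>C at the -3 position of an alternative
#' acceptor 2 nt upstream of the canonical one, aGag context), and
#' `donor_del30` (donor creation removing exactly 30 coding nt in frame).
#'
#' @param n_events Number of true events.
#' @param event_types Types recycled across events.
#' @param true_jaf Target junction allele fraction per event (recycled).
#' @param depth Fragment depth at the event locus in the carrier sample
#'   (recycled).
#' @param n_cases,n_controls Cohort sizes; events and decoys are assigned
#'   to case samples round-robin, controls carry no mutations.
#' @param control_depth Fragment depth per junction locus in non-carrier
#'   samples.
#' @param n_decoys Decoy mutations (exonic, no splicing effect).
#' @param control_contamination Fraction of control samples that also
#'   express each event's alternative junction (recycled).
#' @param include_hla Add an HLA-A gene (no events) to the annotation.
#' @param seed Integer seed; worlds are byte-identical per seed.
#' @return A `scm_world` list: `genome` (DNAStringSet), `annotation`
#'   (exon tibble), `mutations` (mutation tibble incl. decoys), `truth`
#'   (one row per event), `transcripts` (list of transcript models),
#'   `samples` (list of case/control ids), `params`.
#' @export
generate_truth_set <- function(n_events = 4,
                               event_types = c("donor_out", "donor_in",
                                               "acceptor_minus3",
                                               "donor_del30"),
                               true_jaf = 0.5, depth = 100,
                               n_cases = 2, n_controls = 10,
                               control_depth = 30, n_decoys = 0,
                               control_contamination = 0,
                               include_hla = TRUE, seed = 1) {
  stopifnot(n_events >= 1, n_cases >= 1)
  types <- rep_len(event_types, n_events)
  jafs <- rep_len(true_jaf, n_events)
  depths <- rep_len(depth, n_events)
  contam <- rep_len(control_contamination, n_events)
  if (any(jafs <= 0 | jafs > 1)) {
    stop("true_jaf must lie in (0, 1]", call. = FALSE)
  }
  n_genes <- max(n_events, ceiling(n_decoys / 30))
  case_ids <- sprintf("case_%02d", seq_len(n_cases))
  control_ids <- sprintf("ctrl_%02d", seq_len(n_controls))

  with_seed(seed, {
    contigs <- vector("list", n_genes)
    genes <- sprintf("GENE%02d", seq_len(n_genes))
    for (i in seq_len(n_genes)) {
      contig <- build_gene_contig()
      if (i <= n_events) contig <- plant_event(contig, types[i])
      contigs[[i]] <- contig
    }
    chroms <- sprintf("ctg%02d", seq_len(n_genes))

    truth <- purrr::map_dfr(seq_len(n_events), function(i) {
      g <- contigs[[i]]$geom
      n_contam <- round(contam[i] * n_controls)
      contaminated <- if (n_contam > 0) {
        sort(sample(control_ids, n_contam))
      } else {
        character(0)
      }
      tibble::tibble(
        event_id = sprintf("ev%02d", i),
        event_type = types[i],
        gene = genes[i], chrom = chroms[i],
        sample_id = case_ids[(i - 1L) %% n_cases + 1L],
        mut_pos0 = g$mut_pos0, ref_allele = g$ref_allele,
        alt_allele = g$alt_allele,
        variant_class = g$variant_class,
        canonical_start = g$canonical[1], canonical_end = g$canonical[2],
        alt_start = g$alt_intron[1], alt_end = g$alt_intron[2],
        side = g$side, in_out = g$in_out,
        true_jaf = jafs[i], depth = depths[i],
        n_controls = n_controls,
        control_contamination = contam[i],
        contaminated_controls = list(contaminated))
    })

    decoys <- if (n_decoys > 0) {
      slots <- purrr::map_dfr(seq_len(n_genes), function(i) {
        tibble::tibble(gene = genes[i], chrom = chroms[i],
                       pos0 = DECOY_SLOTS(contigs[[i]]$layout))
      })
      pick <- slots[sample.int(nrow(slots), n_decoys), , drop = FALSE]
      pick$ref_allele <- vapply(seq_len(nrow(pick)), function(j) {
        contigs[[match(pick$gene[j], genes)]]$seq[pick$pos0[j] + 1L]
      }, character(1))
      pick$alt_allele <- vapply(pick$ref_allele, function(r) {
        sample(setdiff(DNA_BASES, r), 1)
      }, character(1))
      pick$sample_id <- case_ids[(seq_len(n_decoys) - 1L) %% n_cases + 1L]
      pick
    } else {
      NULL
    }

    mut_rows <- dplyr::bind_rows(
      tibble::tibble(
        sample_id = truth$sample_id, gene = truth$gene, chrom = truth$chrom,
        pos = truth$mut_pos0 + 1L, ref_allele = truth$ref_allele,
        alt_allele = truth$alt_allele, variant_class = truth$variant_class,
        t_ref_count = NA_integer_, t_alt_count = NA_integer_,
        event_id = truth$event_id, is_decoy = FALSE),
      if (!is.null(decoys)) {
        tibble::tibble(
          sample_id = decoys$sample_id, gene = decoys$gene,
          chrom = decoys$chrom, pos = decoys$pos0 + 1L,
          ref_allele = decoys$ref_allele, alt_allele = decoys$alt_allele,
          variant_class = "missense",
          t_ref_count = NA_integer_, t_alt_count = NA_integer_,
          event_id = NA_character_, is_decoy = TRUE)
      })
    mutations <- as_mutation_tbl(mut_rows)

    seqs <- vapply(contigs, function(x) paste(x$seq, collapse = ""),
                   character(1))
    names(seqs) <- chroms
    ly <- gene_layout()
    annotation <- purrr::map_dfr(seq_len(n_genes), function(i) {
      tibble::tibble(
        chrom = chroms[i],
        start = c(ly$ex1[1], ly$ex2[1], ly$ex3[1]),
        end = c(ly$ex1[2], ly$ex2[2], ly$ex3[2]),
        strand = "+", gene = genes[i],
        transcript_id = paste0(genes[i], ".t1"))
    })
    transcripts <- lapply(seq_len(n_genes), function(i) {
      transcript_model(
        exons = tibble::tibble(chrom = chroms[i],
                               start = c(ly$ex1[1], ly$ex2[1], ly$ex3[1]),
                               end = c(ly$ex1[2], ly$ex2[2], ly$ex3[2])),
        strand = "+", cds_start = contigs[[i]]$cds_start,
        protein_id = paste0(genes[i], ".p1"))
    })
    names(transcripts) <- genes
    if (include_hla) {
      hla_seq <- paste(sample(DNA_BASES, 700, replace = TRUE), collapse = "")
      seqs <- c(seqs, ctgHLA = hla_seq)
      annotation <- dplyr::bind_rows(
        annotation,
        tibble::tibble(chrom = "ctgHLA", start = c(100L, 350L),
                       end = c(250L, 500L), strand = "+", gene = "HLA-A",
                       transcript_id = "HLA-A.t1"))
    }
    structure(
      list(genome = Biostrings::DNAStringSet(seqs),
           annotation = annotation, mutations = mutations, truth = truth,
           transcripts = transcripts,
           samples = list(cases = case_ids, controls = control_ids),
           params = list(seed = seed, control_depth = control_depth,
                         n_decoys = n_decoys, include_hla = include_hla)),
      class = "scm_world")
  })
}

#' @export
print.scm_world <- function(x, ...) {
  cat("<scm_world>", length(x$genome), "contig(s),",
      nrow(x$truth), "event(s),", sum(x$mutations$is_decoy), "decoy(s),",
      length(x$samples$cases), "case(s) +", length(x$samples$controls),
      "control(s)\n")
  invisible(x)
}

# ---- read simulation ---------------------------------------------------------

# Vectorised fragment generation for one junction locus of one sample.
# Returns SAM-record rows (two reads per fragment).
simulate_locus_reads <- function(contig_str, chrom, intron, alt, n_frags,
                                 jaf, mutation, read_len, mapq,
                                 low_mapq_fraction, low_mapq,
                                 both_mates_span, mutant_read_fraction,
                                 prefix) {
  if (n_frags == 0) return(NULL)
  L <- read_len
  s <- intron[1]; e <- intron[2]
  is_alt <- if (is.null(alt)) rep(FALSE, n_frags) else runif(n_frags) < jaf
  anchor <- if (is.null(alt)) s - 1L else junction_anchor(
    list(start = alt[1], end = alt[2]), list(pos0 = mutation$pos0))

  seq_of <- function(st, m1, gap_start, gap_end, m2, mutate) {
    # one aligned fragment: M1 (+ optional N gap + M2); apply the alt
    # allele when the mutation is inside an aligned block
    part1 <- substr(contig_str, st + 1L, st + m1)
    if (mutate && mutation$pos0 >= st && mutation$pos0 < st + m1) {
      i <- mutation$pos0 - st + 1L
      substr(part1, i, i) <- mutation$alt_allele
    }
    if (m2 == 0L) return(part1)
    part2 <- substr(contig_str, gap_end + 1L, gap_end + m2)
    if (mutate && mutation$pos0 >= gap_end && mutation$pos0 < gap_end + m2) {
      i <- mutation$pos0 - gap_end + 1L
      substr(part2, i, i) <- mutation$alt_allele
    }
    paste0(part1, part2)
  }

  # read 1: alternative fragments splice at the alternative intron;
  # canonical fragments at a donor-type locus are anchored on the exonic
  # base (contiguous when they end before the canonical donor), else they
  # splice at the canonical intron
  donor_type <- !is.null(alt) && alt[1] < s
  st_can <- if (donor_type) {
    sample(seq(anchor - L + 1L, anchor), n_frags, replace = TRUE)
  } else {
    sample(seq(s - L + 5L, s - 5L), n_frags, replace = TRUE)
  }
  st_alt <- if (is.null(alt)) rep(NA_integer_, n_frags) else {
    sample(seq(alt[1] - L + 5L, alt[1] - 5L), n_frags, replace = TRUE)
  }
  mutate1 <- is_alt & runif(n_frags) < mutant_read_fraction
  pos1 <- ifelse(is_alt, st_alt, st_can)
  spliced_cigar <- function(st, a, b) {
    paste0(a - st, "M", b - a, "N", L - (a - st), "M")
  }
  cigar1 <- character(n_frags)
  seq1 <- character(n_frags)
  for (i in seq_len(n_frags)) {
    if (is_alt[i]) {
      cigar1[i] <- spliced_cigar(pos1[i], alt[1], alt[2])
      seq1[i] <- seq_of(pos1[i], alt[1] - pos1[i], alt[1], alt[2],
                        L - (alt[1] - pos1[i]), mutate1[i])
    } else if (pos1[i] + L <= s) {
      cigar1[i] <- paste0(L, "M")
      seq1[i] <- seq_of(pos1[i], L, 0L, 0L, 0L, FALSE)
    } else {
      cigar1[i] <- spliced_cigar(pos1[i], s, e)
      seq1[i] <- seq_of(pos1[i], s - pos1[i], s, e, L - (s - pos1[i]), FALSE)
    }
  }

  # read 2: plain exonic mate downstream of the intron, except that some
  # alternative fragments have both mates spanning the junction
  # (exercising fragment-level deduplication)
  mate_pos <- e + 40L
  both <- is_alt & runif(n_frags) < both_mates_span
  st2 <- ifelse(both,
                if (is.null(alt)) mate_pos else {
                  sample(seq(alt[1] - L + 5L, alt[1] - 5L), n_frags,
                         replace = TRUE)
                },
                mate_pos)
  mutate2 <- both & runif(n_frags) < mutant_read_fraction
  cigar2 <- character(n_frags)
  seq2 <- character(n_frags)
  for (i in seq_len(n_frags)) {
    if (both[i]) {
      cigar2[i] <- spliced_cigar(st2[i], alt[1], alt[2])
      seq2[i] <- seq_of(st2[i], alt[1] - st2[i], alt[1], alt[2],
                        L - (alt[1] - st2[i]), mutate2[i])
    } else {
      cigar2[i] <- paste0(L, "M")
      seq2[i] <- seq_of(st2[i], L, 0L, 0L, 0L, FALSE)
    }
  }

  q <- ifelse(runif(n_frags) < low_mapq_fraction, low_mapq, mapq)
  qn <- sprintf("%s_%05d", prefix, seq_len(n_frags))
  tl <- st2 + L - pos1
  dplyr::bind_rows(
    tibble::tibble(qname = qn, flag = 99L, chrom = chrom, pos = pos1,
                   mapq = as.integer(q), cigar = cigar1, rnext = "=",
                   pnext = st2 + 1L, tlen = tl, seq = seq1,
                   qual = strrep("I", L)),
    tibble::tibble(qname = qn, flag = 147L, chrom = chrom, pos = st2,
                   mapq = as.integer(q), cigar = cigar2, rnext = "=",
                   pnext = pos1 + 1L, tlen = -tl, seq = seq2,
                   qual = strrep("I", L)))
}

#' Simulate spliced paired-end alignments for a synthetic world
#'
#' For every sample and every gene, fragments are drawn at both junction
#' loci. At an event locus the carrier sample (and any contaminated
#' control) splices each fragment at the alternative junction with
#' probability `true_jaf`, so the expected junction fraction at the locus
#' equals the declared truth; all other fragments use the canonical
#' junction. CIGAR N spans encode introns exactly; reads are error-free by
#' default (junction detection is CIGAR-driven).
#'
#' @param world A [generate_truth_set()] world.
#' @param read_len Read length (default 75).
#' @param mapq Mapping quality of simulated reads (default 60).
#' @param low_mapq_fraction Fraction of fragments downgraded to `low_mapq`
#'   (exercises the Q20 filter).
#' @param low_mapq Mapping quality assigned to downgraded fragments.
#' @param both_mates_span Probability that both mates of an alternative
#'   fragment span the junction (exercises fragment deduplication).
#' @param mutant_read_fraction Probability that an alternative fragment
#'   carries the alternate allele where the mutation is exonic.
#' @param seed Integer seed.
#' @return Named list of alignment tibbles, one per sample
#'   (cases then controls), coordinate sorted.
#' @export
simulate_alignments <- function(world, read_len = 75, mapq = 60,
                                low_mapq_fraction = 0, low_mapq = 10,
                                both_mates_span = 0.2,
                                mutant_read_fraction = 1, seed = 1) {
  ly <- gene_layout()
  if (read_len >= INTRON_LEN) {
    stop("read_len must be shorter than the intron length", call. = FALSE)
  }
  genes <- unique(world$truth$gene)
  all_genes <- setdiff(unique(world$annotation$gene), "HLA-A")
  contig_strs <- vapply(as.character(world$genome), identity, character(1))
  names(contig_strs) <- names(world$genome)
  gene_chrom <- stats::setNames(
    world$annotation$chrom[!duplicated(world$annotation$gene)],
    world$annotation$gene[!duplicated(world$annotation$gene)])
  ctrl_depth <- world$params$control_depth
  samples <- c(world$samples$cases, world$samples$controls)

  with_seed(seed, {
    out <- lapply(samples, function(smp) {
      per_gene <- lapply(all_genes, function(g) {
        chrom <- gene_chrom[[g]]
        cstr <- contig_strs[[chrom]]
        ev <- world$truth[world$truth$gene == g, , drop = FALSE]
        loci <- list(list(intron = ly$in1, alt = NULL),
                     list(intron = ly$in2, alt = NULL))
        depth <- c(ctrl_depth, ctrl_depth)
        jaf <- c(0, 0)
        mutation <- list(NULL, NULL)
        if (nrow(ev) == 1) {
          locus_idx <- if (ev$canonical_start == ly$in1[1]) 1L else 2L
          carrier <- identical(smp, ev$sample_id)
          contaminated <- smp %in% ev$contaminated_controls[[1]]
          if (carrier || contaminated) {
            loci[[locus_idx]]$alt <- c(ev$alt_start, ev$alt_end)
            jaf[locus_idx] <- ev$true_jaf
            mutation[[locus_idx]] <- list(pos0 = ev$mut_pos0,
                                          alt_allele = ev$alt_allele)
            if (carrier) depth[locus_idx] <- ev$depth
          }
        }
        dplyr::bind_rows(lapply(1:2, function(k) {
          simulate_locus_reads(
            cstr, chrom, loci[[k]]$intron, loci[[k]]$alt, depth[k], jaf[k],
            mutation[[k]], read_len, mapq, low_mapq_fraction, low_mapq,
            both_mates_span, mutant_read_fraction,
            prefix = sprintf("%s_%s_L%d", smp, g, k))
        }))
      })
      df <- dplyr::bind_rows(per_gene) %>%
        dplyr::arrange(.data$chrom, .data$pos, .data$qname)
      new_alignments(df, tibble::tibble(
        chrom = names(world$genome),
        length = Biostrings::width(world$genome)))
    })
    names(out) <- samples
    out
  })
}

# ---- world serialisation -----------------------------------------------------

#' Write a synthetic world to standard files
#'
#' Emits `genome.fa`, `annotation.gtf`, `mutations.maf` and a
#' `truth.json` manifest into `dir`; with `alignments` given, also one
#' coordinate-sorted SAM per sample under `dir`.
#'
#' @param world A [generate_truth_set()] world.
#' @param dir Output directory (created if missing).
#' @param alignments Optional result of [simulate_alignments()].
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir, alignments = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(world$genome, file.path(dir, "genome.fa"))
  ann <- world$annotation
  gtf <- paste(
    ann$chrom, "crypticsplice", "exon", ann$start + 1L, ann$end, ".",
    ann$strand, ".",
    sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
            ann$gene, ann$transcript_id, ann$gene),
    sep = "\t")
  readr::write_lines(gtf, file.path(dir, "annotation.gtf"))
  write_mutations(world$mutations, file.path(dir, "mutations.maf"))
  truth <- world$truth
  truth$contaminated_controls <- lapply(truth$contaminated_controls,
                                        as.character)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  if (!is.null(alignments)) {
    for (smp in names(alignments)) {
      write_sam(alignments[[smp]], file.path(dir, paste0(smp, ".sam")),
                genome = world$genome)
    }
  }
  invisible(dir)
}
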