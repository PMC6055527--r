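# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: plain per-record loops and direct table
# arithmetic.

# Re-parse every CIGAR string record by record and tally N spans per
# fragment name; candidates are all introns whose nearer boundary is
# within `window` of the mutation with at least `min_reads` distinct
# fragments at mapq >= min_mapq.
oracle_discover <- function(aln, chrom, mut_pos0, window = 20, min_reads = 5,
                            min_mapq = 20) {
  seen <- list()
  for (i in seq_len(nrow(aln))) {
    if (aln$chrom[i] != chrom) next
    if (aln$mapq[i] < min_mapq) next
    fl <- aln$flag[i]
    if (bitwAnd(fl, 256L) || bitwAnd(fl, 2048L) || bitwAnd(fl, 1024L)) next
    ref <- aln$pos[i]
    m <- gregexpr("\\d+[MIDNSHP=X]", aln$cigar[i])[[1]]
    ops <- regmatches(aln$cigar[i], gregexpr("\\d+[MIDNSHP=X]", aln$cigar[i]))[[1]]
    for (op in ops) {
      len <- as.integer(substr(op, 1, nchar(op) - 1))
      code <- substr(op, nchar(op), nchar(op))
      if (code == "N") {
        key <- paste(ref, ref + len, sep = "-")
        seen[[key]] <- union(seen[[key]], aln$qname[i])
      }
      if (code %in% c("M", "D", "N", "=", "X")) ref <- ref + len
    }
  }
  if (length(seen) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      support = integer()))
  }
  out <- do.call(rbind, lapply(names(seen), function(key) {
    se <- as.integer(strsplit(key, "-")[[1]])
    data.frame(start = se[1], end = se[2], support = length(seen[[key]]))
  }))
  d <- pmin(abs(mut_pos0 - out$start), abs(mut_pos0 - out$end))
  out <- out[d <= window & out$support >= min_reads, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Counting definition of the nearest-rank quantile: the smallest value v
# in the multiset with #(x <= v) > p * n.
oracle_quantile <- function(x, p) {
  n <- length(x)
  for (v in sort(unique(x))) {
    if (sum(x <= v) > p * n) return(v)
  }
  max(x)
}

# Direct table arithmetic for splice scores: multiply raw probabilities
# (plus pseudocount), divide by background, log2 at the end. Vectorised
# over k-mers but structured around products rather than log sums, and
# using match() lookups instead of named indexing.
oracle_score <- function(kmers, model) {
  pc <- model$pseudocount
  ch <- do.call(rbind, strsplit(toupper(kmers), "", fixed = TRUE))
  pick <- function(block) {
    sub <- apply(ch[, block$positions, drop = FALSE], 1, paste0,
                 collapse = "")
    p <- block$probs[match(sub, names(block$probs))]
    p[is.na(p)] <- 0
    unname(p) + pc
  }
  num <- rep(1, length(kmers))
  den <- rep(1, length(kmers))
  for (b in model$blocks) num <- num * pick(b)^b$exponent
  for (b in model$background) den <- den * pick(b)^b$exponent
  for (cs in model$consensus) {
    base <- ch[, cs$position]
    num <- num * (cs$model[match(base, names(cs$model))] + pc)
    den <- den * (cs$background[match(base, names(cs$background))] + pc)
  }
  bad <- apply(ch, 1, function(r) any(!r %in% c("A", "C", "G", "T")))
  out <- log2(num) - log2(den)
  out[bad] <- NA_real_
  unname(out)
}
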