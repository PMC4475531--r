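# Independent oracles used across the suite.

# Exhaustive path-enumeration oracle for glocal affine-gap alignment:
# every monotone alignment path is enumerated explicitly (no dynamic
# programming), with free target overhang on both sides and the full query
# consumed. Exponential; only for tiny sequences.
oracle_glocal_enum <- function(query, target, sc) {
  qs <- strsplit(query, "")[[1]]
  ts <- strsplit(target, "")[[1]]
  m <- length(qs); n <- length(ts)
  best <- -Inf
  rec <- function(i, j, score, lastop) {
    if (i == m) {                      # trailing target overhang is free
      if (score > best) best <<- score
      return(invisible())
    }
    if (j < n) {
      s <- if (qs[i + 1] == ts[j + 1] && qs[i + 1] != "N") sc$match
           else sc$mismatch
      rec(i + 1, j + 1, score + s, "M")
    }
    rec(i + 1, j, score +
          if (lastop == "I") sc$gap_extend else sc$gap_open, "I")
    if (j < n) {
      rec(i, j + 1, score +
            if (lastop == "D") sc$gap_extend else sc$gap_open, "D")
    }
  }
  for (j0 in 0:n) rec(0L, j0, 0, "start")
  best
}

# Established independent implementation of the same glocal contract
# (pattern-global / subject-local affine-gap alignment). Gap-cost mapping:
# ours cost(g) = |open| + (g-1)|ext|; Biostrings cost(g) =
# gapOpening + g*gapExtension.
oracle_glocal_biostrings <- function(query, target, sc) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(sc$match, sc$mismatch)
  Biostrings::score(Biostrings::pairwiseAlignment(
    query, target, type = "global-local", substitutionMatrix = mat,
    gapOpening = -(sc$gap_open - sc$gap_extend),
    gapExtension = -sc$gap_extend))
}

# Exhaustive hypergeometric tail enumeration with choose() products,
# independent of phyper(): the one-tailed Fisher p for the 2x2 table
# [[ref, alt], [expected_ref, expected_alt]].
oracle_fisher_tail <- function(ref_count, alt_count, error_rate) {
  depth <- ref_count + alt_count
  e_alt <- round(depth * error_rate)
  M <- alt_count + e_alt          # total alt margin
  N <- 2L * depth                 # grand total
  K <- depth                      # observed-row margin
  ks <- max(0L, K - (N - M)):min(K, M)
  probs <- choose(M, ks) * choose(N - M, K - ks) / choose(N, K)
  sum(probs[ks >= alt_count])
}

# brute-force pileup: depth profile over [start0, end0) from (pos0, cigar)
oracle_depth <- function(reads_pos0, cigars, start0, end0) {
  depth <- rep.int(0L, end0 - start0)
  for (r in seq_along(reads_pos0)) {
    p <- reads_pos0[r]
    ops <- regmatches(cigars[r], gregexpr("[0-9]+[MIDSHN]", cigars[r]))[[1]]
    for (o in ops) {
      len <- as.integer(sub("[MIDSHN]", "", o))
      op <- sub("[0-9]+", "", o)
      if (op %in% c("M", "D")) {
        lo <- max(p, start0); hi <- min(p + len, end0)
        if (hi > lo) {
          depth[(lo - start0 + 1):(hi - start0)] <-
            depth[(lo - start0 + 1):(hi - start0)] + 1L
        }
        p <- p + len
      } else if (op == "N") {
        p <- p + len
      }
    }
  }
  depth
}

random_scoring <- function() {
  ge <- -sample(1:4, 1)
  scoring_scheme(match = sample(1:5, 1), mismatch = -sample(1:6, 1),
                 gap_open = ge - sample(0:5, 1), gap_extend = ge)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
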