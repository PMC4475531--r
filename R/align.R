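# align: Gotoh affine-gap alignment, single-read and paired-end placement,
# and sorted/indexed BAM emission.

#' Affine-gap scoring scheme
#'
#' Gap of length g costs `gap_open + (g - 1) * gap_extend` (both negative;
#' `gap_open` includes the first gapped base).
#'
#' @param match positive match score.
#' @param mismatch negative mismatch score.
#' @param gap_open negative cost of the first base of a gap.
#' @param gap_extend negative cost of each additional gap base;
#'   `gap_open <= gap_extend`.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -4L, gap_open = -6L,
                           gap_extend = -1L) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            gap_open <= gap_extend)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' Glocal Gotoh alignment of a query against a target window
#'
#' Three-state affine-gap dynamic programming. The full query is aligned;
#' the target may overhang on both sides free of charge. Returns the
#' maximal score under the scheme, a CIGAR over {M,I,D} and the 0-based
#' offset of the alignment start within the target. A target shorter than
#' half the query yields a no-alignment result (score `-Inf`).
#'
#' @param query,target DNA sequences (character scalars).
#' @param scoring a [scoring_scheme()].
#' @return list with `score`, `cigar`, `target_offset`.
#' @export
gotoh_align <- function(query, target, scoring = scoring_scheme()) {
  if (nchar(query) == 0) stop("empty query")
  if (nchar(target) < nchar(query) / 2) {
    return(list(score = -Inf, cigar = NA_character_,
                target_offset = NA_integer_))
  }
  gotoh_cpp(query, target, scoring$match, scoring$mismatch,
            scoring$gap_open, scoring$gap_extend)
}

#' Aligner configuration
#'
#' @param k seed length (8..15).
#' @param max_hits k-mer repeat-masking threshold.
#' @param band diagonal band width for seed voting.
#' @param min_seed_hits minimum seed votes for a candidate band.
#' @param max_candidates cap on candidate windows per read.
#' @param scoring a [scoring_scheme()].
#' @param min_score_frac minimum accepted score as a fraction of the
#'   perfect-match score (`match * read_length`).
#' @param insert_min,insert_max accepted proper-pair insert-size range.
#' @param chunk_size reads per processing chunk in [align_all()].
#' @return object of class `align_config`.
#' @export
align_config <- function(k = 11L, max_hits = 64L, band = 16L,
                         min_seed_hits = 2L, max_candidates = 32L,
                         scoring = scoring_scheme(), min_score_frac = 0.4,
                         insert_min = 100L, insert_max = 600L,
                         chunk_size = 1000L) {
  structure(list(k = as.integer(k), max_hits = as.integer(max_hits),
                 band = as.integer(band),
                 min_seed_hits = as.integer(min_seed_hits),
                 max_candidates = as.integer(max_candidates),
                 scoring = scoring, min_score_frac = min_score_frac,
                 insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max),
                 chunk_size = as.integer(chunk_size)),
            class = "align_config")
}

cigar_ops <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDSHN]", cigar))[[1]]
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

cigar_query_len <- function(cigar) {
  o <- cigar_ops(cigar)
  sum(o$len[o$op %in% c("M", "I", "S")])
}

cigar_ref_len <- function(cigar) {
  o <- cigar_ops(cigar)
  sum(o$len[o$op %in% c("M", "D", "N")])
}

# terminal query gaps (I) become soft clips for SAM emission
cigar_softclip_ends <- function(cigar) {
  o <- cigar_ops(cigar)
  if (nrow(o) == 0) return(cigar)
  if (o$op[1] == "I") o$op[1] <- "S"
  if (o$op[nrow(o)] == "I") o$op[nrow(o)] <- "S"
  paste0(o$len, o$op, collapse = "")
}

# all candidate alignments of one read sequence, best first
align_candidates <- function(seq, ref, index, cfg, rc = NULL) {
  if (is.null(rc)) rc <- revcomp(seq)
  cand <- candidate_positions(seq, index, cfg$min_seed_hits, cfg$band,
                              cfg$max_candidates, rc = rc)
  out <- data.frame(contig = character(0), pos = integer(0),
                    strand = character(0), score = numeric(0),
                    cigar = character(0), stringsAsFactors = FALSE)
  if (nrow(cand) == 0) return(out)
  n <- nrow(cand)
  pos <- integer(n); score <- numeric(n); cig <- character(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    query <- if (cand$strand[i] == "+") seq else rc
    target <- substr(ref[[cand$contig[i]]], cand$window_start[i] + 1L,
                     cand$window_end[i])
    al <- gotoh_align(query, target, cfg$scoring)
    if (!is.finite(al$score)) next
    ok[i] <- TRUE
    pos[i] <- cand$window_start[i] + al$target_offset
    score[i] <- al$score
    cig[i] <- cigar_softclip_ends(al$cigar)
  }
  if (!any(ok)) return(out)
  d <- quick_df(list(contig = cand$contig[ok], pos = pos[ok],
                     strand = cand$strand[ok], score = score[ok],
                     cigar = cig[ok]))
  # dedupe identical placements reached from adjacent bands
  d <- d[!duplicated(d[, c("contig", "pos", "strand")]), , drop = FALSE]
  ci <- match(d$contig, names(ref))
  d[order(-d$score, ci, d$pos, d$strand != "+"), , drop = FALSE]
}

mapq_from_scores <- function(scores) {
  best <- scores[1]
  second <- if (length(scores) >= 2) scores[2] else 0
  as.integer(max(0, min(60, 2 * (best - second))))
}

# plain-list alignment records (hot path); data.frames are assembled once
# per chunk
unmapped_record <- function(read) {
  list(qname = read$read_id, mapped = FALSE, contig = NA_character_,
       pos = NA_integer_, strand = "+", mapq = 0L, cigar = NA_character_,
       score = NA_real_, seq = read$sequence, qual = read$quality)
}

record_from_alignment <- function(read, aln, mapq) {
  fwd <- aln$strand == "+"
  list(qname = read$read_id, mapped = TRUE, contig = aln$contig,
       pos = as.integer(aln$pos), strand = aln$strand,
       mapq = as.integer(mapq), cigar = aln$cigar,
       score = as.numeric(aln$score),
       seq = if (fwd) read$sequence else revcomp(read$sequence),
       qual = if (fwd) read$quality else reverse_string(read$quality))
}

assemble_records <- function(recs) {
  get_chr <- function(f) vapply(recs, function(r) as.character(r[[f]]),
                                character(1))
  get_int <- function(f) vapply(recs, function(r) as.integer(r[[f]]),
                                integer(1))
  quick_df(list(
    qname = get_chr("qname"),
    mapped = vapply(recs, `[[`, logical(1), "mapped"),
    contig = get_chr("contig"), pos = get_int("pos"),
    strand = get_chr("strand"), mapq = get_int("mapq"),
    cigar = get_chr("cigar"),
    score = vapply(recs, function(r) as.numeric(r[["score"]]), numeric(1)),
    seq = get_chr("seq"), qual = get_chr("qual"),
    flag = get_int("flag"), rnext = get_chr("rnext"),
    pnext = get_int("pnext"), tlen = get_int("tlen")))
}

#' Align a single read
#'
#' Runs the Gotoh alignment on every candidate window; the best score wins.
#' Mapping quality is the heuristic `min(60, 2 * (best - second_best))`
#' (second best 0 when absent); it is a separation measure, not a
#' probability. Reads without candidates, or whose best score falls below
#' `min_score_frac * match * read_length`, are returned unmapped.
#'
#' @param read single-row read table.
#' @param ref reference genome.
#' @param index `hash_index` built from `ref`.
#' @param cfg an [align_config()].
#' @return one-row alignment record data.frame.
#' @export
align_read <- function(read, ref, index, cfg = align_config()) {
  as.data.frame(align_read_core(read, ref, index, cfg),
                stringsAsFactors = FALSE)
}

align_read_core <- function(read, ref, index, cfg) {
  cands <- align_candidates(read$sequence, ref, index, cfg)
  min_score <- cfg$min_score_frac * cfg$scoring$match * nchar(read$sequence)
  if (nrow(cands) == 0 || cands$score[1] < min_score) {
    return(unmapped_record(read))
  }
  record_from_alignment(read, lapply(cands, `[`, 1L),
                        mapq_from_scores(cands$score))
}

#' Align a read pair with joint proper-pair scoring
#'
#' Candidate placements of the two mates are scored jointly: placements on
#' the same contig, opposite strands, with an insert size within
#' `[insert_min, insert_max]` are preferred by summed score and flagged as
#' a proper pair; otherwise each mate keeps its best independent placement.
#'
#' @param r1,r2 single-row read tables (mates).
#' @inheritParams align_read
#' @return list with `r1`, `r2` (alignment records) and `proper` (logical).
#' @export
align_pair <- function(r1, r2, ref, index, cfg = align_config()) {
  p <- align_pair_core(r1, r2, ref, index, cfg)
  list(r1 = as.data.frame(p$r1, stringsAsFactors = FALSE),
       r2 = as.data.frame(p$r2, stringsAsFactors = FALSE),
       proper = p$proper)
}

align_pair_core <- function(r1, r2, ref, index, cfg) {
  c1 <- align_candidates(r1$sequence, ref, index, cfg)
  c2 <- align_candidates(r2$sequence, ref, index, cfg)
  ms1 <- cfg$min_score_frac * cfg$scoring$match * nchar(r1$sequence)
  ms2 <- cfg$min_score_frac * cfg$scoring$match * nchar(r2$sequence)
  c1 <- c1[c1$score >= ms1, , drop = FALSE]
  c2 <- c2[c2$score >= ms2, , drop = FALSE]

  best_pair <- NULL
  if (nrow(c1) > 0 && nrow(c2) > 0) {
    end1 <- c1$pos + vapply(c1$cigar, cigar_ref_len, integer(1),
                            USE.NAMES = FALSE)
    end2 <- c2$pos + vapply(c2$cigar, cigar_ref_len, integer(1),
                            USE.NAMES = FALSE)
    for (i in seq_len(nrow(c1))) for (j in seq_len(nrow(c2))) {
      if (c1$contig[i] != c2$contig[j]) next
      if (c1$strand[i] == c2$strand[j]) next
      ins <- max(end1[i], end2[j]) - min(c1$pos[i], c2$pos[j])
      if (ins < cfg$insert_min || ins > cfg$insert_max) next
      s <- c1$score[i] + c2$score[j]
      if (is.null(best_pair) || s > best_pair$s) {
        best_pair <- list(i = i, j = j, s = s)
      }
    }
  }
  if (!is.null(best_pair)) {
    a1 <- record_from_alignment(r1, lapply(c1, `[`, best_pair$i),
                                mapq_from_scores(c1$score))
    a2 <- record_from_alignment(r2, lapply(c2, `[`, best_pair$j),
                                mapq_from_scores(c2$score))
    return(list(r1 = a1, r2 = a2, proper = TRUE))
  }
  a1 <- if (nrow(c1) > 0) {
    record_from_alignment(r1, lapply(c1, `[`, 1L), mapq_from_scores(c1$score))
  } else unmapped_record(r1)
  a2 <- if (nrow(c2) > 0) {
    record_from_alignment(r2, lapply(c2, `[`, 1L), mapq_from_scores(c2$score))
  } else unmapped_record(r2)
  list(r1 = a1, r2 = a2, proper = FALSE)
}

# assemble SAM fields for a (possibly paired) record set
sam_lines <- function(recs) {
  pos1 <- ifelse(recs$mapped, recs$pos + 1L, 0L)
  rname <- ifelse(recs$mapped, recs$contig, "*")
  cig <- ifelse(recs$mapped, recs$cigar, "*")
  paste(recs$qname, recs$flag, rname, pos1, recs$mapq, cig,
        recs$rnext, recs$pnext, recs$tlen, recs$seq, recs$qual, sep = "\t")
}

flag_of <- function(mapped, strand, paired = FALSE, proper = FALSE,
                    mate_mapped = TRUE, mate_strand = "+", first = TRUE) {
  f <- 0L
  if (paired) {
    f <- f + 1L
    if (proper) f <- f + 2L
    if (!mate_mapped) f <- f + 8L
    if (mate_mapped && mate_strand == "-") f <- f + 32L
    f <- f + if (first) 64L else 128L
  }
  if (!mapped) f <- f + 4L
  if (mapped && strand == "-") f <- f + 16L
  f
}

finish_single <- function(rec) {
  rec$flag <- flag_of(rec$mapped, rec$strand)
  rec$rnext <- "*"; rec$pnext <- 0L; rec$tlen <- 0L
  rec
}

finish_pair <- function(p) {
  a <- p$r1; b <- p$r2
  a$flag <- flag_of(a$mapped, a$strand, paired = TRUE, proper = p$proper,
                    mate_mapped = b$mapped, mate_strand = b$strand,
                    first = TRUE)
  b$flag <- flag_of(b$mapped, b$strand, paired = TRUE, proper = p$proper,
                    mate_mapped = a$mapped, mate_strand = a$strand,
                    first = FALSE)
  a$rnext <- if (b$mapped) b$contig else "*"
  b$rnext <- if (a$mapped) a$contig else "*"
  a$pnext <- if (b$mapped) b$pos + 1L else 0L
  b$pnext <- if (a$mapped) a$pos + 1L else 0L
  a$tlen <- 0L; b$tlen <- 0L
  if (a$mapped && b$mapped && a$contig == b$contig) {
    ea <- a$pos + cigar_ref_len(a$cigar)
    eb <- b$pos + cigar_ref_len(b$cigar)
    ins <- max(ea, eb) - min(a$pos, b$pos)
    if (a$pos <= b$pos) { a$tlen <- ins; b$tlen <- -ins }
    else { a$tlen <- -ins; b$tlen <- ins }
  }
  list(a, b)
}

#' Align a read set and write a sorted, indexed BAM
#'
#' Reads are processed in fixed-size chunks whose results are combined in
#' input order, so the output is identical for any worker count. Supply
#' `reads2` for paired-end data (row i of `reads` and `reads2` are mates).
#'
#' @param reads read table (mate 1 for paired data).
#' @param ref reference genome.
#' @param output output BAM path (".bam" appended if missing).
#' @param cfg an [align_config()].
#' @param reads2 optional mate-2 read table.
#' @param n_workers chunk workers (via parallel::mclapply); results are
#'   order-stable by construction.
#' @return list with `bam` (path) and `stats` (class `align_stats`).
#' @export
align_all <- function(reads, ref, output, cfg = align_config(),
                      reads2 = NULL, n_workers = 1L) {
  ref <- as_reference(ref)
  index <- build_index(ref, cfg$k, cfg$max_hits)
  paired <- !is.null(reads2)
  if (paired) stopifnot(nrow(reads) == nrow(reads2))
  n <- nrow(reads)
  chunks <- if (n > 0) split(seq_len(n),
                             ceiling(seq_len(n) / cfg$chunk_size))
            else list()
  worker <- function(idx) {
    recs <- vector("list", length(idx) * (if (paired) 2L else 1L))
    for (q in seq_along(idx)) {
      i <- idx[[q]]
      if (paired) {
        p <- finish_pair(align_pair_core(reads[i, ], reads2[i, ], ref,
                                         index, cfg))
        recs[[2L * q - 1L]] <- p[[1]]
        recs[[2L * q]] <- p[[2]]
      } else {
        recs[[q]] <- finish_single(align_read_core(reads[i, ], ref, index,
                                                   cfg))
      }
    }
    assemble_records(recs)
  }
  res <- if (length(chunks) == 0) {
    list()
  } else if (n_workers > 1L) {
    parallel::mclapply(chunks, worker, mc.cores = n_workers)
  } else {
    lapply(chunks, worker)
  }
  recs <- if (length(res)) do.call(rbind, res) else NULL

  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", names(ref), "\tLN:", nchar(ref)))
  body <- character(0)
  stats <- list(total = if (is.null(recs)) 0L else nrow(recs),
                mapped = 0L, unmapped = 0L, proper_pairs = 0L,
                per_contig = setNames(integer(length(ref)), names(ref)))
  if (!is.null(recs)) {
    ci <- match(recs$contig, names(ref))
    ord <- order(!recs$mapped, ci, recs$pos, recs$qname, recs$flag)
    recs <- recs[ord, , drop = FALSE]
    body <- sam_lines(recs)
    stats$mapped <- sum(recs$mapped)
    stats$unmapped <- sum(!recs$mapped)
    stats$proper_pairs <- sum(bitwAnd(recs$flag, 2L) > 0)
    tc <- table(factor(recs$contig[recs$mapped], levels = names(ref)))
    stats$per_contig <- setNames(as.integer(tc), names(ref))
  }
  class(stats) <- "align_stats"

  if (!grepl("\\.bam$", output)) output <- paste0(output, ".bam")
  samfile <- sub("\\.bam$", ".sam", output)
  writeLines(c(header, body), samfile)
  dest <- sub("\\.bam$", "", output)
  bam <- Rsamtools::asBam(samfile, destination = dest, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(samfile)
  list(bam = bam, stats = stats)
}

#' @export
print.align_stats <- function(x, ...) {
  cat("alignment: ", x$mapped, " mapped, ", x$unmapped, " unmapped, ",
      x$proper_pairs, " proper-pair records\n", sep = "")
  for (ct in names(x$per_contig)) {
    cat("  ", ct, ": ", x$per_contig[[ct]], "\n", sep = "")
  }
  invisible(x)
}
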