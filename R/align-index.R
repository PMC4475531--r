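# align (indexing): hash-based k-mer reference index and diagonal-voting
# candidate position selection for the seed-and-extend aligner.

#' Build a hash k-mer index over a reference genome
#'
#' Every k-mer occurrence in the reference is recorded as (contig, offset).
#' K-mers containing N are skipped; k-mers occurring more than `max_hits`
#' times are masked (treated as absent) so repeats do not flood the seeding
#' stage.
#'
#' @param ref reference genome (named character vector).
#' @param k seed length, 8..15.
#' @param max_hits repeat-masking threshold.
#' @return object of class `hash_index`.
#' @export
build_index <- function(ref, k = 11L, max_hits = 64L) {
  stopifnot(k >= 8L, k <= 15L)
  ref <- as_reference(ref)
  kmers <- character(0); contig_i <- integer(0); offs <- integer(0)
  for (ci in seq_along(ref)) {
    n <- nchar(ref[[ci]])
    if (n < k) {
      warning("contig ", names(ref)[ci], " shorter than k = ", k,
              "; skipped", call. = FALSE)
      next
    }
    km <- substring(ref[[ci]], 1:(n - k + 1L), k:n)
    ok <- !grepl("N", km, fixed = TRUE)
    kmers <- c(kmers, km[ok])
    contig_i <- c(contig_i, rep.int(ci, sum(ok)))
    offs <- c(offs, which(ok) - 1L)
  }
  env <- new.env(hash = TRUE, parent = emptyenv(),
                 size = max(29L, length(kmers)))
  if (length(kmers)) {
    grp <- split(seq_along(kmers), kmers)
    for (km in names(grp)) {
      idx <- grp[[km]]
      if (length(idx) > max_hits) next  # masked
      o <- order(contig_i[idx], offs[idx])
      assign(km, cbind(contig = contig_i[idx][o], offset = offs[idx][o]),
             envir = env)
    }
  }
  structure(list(k = as.integer(k), max_hits = as.integer(max_hits),
                 contigs = names(ref), contig_lengths = nchar(ref),
                 env = env),
            class = "hash_index")
}

#' Look up one k-mer in the index
#' @param index a `hash_index`.
#' @param kmer character scalar of length `index$k`.
#' @return integer matrix with columns contig (index) and offset (0-based),
#'   or NULL if absent/masked.
#' @export
index_lookup <- function(index, kmer) {
  get0(kmer, envir = index$env, ifnotfound = NULL)
}

#' Candidate alignment positions by diagonal voting
#'
#' Every non-masked k-mer of the read (and of its reverse complement) is
#' looked up; each hit votes for the diagonal `reference_offset -
#' read_offset`. Votes are binned into diagonal bands of width `band`;
#' bands with at least `min_seed_hits` votes become candidate windows,
#' ranked by vote count (ties: contig order, lower offset, then + strand)
#' and truncated to `max_candidates`.
#'
#' @param read_seq read sequence (character scalar).
#' @param index a `hash_index`.
#' @param min_seed_hits minimum votes for a band.
#' @param band diagonal band width.
#' @param max_candidates cap on returned candidates.
#' @param rc optional precomputed reverse complement of `read_seq`.
#' @return data.frame: contig, strand, seed_count, band_start, window_start,
#'   window_end (0-based half-open window on the contig).
#' @export
candidate_positions <- function(read_seq, index, min_seed_hits = 2L,
                                band = 16L, max_candidates = 32L,
                                rc = NULL) {
  k <- index$k
  L <- nchar(read_seq)
  empty <- data.frame(contig = character(0), strand = character(0),
                      seed_count = integer(0), band_start = integer(0),
                      window_start = integer(0), window_end = integer(0),
                      stringsAsFactors = FALSE)
  if (L < k) return(empty)
  a_ci <- integer(0); a_bin <- integer(0); a_n <- integer(0)
  a_strand <- character(0)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") read_seq else (rc %||% revcomp(read_seq))
    km <- substring(s, 1:(L - k + 1L), k:L)
    hits <- mget(km, envir = index$env, ifnotfound = list(NULL))
    nh <- vapply(hits, function(h) if (is.null(h)) 0L else nrow(h),
                 integer(1))
    if (sum(nh) == 0) next
    m <- do.call(rbind, hits[nh > 0])
    read_off <- rep.int(which(nh > 0) - 1L, nh[nh > 0])
    bin <- as.integer(floor((m[, "offset"] - read_off) / band))
    key <- m[, "contig"] * 1e9 + bin + 5e8  # contig/bin packed; bin >= -5e8
    cnt <- table(key)
    keyv <- as.numeric(names(cnt))
    a_ci <- c(a_ci, as.integer(keyv %/% 1e9))
    a_bin <- c(a_bin, as.integer(keyv %% 1e9 - 5e8))
    a_n <- c(a_n, as.integer(cnt))
    a_strand <- c(a_strand, rep.int(strand, length(cnt)))
  }
  if (length(a_n) == 0) return(empty)
  sel <- a_n >= min_seed_hits
  if (!any(sel)) return(empty)
  d <- quick_df(list(contig_i = a_ci[sel], bin = a_bin[sel],
                     strand = a_strand[sel], seed_count = a_n[sel]))
  d <- d[order(-d$seed_count, d$contig_i, d$bin * band,
               d$strand != "+"), , drop = FALSE]
  d <- head(d, max_candidates)
  clen <- index$contig_lengths[d$contig_i]
  band_start <- d$bin * as.integer(band)
  quick_df(list(contig = index$contigs[d$contig_i], strand = d$strand,
                seed_count = d$seed_count, band_start = band_start,
                window_start = pmax(0L, band_start - as.integer(band)),
                window_end = as.integer(pmin(clen, band_start +
                                               as.integer(band) + L +
                                               as.integer(band)))))
}
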