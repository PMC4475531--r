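# readqc: raw-read statistics, filtering, trimming, adapter removal and
# barcode demultiplexing.

#' Raw-read quality statistics
#'
#' Computes the distributions a sequencing QC review needs: read length,
#' per-read mean quality (arithmetic mean of Phred scores, rounded),
#' GC-content (percent of non-N bases, 1%-wide bins, floor; all-N reads in
#' bin 0), per-position base composition and mean quality, and k-mer counts
#' over the first/last `W` bases with observed/expected enrichment under the
#' read-set base composition.
#'
#' @param reads read table.
#' @param k k-mer size for the start/end windows.
#' @param W window width at each read end; `k <= W`.
#' @return object of class `read_stats`.
#' @export
compute_read_stats <- function(reads, k = 5L, W = 10L) {
  stopifnot(k >= 1L, k <= W)
  n <- nrow(reads)
  empty_named_int <- setNames(integer(0), character(0))
  if (n == 0) {
    out <- list(n_reads = 0L, length_histogram = empty_named_int,
                mean_quality_histogram = empty_named_int,
                gc_histogram = empty_named_int,
                per_position_base_counts = matrix(0L, 0, 5,
                  dimnames = list(NULL, c("A", "C", "G", "T", "N"))),
                per_position_quality_mean = numeric(0),
                kmer_counts_start = empty_named_int,
                kmer_counts_end = empty_named_int,
                kmer_enrichment_start = numeric(0),
                kmer_enrichment_end = numeric(0), k = k, W = W)
    class(out) <- "read_stats"
    return(out)
  }
  lens <- nchar(reads$sequence)
  tab <- function(x) {
    t <- table(x)
    setNames(as.integer(t), names(t))
  }
  mean_q <- vapply(reads$quality,
                   function(q) round(mean(phred_decode(q))), numeric(1),
                   USE.NAMES = FALSE)
  n_gc <- nchar(gsub("[^GC]", "", reads$sequence))
  n_nonN <- nchar(gsub("N", "", reads$sequence))
  gc_bin <- ifelse(n_nonN == 0, 0L, as.integer(floor(100 * n_gc / n_nonN)))

  maxlen <- max(lens)
  bases <- c("A", "C", "G", "T", "N")
  base_counts <- matrix(0L, nrow = maxlen, ncol = 5,
                        dimnames = list(NULL, bases))
  qual_mean <- numeric(maxlen)
  for (p in seq_len(maxlen)) {
    here <- lens >= p
    ch <- substr(reads$sequence[here], p, p)
    base_counts[p, ] <- as.integer(table(factor(ch, levels = bases)))
    qv <- utf8ToInt(paste(substr(reads$quality[here], p, p),
                          collapse = "")) - 33L
    qual_mean[p] <- mean(qv)
  }

  window_kmers <- function(win) {
    wl <- nchar(win)
    out <- character(0)
    for (off in seq_len(W - k + 1L)) {
      ok <- wl >= off + k - 1L
      out <- c(out, substr(win[ok], off, off + k - 1L))
    }
    out[!grepl("N", out, fixed = TRUE)]
  }
  start_k <- window_kmers(substr(reads$sequence, 1L, W))
  end_k <- window_kmers(substr(reads$sequence,
                               pmax(1L, lens - W + 1L), lens))

  # observed/expected under the overall base composition
  base_tot <- colSums(base_counts)[c("A", "C", "G", "T")]
  base_p <- if (sum(base_tot) > 0) base_tot / sum(base_tot)
            else setNames(rep(0.25, 4), c("A", "C", "G", "T"))
  enrich <- function(counts) {
    if (length(counts) == 0) return(numeric(0))
    expp <- vapply(names(counts), function(km) {
      prod(base_p[strsplit(km, "")[[1]]])
    }, numeric(1))
    obs <- counts / sum(counts)
    obs / expp
  }
  sk <- tab(start_k); ek <- tab(end_k)

  out <- list(n_reads = n, length_histogram = tab(lens),
              mean_quality_histogram = tab(mean_q), gc_histogram = tab(gc_bin),
              per_position_base_counts = base_counts,
              per_position_quality_mean = qual_mean,
              kmer_counts_start = sk, kmer_counts_end = ek,
              kmer_enrichment_start = enrich(sk),
              kmer_enrichment_end = enrich(ek), k = k, W = W)
  class(out) <- "read_stats"
  out
}

#' @export
print.read_stats <- function(x, ...) {
  cat("read_stats:", x$n_reads, "reads\n")
  if (x$n_reads > 0) {
    cat("  length range:", paste(range(as.integer(names(x$length_histogram))),
                                 collapse = "-"), "\n")
    cat("  mean quality bins:",
        paste(names(x$mean_quality_histogram), collapse = ","), "\n")
  }
  invisible(x)
}

#' Read filtering / trimming configuration
#'
#' @param min_length,max_length optional length bounds applied after
#'   trimming.
#' @param min_mean_quality optional minimum arithmetic-mean Phred score.
#' @param trim5,trim3 fixed number of bases removed from the 5'/3' ends.
#' @param max_read_length optional cap; excess 3' bases are truncated.
#' @param adapters character vector of 3' adapter sequences.
#' @param adapter_min_overlap minimum read-suffix/adapter-prefix overlap.
#' @param adapter_max_mismatch_rate maximum mismatch fraction in the overlap.
#' @return object of class `read_filter_config`.
#' @export
read_filter_config <- function(min_length = NULL, max_length = NULL,
                               min_mean_quality = NULL, trim5 = 0L,
                               trim3 = 0L, max_read_length = NULL,
                               adapters = character(0),
                               adapter_min_overlap = 8L,
                               adapter_max_mismatch_rate = 0.1) {
  if (!is.null(min_length) && !is.null(max_length) &&
      min_length > max_length) {
    stop("min_length must be <= max_length")
  }
  stopifnot(trim5 >= 0, trim3 >= 0, adapter_min_overlap >= 1,
            adapter_max_mismatch_rate >= 0, adapter_max_mismatch_rate < 1)
  if (length(adapters)) validate_dna(toupper(adapters), "adapter")
  structure(list(min_length = min_length, max_length = max_length,
                 min_mean_quality = min_mean_quality, trim5 = as.integer(trim5),
                 trim3 = as.integer(trim3), max_read_length = max_read_length,
                 adapters = toupper(adapters),
                 adapter_min_overlap = as.integer(adapter_min_overlap),
                 adapter_max_mismatch_rate = adapter_max_mismatch_rate),
            class = "read_filter_config")
}

# best (longest) suffix-of-read / prefix-of-adapter overlap, anchored at
# the read's 3' end; returns the 1-based read position where trimming
# starts, or NA
adapter_trim_start <- function(seq, adapter, min_overlap, max_rate) {
  len <- nchar(seq); alen <- nchar(adapter)
  if (len < min_overlap || alen < min_overlap) return(NA_integer_)
  for (s in max(1L, len - alen + 1L):(len - min_overlap + 1L)) {
    ov <- len - s + 1L           # suffix must be a prefix of the adapter
    if (ov < min_overlap) break
    mism <- hamming(substr(seq, s, len), substr(adapter, 1L, ov))
    if (mism <= ov * max_rate) return(s)
  }
  NA_integer_
}

#' Process one read through the trimming/filter chain
#'
#' Fixed order: (1) 5' trim, (2) 3' adapter removal, (3) 3' trim,
#' (4) truncation to `max_read_length`, (5) length and mean-quality gates.
#' Qualities are trimmed in lockstep with bases. Rejection returns the first
#' failing rule.
#'
#' @param read single-row read table (or list with sequence/quality).
#' @param cfg a [read_filter_config()].
#' @return list with elements `rejected` (logical), and either `read`
#'   (processed single-row table) or `reason`.
#' @export
process_read <- function(read, cfg) {
  seq <- read$sequence; qual <- read$quality
  if (cfg$trim5 > 0L) {
    seq <- substr(seq, cfg$trim5 + 1L, nchar(seq))
    qual <- substr(qual, cfg$trim5 + 1L, nchar(qual))
  }
  for (ad in cfg$adapters) {
    s <- adapter_trim_start(seq, ad, cfg$adapter_min_overlap,
                            cfg$adapter_max_mismatch_rate)
    if (!is.na(s)) {
      seq <- substr(seq, 1L, s - 1L)
      qual <- substr(qual, 1L, s - 1L)
    }
  }
  if (cfg$trim3 > 0L) {
    keep <- max(0L, nchar(seq) - cfg$trim3)
    seq <- substr(seq, 1L, keep); qual <- substr(qual, 1L, keep)
  }
  if (!is.null(cfg$max_read_length) && nchar(seq) > cfg$max_read_length) {
    seq <- substr(seq, 1L, cfg$max_read_length)
    qual <- substr(qual, 1L, cfg$max_read_length)
  }
  if (!is.null(cfg$min_length) && nchar(seq) < cfg$min_length) {
    return(list(rejected = TRUE, reason = "min_length"))
  }
  if (!is.null(cfg$max_length) && nchar(seq) > cfg$max_length) {
    return(list(rejected = TRUE, reason = "max_length"))
  }
  if (!is.null(cfg$min_mean_quality)) {
    mq <- if (nchar(qual)) mean(phred_decode(qual)) else 0
    if (mq < cfg$min_mean_quality) {
      return(list(rejected = TRUE, reason = "min_mean_quality"))
    }
  }
  out <- read
  out$sequence <- seq
  out$quality <- qual
  list(rejected = FALSE, read = out)
}

#' Filter a read set
#'
#' Applies [process_read()] to every read; the kept reads plus the
#' per-reason rejection counts partition the input.
#'
#' @param reads read table.
#' @param cfg a [read_filter_config()].
#' @return list with `kept` (read table) and `summary` (named integer
#'   vector of rejection counts).
#' @export
filter_reads <- function(reads, cfg) {
  keep <- logical(nrow(reads))
  seqs <- character(nrow(reads)); quals <- character(nrow(reads))
  reasons <- character(0)
  for (i in seq_len(nrow(reads))) {
    r <- process_read(reads[i, ], cfg)
    if (r$rejected) {
      reasons <- c(reasons, r$reason)
    } else {
      keep[i] <- TRUE
      seqs[i] <- r$read$sequence
      quals[i] <- r$read$quality
    }
  }
  kept <- reads[keep, , drop = FALSE]
  kept$sequence <- seqs[keep]
  kept$quality <- quals[keep]
  rownames(kept) <- NULL
  summary <- if (length(reasons)) {
    t <- table(reasons)
    setNames(as.integer(t), names(t))
  } else setNames(integer(0), character(0))
  list(kept = kept, summary = summary)
}

#' Demultiplex reads by inline 5' barcodes
#'
#' Barcodes must be equal length and pairwise Hamming distance greater than
#' `2 * max_mismatches` so every assignment is unambiguous. The matched
#' barcode bases and their qualities are removed from assigned reads.
#'
#' @param reads read table.
#' @param barcodes named character vector: sample name -> barcode sequence.
#' @param max_mismatches maximum Hamming distance to accept a barcode.
#' @return named list of read tables, one per sample plus `unassigned`.
#' @export
demultiplex <- function(reads, barcodes, max_mismatches = 0L) {
  if (is.null(names(barcodes)) || any(!nzchar(names(barcodes)))) {
    stop("barcodes must be a named vector (sample -> barcode)")
  }
  barcodes <- toupper(barcodes)
  L <- unique(nchar(barcodes))
  if (length(L) != 1) stop("all barcodes must have the same length")
  if (length(barcodes) > 1) {
    for (i in seq_along(barcodes)) for (j in seq_len(i - 1L)) {
      if (hamming(barcodes[i], barcodes[j]) <= 2L * max_mismatches) {
        stop(sprintf(
          "barcodes %s and %s are closer than 2*max_mismatches apart",
          barcodes[j], barcodes[i]))
      }
    }
  }
  prefix <- substr(reads$sequence, 1L, L)
  long_enough <- nchar(reads$sequence) >= L
  dist <- sapply(barcodes, function(bc) {
    d <- integer(nrow(reads))
    for (p in seq_len(L)) {
      d <- d + (substr(prefix, p, p) != substr(bc, p, p))
    }
    d
  })
  dist <- matrix(dist, nrow = nrow(reads))
  assigned <- rep(NA_integer_, nrow(reads))
  if (nrow(reads) > 0 && length(barcodes) > 0) {
    hit <- dist <= max_mismatches
    nhit <- rowSums(hit)
    one <- which(long_enough & nhit == 1)
    assigned[one] <- apply(hit[one, , drop = FALSE], 1, which)
  }
  out <- list()
  for (si in seq_along(barcodes)) {
    sname <- names(barcodes)[si]
    idx <- which(!is.na(assigned) & assigned == si)
    sub <- reads[idx, , drop = FALSE]
    sub$sequence <- substr(sub$sequence, L + 1L, nchar(sub$sequence))
    sub$quality <- substr(sub$quality, L + 1L, nchar(sub$quality))
    sub$sample <- rep_len(sname, nrow(sub))
    rownames(sub) <- NULL
    out[[sname]] <- sub
  }
  un <- reads[is.na(assigned), , drop = FALSE]
  rownames(un) <- NULL
  out[["unassigned"]] <- un
  out
}
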