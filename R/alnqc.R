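# alnqc: post-alignment quality control and region-of-interest coverage.

#' Summarise a coordinate-sorted, indexed BAM
#'
#' @param bam BAM path (index `.bam.bai` required).
#' @return `align_stats`: mapped, unmapped, proper_pairs, per_contig counts.
#' @export
alignment_summary <- function(bam) {
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    stop("BAM index not found; run Rsamtools::indexBam('", bam, "') first")
  }
  idx <- Rsamtools::idxstatsBam(bam)
  contigs <- as.character(idx$seqnames[idx$seqnames != "*"])
  per_contig <- setNames(as.integer(idx$mapped[idx$seqnames != "*"]),
                         contigs)
  unmapped <- sum(idx$unmapped)
  proper <- Rsamtools::countBam(bam, param = Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE)))$records
  stats <- list(total = sum(per_contig) + unmapped,
                mapped = sum(per_contig), unmapped = unmapped,
                proper_pairs = proper, per_contig = per_contig)
  class(stats) <- "align_stats"
  stats
}

#' Depth of coverage over regions of interest
#'
#' Depth at a base counts reads whose aligned span (CIGAR M and D
#' operations) covers it: a deleted base was still interrogated by the
#' read, which is the diagnostically relevant notion. Secondary and
#' duplicate records are excluded.
#'
#' @param bam indexed BAM path.
#' @param regions data.frame of regions (contig, start, end, label;
#'   0-based half-open) as from [read_regions()].
#' @param thresholds integer depths for the fraction-at-threshold columns.
#' @return data.frame with one row per region: mean_depth, min_depth and a
#'   `pct_ge_<t>` column (fraction of bases with depth >= t) per threshold;
#'   regions on unknown contigs carry an `error` message instead of values.
#' @export
region_coverage <- function(bam, regions, thresholds = c(1L, 10L, 20L, 30L)) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  out <- regions
  out$mean_depth <- NA_real_
  out$min_depth <- NA_integer_
  for (t in thresholds) out[[paste0("pct_ge_", t)]] <- NA_real_
  out$error <- NA_character_
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE)
  for (i in seq_len(nrow(regions))) {
    ct <- regions$contig[i]
    if (!ct %in% names(hdr)) {
      out$error[i] <- paste0("contig not in BAM header: ", ct)
      next
    }
    gr <- GenomicRanges::GRanges(ct, IRanges::IRanges(
      start = regions$start[i] + 1L, end = regions$end[i]))
    param <- Rsamtools::ScanBamParam(which = gr, flag = flags)
    ga <- GenomicAlignments::readGAlignments(bam, param = param)
    cvg <- GenomicAlignments::coverage(ga, drop.D.ranges = FALSE)
    width <- regions$end[i] - regions$start[i]
    depth <- rep.int(0L, width)
    if (ct %in% names(cvg)) {
      rl <- cvg[[ct]]
      lo <- regions$start[i] + 1L
      hi <- min(regions$end[i], length(rl))
      if (hi >= lo) {
        d <- as.integer(S4Vectors::window(rl, lo, hi))
        depth[seq_along(d)] <- d
      }
    }
    out$mean_depth[i] <- mean(depth)
    out$min_depth[i] <- min(depth)
    for (t in thresholds) {
      out[[paste0("pct_ge_", t)]][i] <- mean(depth >= t)
    }
  }
  attr(out, "thresholds") <- thresholds
  out
}

#' Export alignment QC as an archival report
#'
#' JSON reports re-parse to the same values; HTML reports are
#' self-contained with one table row per region.
#'
#' @param stats `align_stats` from [alignment_summary()] or [align_all()].
#' @param coverages data.frame from [region_coverage()].
#' @param path output file.
#' @param format "json" or "html".
#' @return `path`, invisibly.
#' @export
qc_report <- function(stats, coverages, path, format = c("json", "html")) {
  format <- match.arg(format)
  payload <- list(
    schema_version = "1.0",
    alignment = list(total = stats$total, mapped = stats$mapped,
                     unmapped = stats$unmapped,
                     proper_pairs = stats$proper_pairs,
                     per_contig = as.list(stats$per_contig)),
    coverage = coverages)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    writeLines(html_report_page("Alignment QC report", c(
      "<h2>Alignment</h2>",
      sprintf("<p>mapped: %d; unmapped: %d; proper pairs: %d</p>",
              stats$mapped, stats$unmapped, stats$proper_pairs),
      "<h2>Region coverage</h2>",
      html_table(coverages))), path)
  }
  invisible(path)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df) {
  if (nrow(df) == 0) {
    return("<table><tr><td>(empty)</td></tr></table>")
  }
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, format = "g", digits = 6) else as.character(v)
  }
  cells <- vapply(df, function(col) html_escape(fmt(col)),
                  character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  rows <- apply(cells, 1, function(r) {
    paste0("<tr><td>", paste(r, collapse = "</td><td>"), "</td></tr>")
  })
  paste0("<table>\n<tr><th>",
         paste(html_escape(names(df)), collapse = "</th><th>"),
         "</th></tr>\n", paste(rows, collapse = "\n"), "\n</table>")
}

html_report_page <- function(title, body) {
  c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
    paste0("<title>", html_escape(title), "</title>"),
    "<style>table{border-collapse:collapse}td,th{border:1px solid #999;",
    "padding:2px 6px;font:12px sans-serif}</style></head><body>",
    paste0("<h1>", html_escape(title), "</h1>"), body, "</body></html>")
}
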