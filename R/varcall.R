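# varcall: pileup construction and Varscan-2-model SNP/indel calling with
# artifact filters.

#' Variant-caller configuration
#'
#' Defaults mirror the published Varscan 2 model parameters; every gate is
#' exposed.
#'
#' @param min_coverage minimum depth at the site.
#' @param min_alt_reads minimum reads supporting the alternate allele.
#' @param min_avg_base_quality minimum mean base quality of alt-supporting
#'   observations (indel alleles are exempt).
#' @param min_vaf minimum variant allele frequency.
#' @param max_pvalue maximum one-tailed Fisher exact p-value.
#' @param het_vaf_max VAF at or above which a call is homozygous.
#' @param error_rate assumed sequencing error rate of the null model.
#' @param strand_balance_min minimum `min(fwd, rev) / alt_count`.
#' @return object of class `caller_config`.
#' @export
caller_config <- function(min_coverage = 8L, min_alt_reads = 2L,
                          min_avg_base_quality = 15L, min_vaf = 0.01,
                          max_pvalue = 0.01, het_vaf_max = 0.75,
                          error_rate = 0.001, strand_balance_min = 0.1) {
  stopifnot(min_vaf > 0, min_vaf <= 1, het_vaf_max > 0, het_vaf_max < 1,
            error_rate > 0, error_rate < 1)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_alt_reads = as.integer(min_alt_reads),
                 min_avg_base_quality = min_avg_base_quality,
                 min_vaf = min_vaf, max_pvalue = max_pvalue,
                 het_vaf_max = het_vaf_max, error_rate = error_rate,
                 strand_balance_min = strand_balance_min),
            class = "caller_config")
}

#' Build a pileup from an indexed BAM
#'
#' Each reference position covered by at least one primary, non-duplicate
#' read yields observations decoded from the CIGAR: M operations give base
#' observations; I gives a `+SEQ` allele anchored at the preceding
#' reference base; D gives a `-SEQ` allele anchored at the base preceding
#' the deleted run. Overlapping mates both contribute (no fragment
#' de-duplication).
#'
#' @param bam coordinate-sorted, indexed BAM.
#' @param ref reference genome; must contain every contig of the BAM.
#' @param regions optional region data.frame restricting the pileup.
#' @return data.frame: contig, pos (0-based), ref_base, allele, fwd, rev,
#'   qualsum.
#' @export
build_pileup <- function(bam, ref, regions = NULL) {
  ref <- as_reference(ref)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  missing <- setdiff(names(hdr), names(ref))
  if (length(missing)) {
    stop("BAM contig absent from reference: ", missing[1])
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE)
  what <- c("rname", "pos", "strand", "seq", "qual", "cigar")
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref_base = character(0), allele = character(0),
                      fwd = integer(0), rev = integer(0),
                      qualsum = numeric(0), stringsAsFactors = FALSE)
  decode <- function(x) {
    if (length(x$pos) == 0) return(NULL)
    pileup_cpp(match(as.character(x$rname), names(ref)), x$pos - 1L,
               as.character(x$strand) == "-", as.character(x$seq),
               as.character(x$qual), x$cigar, unname(ref))
  }
  if (is.null(regions)) {
    chunk <- Rsamtools::scanBam(
      bam, param = Rsamtools::ScanBamParam(what = what, flag = flags))[[1]]
    parts <- list(decode(chunk))
  } else {
    # merge overlapping regions so no read is decoded twice, then clip each
    # part to its region so reads spanning two regions are not double-counted
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      regions$contig,
      IRanges::IRanges(start = regions$start + 1L, end = regions$end)))
    chunks <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
      what = what, flag = flags, which = gr))
    parts <- lapply(seq_along(chunks), function(i) {
      p <- decode(chunks[[i]])
      if (is.null(p)) return(NULL)
      lo <- GenomicRanges::start(gr)[i] - 1L
      hi <- GenomicRanges::end(gr)[i]
      p[p$pos >= lo & p$pos < hi, , drop = FALSE]
    })
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0) return(empty)
  p <- do.call(rbind, parts)
  out <- data.frame(contig = names(ref)[p$contig_idx], pos = p$pos,
                    ref_base = substr(ref[p$contig_idx], p$pos + 1L,
                                      p$pos + 1L),
                    allele = p$allele, fwd = p$fwd, rev = p$rev,
                    qualsum = p$qualsum, stringsAsFactors = FALSE)
  out[order(match(out$contig, names(ref)), out$pos, out$allele), ,
      drop = FALSE]
}

#' One-tailed Fisher exact p-value for variant support
#'
#' Tests the observed ref/alt read counts against the counts expected under
#' the sequencing-error null: `expected_alt = round(depth * error_rate)`.
#' The p-value is the hypergeometric probability of alternate-allele
#' support at least as large as observed with all margins fixed
#' (Varscan 2 model). Vectorised.
#'
#' @param ref_count,alt_count observed reference/alternate read counts.
#' @param error_rate assumed error rate of the null model.
#' @return p-value(s) in (0, 1].
#' @export
variant_pvalue <- function(ref_count, alt_count, error_rate = 0.001) {
  depth <- ref_count + alt_count
  if (any(depth <= 0)) stop("variant_pvalue undefined at depth 0")
  expected_alt <- round(depth * error_rate)
  total_alt <- alt_count + expected_alt
  total_ref <- ref_count + (depth - expected_alt)
  stats::phyper(alt_count - 1, total_alt, total_ref, depth,
                lower.tail = FALSE)
}

# vectorised gate evaluation over a pileup; returns one row per non-reference
# allele with filter flags and emission fields; indel records are
# left-aligned against `ref` (VCF normalization) when it is supplied
evaluate_alleles <- function(pileup, cfg, ref = NULL) {
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = integer(0), alt_count = integer(0),
                      vaf = numeric(0), fwd = integer(0), rev = integer(0),
                      mean_alt_quality = numeric(0), pvalue = numeric(0),
                      genotype = character(0), filter_flags = character(0),
                      pass = logical(0), stringsAsFactors = FALSE)
  if (nrow(pileup) == 0) return(empty)
  colkey <- paste(pileup$contig, pileup$pos, sep = "\r")
  depth_by_col <- tapply(pileup$fwd + pileup$rev, colkey, sum)
  is_alt <- pileup$allele != pileup$ref_base
  alt <- pileup[is_alt, , drop = FALSE]
  if (nrow(alt) == 0) return(empty)
  depth <- as.integer(depth_by_col[paste(alt$contig, alt$pos, sep = "\r")])
  alt_count <- alt$fwd + alt$rev
  vaf <- alt_count / depth
  meanq <- alt$qualsum / alt_count
  sb <- pmin(alt$fwd, alt$rev) / alt_count
  pv <- variant_pvalue(depth - alt_count, alt_count, cfg$error_rate)
  is_indel <- grepl("^[+-]", alt$allele)

  flags <- character(nrow(alt))
  addflag <- function(flags, bad, name) {
    ifelse(bad, ifelse(nzchar(flags), paste(flags, name, sep = ","), name),
           flags)
  }
  flags <- addflag(flags, depth < cfg$min_coverage, "min_coverage")
  flags <- addflag(flags, alt_count < cfg$min_alt_reads, "min_alt_reads")
  flags <- addflag(flags, !is_indel & meanq < cfg$min_avg_base_quality,
                   "min_avg_base_quality")
  flags <- addflag(flags, vaf < cfg$min_vaf, "min_vaf")
  flags <- addflag(flags, pv > cfg$max_pvalue, "max_pvalue")
  flags <- addflag(flags, sb < cfg$strand_balance_min, "strand_balance")

  # VCF-convention emission (1-based, indels left-anchored)
  ref_out <- alt$ref_base
  alt_out <- alt$allele
  ins <- startsWith(alt$allele, "+")
  del <- startsWith(alt$allele, "-")
  ref_out[ins] <- alt$ref_base[ins]
  alt_out[ins] <- paste0(alt$ref_base[ins], sub("^\\+", "", alt$allele[ins]))
  ref_out[del] <- paste0(alt$ref_base[del], sub("^-", "", alt$allele[del]))
  alt_out[del] <- alt$ref_base[del]
  pos_out <- alt$pos + 1L
  if (!is.null(ref)) {
    for (i in which(ins | del)) {
      la <- left_align_variant(ref[[alt$contig[i]]], pos_out[i],
                               ref_out[i], alt_out[i])
      pos_out[i] <- la$pos; ref_out[i] <- la$ref; alt_out[i] <- la$alt
    }
  }

  data.frame(contig = alt$contig, pos = pos_out, ref = ref_out,
             alt = alt_out, depth = depth, alt_count = alt_count,
             vaf = vaf,
             fwd = alt$fwd, rev = alt$rev, mean_alt_quality = meanq,
             pvalue = pv,
             genotype = ifelse(vaf < cfg$het_vaf_max, "het", "hom"),
             filter_flags = flags, pass = !nzchar(flags),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call variants at one pileup column
#'
#' Applies every configured gate to each non-reference allele of the
#' column. The returned data.frame contains the passing records; the full
#' per-allele evaluation (including failed gates in `filter_flags`) is
#' attached as attribute `"evaluated"`.
#'
#' @param column pileup rows of a single (contig, pos).
#' @param cfg a [caller_config()].
#' @param ref optional reference genome; when given, emitted indels are
#'   left-aligned (VCF normalization).
#' @return data.frame of emitted variant records (possibly 0 rows).
#' @export
call_site <- function(column, cfg = caller_config(), ref = NULL) {
  stopifnot(length(unique(paste(column$contig, column$pos))) <= 1)
  ev <- evaluate_alleles(column, cfg, ref)
  out <- ev[ev$pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "evaluated") <- ev
  out
}

#' Call SNPs and small indels from a BAM
#'
#' Composition of [build_pileup()] and the per-site gates; emitted records
#' follow the VCF convention (1-based positions, indels anchored on the
#' preceding reference base). Multi-allelic sites yield one record per
#' alternate allele.
#'
#' @param bam coordinate-sorted, indexed BAM.
#' @param ref reference genome.
#' @param regions optional region restriction.
#' @param cfg a [caller_config()].
#' @param vcf_path optional path; when given, records are also written as
#'   VCF 4.2.
#' @return data.frame of variant records, sorted by (contig, pos); full
#'   allele evaluations in attribute `"evaluated"`.
#' @export
call_variants <- function(bam, ref, regions = NULL, cfg = caller_config(),
                          vcf_path = NULL) {
  pile <- build_pileup(bam, ref, regions)
  ev <- evaluate_alleles(pile, cfg, ref)
  out <- ev[ev$pass, , drop = FALSE]
  ord <- order(match(out$contig, names(ref)), out$pos, out$alt)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(vcf_path)) write_vcf(out, ref, vcf_path)
  attr(out, "evaluated") <- ev
  out
}

#' Write variant records as VCF 4.2
#'
#' @param records variant records (as from [call_variants()]).
#' @param ref reference genome (for contig header lines).
#' @param path output file.
#' @param sample sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, ref, path, sample = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=diagseq",
           paste0("##contig=<ID=", names(ref), ",length=", nchar(ref), ">"),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
           "##INFO=<ID=PV,Number=1,Type=Float,Description=\"One-tailed Fisher exact p-value\">",
           "##INFO=<ID=SB,Number=2,Type=Integer,Description=\"Alt-supporting forward,reverse reads\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  lines <- hdr
  if (nrow(records) > 0) {
    info <- sprintf("DP=%d;AF=%s;PV=%s;SB=%d,%d", records$depth,
                    formatC(records$vaf, format = "g", digits = 6),
                    formatC(records$pvalue, format = "g", digits = 6),
                    records$fwd, records$rev)
    gt <- ifelse(records$genotype == "hom", "1/1", "0/1")
    smp <- sprintf("%s:%d:%d,%d:%s", gt, records$depth,
                   records$depth - records$alt_count, records$alt_count,
                   formatC(records$vaf, format = "g", digits = 6))
    lines <- c(lines, paste(records$contig, records$pos, ".", records$ref,
                            records$alt, ".", "PASS", info, "GT:DP:AD:AF",
                            smp, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF into the variant-record representation
#'
#' @param path VCF file.
#' @return data.frame with contig, pos, ref, alt plus DP/AF/PV/genotype
#'   columns when present.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty)
  out <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  getinfo <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    suppressWarnings(as.numeric(val))
  }
  out$depth <- as.integer(getinfo("DP"))
  out$vaf <- getinfo("AF")
  out$pvalue <- getinfo("PV")
  gt <- tryCatch(vcfR::extract.gt(v, element = "GT"),
                 error = function(e) NULL)
  if (!is.null(gt)) {
    out$genotype <- ifelse(gt[, 1] == "1/1", "hom", "het")
  }
  out
}
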