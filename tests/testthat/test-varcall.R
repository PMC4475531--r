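# Pileup decoding, the Fisher-exact support test, per-site gates, and
# whole-sample calling against the simulator truth set.

make_mini_bam <- function(sam_body, ref, dir = tempdir()) {
  sam <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", names(ref), "\tLN:", nchar(ref)))
  writeLines(c(header, sam_body), sam)
  bam <- Rsamtools::asBam(sam, destination = tempfile(),
                          overwrite = TRUE, indexDestination = TRUE)
  bam
}

test_that("pileup decodes M, I and D CIGAR operations", {
  ref <- c(c1 = paste0(strrep("A", 10), "ACGT", strrep("A", 10)))
  q <- phred_encode(rep(30L, 4))
  bam <- make_mini_bam(paste("r1", 0, "c1", 11, 60, "4M", "*", 0, 0,
                             "ACGT", q, sep = "\t"), ref)
  p <- build_pileup(bam, ref)
  expect_equal(nrow(p), 4)
  expect_equal(p$pos, 10:13)
  expect_equal(p$allele, c("A", "C", "G", "T"))
  expect_equal(p$fwd, rep(1L, 4))
  expect_equal(p$qualsum, rep(30, 4))

  # 2M1I2M anchors the insertion at the second M position
  bam2 <- make_mini_bam(paste("r2", 16, "c1", 11, 60, "2M1I2M", "*", 0, 0,
                              "ACNGT", phred_encode(rep(30L, 5)),
                              sep = "\t"),
                        ref)
  p2 <- build_pileup(bam2, ref)
  ins <- p2[startsWith(p2$allele, "+"), ]
  expect_equal(ins$pos, 11L)
  expect_equal(ins$allele, "+N")
  expect_equal(ins$rev, 1L)

  # deletion: anchored before the deleted run, allele carries the ref bases
  bam3 <- make_mini_bam(paste("r3", 0, "c1", 11, 60, "2M2D2M", "*", 0, 0,
                              "ACAA", phred_encode(rep(30L, 4)),
                              sep = "\t"), ref)
  p3 <- build_pileup(bam3, ref)
  del <- p3[startsWith(p3$allele, "-"), ]
  expect_equal(del$pos, 11L)
  expect_equal(del$allele, "-GT")
})

test_that("overlapping mates both contribute observations", {
  ref <- c(c1 = strrep("ACGT", 10))
  q <- phred_encode(rep(30L, 8))
  body <- c(paste("m/1", 0, "c1", 1, 60, "8M", "*", 0, 0, "ACGTACGT", q,
                  sep = "\t"),
            paste("m/2", 16, "c1", 1, 60, "8M", "*", 0, 0, "ACGTACGT", q,
                  sep = "\t"))
  p <- build_pileup(make_mini_bam(body, ref), ref)
  expect_equal(p$fwd + p$rev, rep(2L, 8))
})

test_that("variant p-value equals the exhaustive hypergeometric oracle", {
  for (err in c(0.001, 0.01, 0.05)) {
    for (depth in c(1:12, 20, 30)) {
      alt <- 0:depth
      p <- variant_pvalue(depth - alt, alt, err)
      oracle <- vapply(alt, function(a)
        oracle_fisher_tail(depth - a, a, err), numeric(1))
      expect_true(all(abs(p - oracle) <= 1e-9),
                  label = sprintf("depth %d err %g", depth, err))
      # no alternate support is never significant
      expect_equal(p[1], 1.0)
      # non-increasing in alt_count at fixed depth
      expect_true(all(diff(p) <= 1e-12))
    }
  }
  expect_error(variant_pvalue(0, 0), "depth 0")
})

test_that("per-site gates pass a clean het SNP and reject artifacts", {
  # balanced 10 ref / 10 alt at q30: every default gate passes
  col <- data.frame(contig = "c1", pos = 99L, ref_base = "A",
                    allele = c("A", "G"), fwd = c(5L, 5L), rev = c(5L, 5L),
                    qualsum = c(300, 300), stringsAsFactors = FALSE)
  out <- call_site(col, caller_config())
  expect_equal(nrow(out), 1)
  expect_equal(out$alt, "G")
  expect_equal(out$vaf, 0.5)
  expect_equal(out$genotype, "het")
  expect_equal(out$pos, 100L)  # VCF 1-based

  # coverage gate: depth 6 below min_coverage 8
  col6 <- col
  col6$fwd <- c(2L, 1L); col6$rev <- c(1L, 2L)
  col6$qualsum <- c(90, 90)
  expect_equal(nrow(call_site(col6, caller_config())), 0)

  # strand imbalance is rejected and recorded in the filter flags
  sb <- data.frame(contig = "c1", pos = 9L, ref_base = "A",
                   allele = c("A", "T"), fwd = c(10L, 10L),
                   rev = c(10L, 0L), qualsum = c(600, 300),
                   stringsAsFactors = FALSE)
  out_sb <- call_site(sb, caller_config(strand_balance_min = 0.1))
  expect_equal(nrow(out_sb), 0)
  ev <- attr(out_sb, "evaluated")
  expect_match(ev$filter_flags[ev$alt == "T"], "strand_balance")

  # homozygous call above het_vaf_max
  hom <- data.frame(contig = "c1", pos = 9L, ref_base = "A",
                    allele = "C", fwd = 12L, rev = 13L, qualsum = 750,
                    stringsAsFactors = FALSE)
  expect_equal(call_site(hom, caller_config())$genotype, "hom")
})

test_that("raising any caller threshold never increases emitted records", {
  set.seed(31)
  ds <- simulate_dataset(contigs = c(chr1 = 6000L), n_snps = 8,
                         n_indels = 2, coverage = 30, seed = 31,
                         error_rate = 0.01)
  res <- align_all(ds$reads1, ds$ref, output = tmpfile(".bam"),
                   reads2 = ds$reads2)
  pile <- build_pileup(res$bam, ds$ref)
  count_with <- function(...) {
    nrow(diagseq:::evaluate_alleles(pile, caller_config(...), ds$ref) |>
           (\(d) d[d$pass, ])())
  }
  base <- count_with()
  expect_true(count_with(min_coverage = 20) <= base)
  expect_true(count_with(min_alt_reads = 6) <= base)
  expect_true(count_with(min_vaf = 0.3) <= base)
  expect_true(count_with(max_pvalue = 1e-6) <= base)
  expect_true(count_with(min_avg_base_quality = 30) <= base)
  expect_true(count_with(strand_balance_min = 0.4) <= base)

  # every emitted record satisfies every configured gate, re-checked
  cfg <- caller_config()
  calls <- call_variants(res$bam, ds$ref, cfg = cfg)
  expect_true(all(calls$depth >= cfg$min_coverage))
  expect_true(all(calls$alt_count >= cfg$min_alt_reads))
  expect_true(all(calls$vaf >= cfg$min_vaf))
  expect_true(all(calls$pvalue <= cfg$max_pvalue))
  expect_true(all(pmin(calls$fwd, calls$rev) / calls$alt_count >=
                    cfg$strand_balance_min))
})

test_that("calling recovers the implanted truth set and writes valid VCF", {
  ds <- simulate_dataset(contigs = c(chr1 = 12000L), n_snps = 10,
                         n_indels = 3, coverage = 50, seed = 1,
                         error_rate = 0.005)
  res <- align_all(ds$reads1, ds$ref, output = tmpfile(".bam"),
                   reads2 = ds$reads2)
  vcf <- tmpfile(".vcf")
  calls <- call_variants(res$bam, ds$ref, vcf_path = vcf)
  tk <- paste(ds$truth$contig, ds$truth$pos, ds$truth$ref, ds$truth$alt)
  ck <- paste(calls$contig, calls$pos, calls$ref, calls$alt)
  is_snp <- nchar(ds$truth$ref) == 1 & nchar(ds$truth$alt) == 1
  expect_equal(sum(tk[is_snp] %in% ck), sum(is_snp))       # all SNPs
  expect_true(sum(tk[!is_snp] %in% ck) >= sum(!is_snp) - 1) # indels
  expect_true(all(calls$genotype[match(tk, ck)] == "het", na.rm = TRUE))

  # records sorted, and the emitted VCF round-trips through the reader
  expect_false(is.unsorted(calls$pos))
  back <- read_vcf(vcf)
  expect_equal(back$contig, calls$contig)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$depth, calls$depth)
  expect_equal(back$genotype, calls$genotype)
  # and parses under the standard Bioconductor VCF reader
  v <- VariantAnnotation::readVcf(vcf, genome = "synthetic")
  expect_equal(length(v), nrow(calls))
})

test_that("error-free reads from the unmodified reference call nothing", {
  ref <- make_reference(c(chrQ = 5000L), seed = 33)
  sim <- simulate_reads(ref, read_length = 100, coverage = 20,
                        paired = FALSE, error_rate = 0, seed = 33)
  res <- align_all(sim$reads1, ref, output = tmpfile(".bam"))
  calls <- call_variants(res$bam, ref)
  expect_equal(nrow(calls), 0)
})

test_that("homozygous variants are called hom", {
  ds <- simulate_dataset(contigs = c(chr1 = 6000L), n_snps = 5,
                         n_indels = 0, snp_genotype = "hom",
                         coverage = 40, seed = 34, error_rate = 0.002)
  res <- align_all(ds$reads1, ds$ref, output = tmpfile(".bam"),
                   reads2 = ds$reads2)
  calls <- call_variants(res$bam, ds$ref)
  tk <- paste(ds$truth$contig, ds$truth$pos, ds$truth$ref, ds$truth$alt)
  ck <- paste(calls$contig, calls$pos, calls$ref, calls$alt)
  expect_true(all(tk %in% ck))
  expect_true(all(calls$genotype[ck %in% tk] == "hom"))
})
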