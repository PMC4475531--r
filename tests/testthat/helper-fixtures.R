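# Shared fixtures, built in code.

three_read_fixture <- function() {
  new_reads(c("r1", "r2", "r3"),
            c("ACGT", "GGCC", "AT"),
            c(phred_encode(rep(30L, 4)), phred_encode(rep(40L, 4)),
              phred_encode(rep(20L, 2))))
}

# Two-exon plus-strand gene on a 74 bp contig, CDS "ATGTACGGA"+"TCTGGATAA"
# (ATG TAC GGA TCT GGA TAA). Exon1 [10,22), intron [22,52) with canonical
# GT..AG, exon2 [52,64); CDS [13,61).
toy_gene_fixture <- function() {
  intron_mid <- "CACACACACACACACACACACACACA"   # 26 bases
  contig <- paste0("AAAAACCCCC",               # [0,10)
                   "TTT", "ATGTACGGA",         # exon1: utr5 + cds
                   "GT", intron_mid, "AG",     # intron [22,52)
                   "TCTGGATAA", "TTT",         # exon2: cds + utr3
                   "GGGGGAAAAA")               # [64,74)
  stopifnot(nchar(contig) == 74)
  tx <- structure(list(
    transcript_id = "toytx", gene_name = "TOYGENE", contig = "chrT",
    strand = "+", exons = data.frame(start = c(10L, 52L),
                                     end = c(22L, 64L)),
    cds_start = 13L, cds_end = 61L, phenotype_terms = character(0)),
    class = "transcript_model")
  list(ref = c(chrT = contig), tx = tx)
}

# mirror a reference contig and a transcript onto the reverse complement,
# so the same biological gene is represented on the minus strand
mirror_fixture <- function(ref, tx) {
  contig <- ref[[tx$contig]]
  L <- nchar(contig)
  ref2 <- setNames(revcomp(contig), tx$contig)
  ex <- data.frame(start = L - rev(tx$exons$end),
                   end = L - rev(tx$exons$start))
  tx2 <- tx
  tx2$strand <- if (tx$strand == "+") "-" else "+"
  tx2$exons <- ex
  tx2$cds_start <- L - tx$cds_end
  tx2$cds_end <- L - tx$cds_start
  list(ref = ref2, tx = tx2)
}

# mirror a SNV onto the reverse-complemented contig
mirror_snv <- function(variant, L) {
  list(contig = variant$contig, pos = L - variant$pos + 1L,
       ref = revcomp(variant$ref), alt = revcomp(variant$alt))
}

tmpfile <- function(ext) tempfile(fileext = ext)
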