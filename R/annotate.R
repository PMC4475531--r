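# annotate: transcript-level consequence prediction and joining of local
# known-variant / population-frequency / phenotype tables.

#' Consequence terms in decreasing severity
#'
#' Fixed ordering used to pick the worst-overall consequence of a variant.
#' @export
CONSEQUENCE_SEVERITY <- c("stop_gained", "start_lost", "stop_lost",
                          "frameshift", "splice_donor", "splice_acceptor",
                          "missense", "inframe_insertion",
                          "inframe_deletion", "synonymous", "utr",
                          "intronic", "intergenic")

#' Predict the consequence of a variant on one transcript
#'
#' Decision procedure: outside the transcript span -> intergenic; within
#' the two intronic bases flanking an exon boundary (in transcription
#' direction) -> splice_donor / splice_acceptor; deeper intron ->
#' intronic; exonic outside the CDS -> utr; in the CDS an indel is
#' frameshift when its length is not divisible by 3, otherwise
#' inframe_insertion/deletion; a CDS SNV is classified by translating the
#' reference and alternate codons of the spliced CDS (reverse-complemented
#' for minus-strand transcripts) with the standard genetic code.
#'
#' @param variant list or one-row data.frame with contig, pos (1-based),
#'   ref, alt (VCF convention; indels left-anchored).
#' @param tx a transcript model (see [load_gene_model()]).
#' @param ref reference genome.
#' @return list with transcript_id, term, hgvs_like.
#' @export
predict_consequence <- function(variant, tx, ref) {
  stopifnot(variant$contig == tx$contig)
  pos0 <- variant$pos - 1L
  refseq <- ref[[variant$contig]]
  seen <- substr(refseq, variant$pos, variant$pos + nchar(variant$ref) - 1L)
  if (seen != variant$ref) {
    stop(sprintf("variant ref allele %s disagrees with reference %s at %s:%d",
                 variant$ref, seen, variant$contig, variant$pos))
  }
  is_snv <- nchar(variant$ref) == 1L && nchar(variant$alt) == 1L
  # first changed base: for anchored indels the base after the anchor
  e <- if (is_snv) pos0 else pos0 + 1L

  term <- classify_position(e, tx, is_snv, variant, refseq)
  list(transcript_id = tx$transcript_id, term = term,
       hgvs_like = hgvs_like(variant, tx, ref, term))
}

classify_position <- function(e, tx, is_snv, variant, refseq) {
  span_start <- min(tx$exons$start); span_end <- max(tx$exons$end)
  if (e < span_start || e >= span_end) return("intergenic")
  ex <- tx$exons
  # intron membership with 2-base splice windows
  if (nrow(ex) > 1) {
    for (i in seq_len(nrow(ex) - 1L)) {
      s <- ex$end[i]; t <- ex$start[i + 1L]  # intron [s, t)
      if (e >= s && e < t) {
        donor <- if (tx$strand == "+") c(s, s + 1L) else c(t - 2L, t - 1L)
        acceptor <- if (tx$strand == "+") c(t - 2L, t - 1L) else c(s, s + 1L)
        if (e >= donor[1] && e <= donor[2]) return("splice_donor")
        if (e >= acceptor[1] && e <= acceptor[2]) return("splice_acceptor")
        return("intronic")
      }
    }
  }
  # exonic
  if (e < tx$cds_start || e >= tx$cds_end) return("utr")
  if (!is_snv) {
    dlen <- nchar(variant$alt) - nchar(variant$ref)
    if (dlen %% 3L != 0L) return("frameshift")
    return(if (dlen > 0) "inframe_insertion" else "inframe_deletion")
  }
  snv_cds_term(e, tx, variant, refseq)
}

snv_cds_term <- function(e, tx, variant, refseq) {
  map <- cds_position_map(tx)   # genomic positions in transcription order
  idx <- match(e, map)
  if (is.na(idx)) return("intronic")  # inside CDS bounds but intronic gap
  cds <- spliced_cds_seq(tx, setNames(list(refseq), tx$contig))
  ref_b <- variant$ref; alt_b <- variant$alt
  if (tx$strand == "-") {
    ref_b <- revcomp(ref_b); alt_b <- revcomp(alt_b)
  }
  stopifnot(substr(cds, idx, idx) == ref_b)
  codon_i <- (idx - 1L) %/% 3L          # 0-based codon index
  within <- (idx - 1L) %% 3L
  ref_codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  alt_codon <- ref_codon
  substr(alt_codon, within + 1L, within + 1L) <- alt_b
  ref_aa <- codon_aa(ref_codon); alt_aa <- codon_aa(alt_codon)
  if (ref_aa == alt_aa) return("synonymous")
  if (codon_i == 0L && ref_codon == "ATG") return("start_lost")
  if (ref_aa == "*") return("stop_lost")
  if (alt_aa == "*") return("stop_gained")
  "missense"
}

# best-effort c./p.-style string; unvalidated
hgvs_like <- function(variant, tx, ref, term) {
  g <- sprintf("g.%d%s>%s", variant$pos, variant$ref, variant$alt)
  if (!(nchar(variant$ref) == 1 && nchar(variant$alt) == 1)) return(g)
  map <- cds_position_map(tx)
  idx <- match(variant$pos - 1L, map)
  if (is.na(idx)) return(g)
  ref_b <- variant$ref; alt_b <- variant$alt
  if (tx$strand == "-") {
    ref_b <- revcomp(ref_b); alt_b <- revcomp(alt_b)
  }
  cds <- spliced_cds_seq(tx, ref)
  codon_i <- (idx - 1L) %/% 3L
  within <- (idx - 1L) %% 3L
  ref_codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  alt_codon <- ref_codon
  substr(alt_codon, within + 1L, within + 1L) <- alt_b
  sprintf("c.%d%s>%s p.%s%d%s", idx, ref_b, alt_b, codon_aa(ref_codon),
          codon_i + 1L, codon_aa(alt_codon))
}

#' Merge SIFT and PolyPhen predictions by severity
#'
#' When the two tools disagree, the value whose severity rank is highest
#' is displayed; equal ranks report both; two unknowns yield
#' "no prediction".
#'
#' @param sift one of deleterious, tolerated, unknown.
#' @param polyphen one of probably_damaging, possibly_damaging, benign,
#'   unknown.
#' @return character scalar: the displayed prediction.
#' @export
merge_severity <- function(sift, polyphen) {
  sift_rank <- c(deleterious = 1L, tolerated = 2L, unknown = 99L)
  poly_rank <- c(probably_damaging = 1L, possibly_damaging = 2L,
                 benign = 3L, unknown = 99L)
  sift <- if (is.null(sift) || is.na(sift) || !nzchar(sift)) "unknown"
          else sift
  polyphen <- if (is.null(polyphen) || is.na(polyphen) || !nzchar(polyphen))
    "unknown" else polyphen
  rs <- sift_rank[[sift]]; rp <- poly_rank[[polyphen]]
  if (rs == 99L && rp == 99L) return("no prediction")
  if (rs < rp) return(sift)
  if (rp < rs) return(polyphen)
  paste(sift, polyphen, sep = "|")
}

#' Load a local known-variant table
#'
#' Tab-separated with header columns: contig, pos, ref, alt, id,
#' frequency, sift, polyphen, clinsig.
#'
#' @param path TSV file.
#' @return data.frame keyed by (contig, pos, ref, alt).
#' @export
load_known_variants <- function(path) {
  kt <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, quote = "",
                   colClasses = c(pos = "integer"))
  need <- c("contig", "pos", "ref", "alt", "id", "frequency", "sift",
            "polyphen", "clinsig")
  if (!all(need %in% names(kt))) {
    stop("known-variant table must have columns: ",
         paste(need, collapse = ", "))
  }
  if (any(kt$frequency < 0 | kt$frequency > 1, na.rm = TRUE)) {
    stop("population frequencies must lie in [0, 1]")
  }
  key <- paste(kt$contig, kt$pos, kt$ref, kt$alt)
  if (anyDuplicated(key)) stop("duplicate (contig,pos,ref,alt) keys")
  kt
}

#' Load a gene -> phenotype-term table
#'
#' Tab-separated, two columns (gene, term), no header required; HPO-style
#' vocabularies are accepted as plain terms.
#'
#' @param path TSV file.
#' @return named list gene -> character vector of terms.
#' @export
load_phenotypes <- function(path) {
  pt <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, quote = "",
                   col.names = c("gene", "term"))
  if (nrow(pt) > 0 && pt$gene[1] == "gene" && pt$term[1] == "term") {
    pt <- pt[-1, , drop = FALSE]
  }
  split(pt$term, pt$gene)
}

# left-trim shared ref/alt prefix (keeps at least one base each)
normalize_allele <- function(pos, ref, alt) {
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

variant_norm_key <- function(contig, pos, ref, alt) {
  mapply(function(c, p, r, a) {
    n <- normalize_allele(p, r, a)
    paste(c, n$pos, n$ref, n$alt)
  }, contig, pos, ref, alt, USE.NAMES = FALSE)
}

#' Annotate variant records
#'
#' Each variant gains its per-transcript consequence list, the
#' worst-overall consequence under the fixed severity order, known-variant
#' id / population frequency / SIFT / PolyPhen / clinical significance
#' when the normalized (contig,pos,ref,alt) key matches, the merged
#' severity display, and the phenotype terms of affected genes. Core
#' variant fields are never altered.
#'
#' @param variants variant-record data.frame (contig, pos, ref, alt, ...).
#' @param gene_model list of transcript models.
#' @param ref reference genome.
#' @param known_table optional [load_known_variants()] table.
#' @param phenotype_table optional [load_phenotypes()] list.
#' @return `variants` with annotation columns appended; the per-transcript
#'   consequence lists are in attribute `"consequences"`.
#' @export
annotate_variants <- function(variants, gene_model, ref, known_table = NULL,
                              phenotype_table = NULL) {
  n <- nrow(variants)
  worst <- character(n); genes <- character(n); conseq <- character(n)
  details <- vector("list", n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    hits <- list()
    for (tx in gene_model) {
      if (tx$contig != v$contig) next
      cons <- predict_consequence(v, tx, ref)
      if (cons$term == "intergenic") next
      hits[[length(hits) + 1L]] <- cons
    }
    details[[i]] <- hits
    if (length(hits) == 0) {
      worst[i] <- "intergenic"; genes[i] <- ""; conseq[i] <- ""
    } else {
      terms <- vapply(hits, `[[`, character(1), "term")
      worst[i] <- CONSEQUENCE_SEVERITY[min(match(terms,
                                                 CONSEQUENCE_SEVERITY))]
      txids <- vapply(hits, `[[`, character(1), "transcript_id")
      genes[i] <- paste(unique(vapply(txids, function(t)
        gene_model[[t]]$gene_name, character(1))), collapse = ",")
      conseq[i] <- paste(paste0(txids, ":", terms), collapse = ",")
    }
  }
  out <- variants
  out$genes <- genes
  out$consequences <- conseq
  out$worst_consequence <- worst

  out$known_id <- NA_character_
  out$population_frequency <- NA_real_
  out$sift <- NA_character_
  out$polyphen <- NA_character_
  out$clinical_significance <- NA_character_
  if (!is.null(known_table) && nrow(known_table) > 0 && n > 0) {
    vk <- variant_norm_key(out$contig, out$pos, out$ref, out$alt)
    kk <- variant_norm_key(known_table$contig, known_table$pos,
                           known_table$ref, known_table$alt)
    m <- match(vk, kk)
    hit <- !is.na(m)
    out$known_id[hit] <- known_table$id[m[hit]]
    out$population_frequency[hit] <- known_table$frequency[m[hit]]
    out$sift[hit] <- known_table$sift[m[hit]]
    out$polyphen[hit] <- known_table$polyphen[m[hit]]
    out$clinical_significance[hit] <- known_table$clinsig[m[hit]]
  }
  out$prediction_display <- mapply(merge_severity, out$sift, out$polyphen,
                                   USE.NAMES = FALSE)
  out$phenotype_terms <- vapply(seq_len(n), function(i) {
    gs <- strsplit(genes[i], ",", fixed = TRUE)[[1]]
    if (is.null(phenotype_table) || length(gs) == 0) return("")
    paste(unique(unlist(phenotype_table[gs], use.names = FALSE)),
          collapse = ",")
  }, character(1))
  attr(out, "consequences") <- details
  out
}
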