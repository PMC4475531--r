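# seqio: readers/writers for FASTQ/FASTA/BED/GFF and the internal read
# representation. All internal coordinates are 0-based half-open; emitted
# SAM/VCF/GFF positions are 1-based.

#' Construct the internal read table
#'
#' Reads are held in an ordinary data.frame with one row per read and a
#' Phred+33 encoded quality string, so that large read sets stay compact.
#'
#' @param read_id character vector of read identifiers.
#' @param sequence character vector over {A,C,G,T,N}.
#' @param quality character vector, Phred+33, same width as `sequence`.
#' @param mate one of "none", "first", "second" (recycled).
#' @param sample optional sample label (set by [demultiplex()]).
#' @return data.frame with columns read_id, sequence, quality, mate, sample.
#' @export
new_reads <- function(read_id, sequence, quality,
                      mate = "none", sample = NA_character_) {
  sequence <- toupper(sequence)
  validate_dna(sequence, "read sequence")
  if (any(nchar(sequence) != nchar(quality))) {
    stop("quality/sequence length mismatch (record ",
         which(nchar(sequence) != nchar(quality))[1], ")")
  }
  data.frame(read_id = as.character(read_id), sequence = sequence,
             quality = as.character(quality),
             mate = rep_len(mate, length(read_id)),
             sample = rep_len(sample, length(read_id)),
             stringsAsFactors = FALSE)
}

#' Import raw reads from FASTQ or FASTA
#'
#' FASTQ qualities are decoded as Phred+33. FASTA carries no qualities, so
#' every base receives `default_quality` (a neutral "good" call of Q30 by
#' default).
#'
#' @param path input file.
#' @param format "fastq" or "fasta".
#' @param default_quality Phred score assumed for quality-less formats.
#' @return read table as from [new_reads()].
#' @export
read_raw_reads <- function(path, format = c("fastq", "fasta"),
                           default_quality = 30L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    return(new_reads(character(0), character(0), character(0)))
  }
  if (format == "fastq") {
    x <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq",
                                   with.qualities = TRUE),
      error = function(e) stop("malformed FASTQ record in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  } else {
    x <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) stop("malformed FASTA record in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    qual <- vapply(Biostrings::width(x),
                   function(w) phred_encode(rep.int(default_quality, w)),
                   character(1))
  }
  ids <- sub("[ \t].*$", "", names(x))
  new_reads(ids, as.character(x), qual)
}

#' Write reads as Phred+33 FASTQ
#'
#' Round-trips exactly through [read_raw_reads()].
#'
#' @param reads read table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$read_id
  Biostrings::writeXStringSet(dna, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased on load; bases outside {A,C,G,T,N} are rejected.
#'
#' @param path FASTA file.
#' @return named character vector, contig name -> sequence.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  ref <- toupper(as.character(x))
  names(ref) <- sub("[ \t].*$", "", names(x))
  as_reference(ref)
}

# validate a named character vector as a reference genome
as_reference <- function(ref) {
  if (length(ref) == 0) stop("reference has no contigs")
  if (anyNA(names(ref)) || any(!nzchar(names(ref)))) {
    stop("reference contig names must be non-empty")
  }
  if (anyDuplicated(names(ref))) stop("duplicate contig names in reference")
  if (any(!nzchar(ref))) stop("reference contigs must be non-empty")
  ref <- toupper(ref)
  validate_dna(ref, "reference")
  ref
}

#' Write a reference genome to FASTA
#' @param ref named character vector of contigs.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  dna <- Biostrings::DNAStringSet(ref)
  names(dna) <- names(ref)
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}

#' Read regions of interest from BED or GFF
#'
#' BED is 0-based half-open and used as is; GFF intervals are 1-based
#' inclusive and converted on read. Internally all intervals are 0-based
#' half-open.
#'
#' @param path input file.
#' @param format "bed" or "gff".
#' @return data.frame with columns contig, start, end, label.
#' @export
read_regions <- function(path, format = c("bed", "gff")) {
  format <- match.arg(format)
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      stringsAsFactors = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty)
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED"
                                           else "GFF")
  if (length(gr) == 0) return(empty)
  lab <- if (!is.null(gr$name)) as.character(gr$name)
         else if (!is.null(gr$ID)) as.character(gr$ID)
         else NA_character_
  out <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    label = lab, stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) {
    stop("region with start >= end after coordinate conversion in ", path)
  }
  out
}

#' Region constructor (0-based half-open)
#' @param contig contig name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param label optional label.
#' @return data.frame of regions.
#' @export
region <- function(contig, start, end, label = NA_character_) {
  if (any(start < 0) || any(start >= end)) stop("require 0 <= start < end")
  data.frame(contig = contig, start = as.integer(start),
             end = as.integer(end), label = label, stringsAsFactors = FALSE)
}

#' Load a transcript gene model from GFF3
#'
#' Expects gene / mRNA (or transcript) / exon / CDS features linked with
#' ID/Parent attributes. Transcripts violating the model invariants
#' (sorted non-overlapping exons, CDS contained in the exon span, spliced
#' CDS length divisible by 3) are skipped with a warning.
#'
#' @param gff_path GFF3 file.
#' @return list of transcript models; each a list with transcript_id,
#'   gene_name, contig, strand, exons (data.frame start/end, 0-based
#'   half-open), cds_start, cds_end, phenotype_terms.
#' @export
load_gene_model <- function(gff_path) {
  gr <- rtracklayer::import(gff_path, format = "GFF")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$type <- as.character(df$type)
  getattr <- function(col) {
    if (col %in% names(df)) as.character(df[[col]]) else rep(NA_character_,
                                                             nrow(df))
  }
  ids <- getattr("ID")
  parents <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) as.character(p)[1]
                                  else NA_character_, character(1))
  } else rep(NA_character_, nrow(df))
  namecol <- getattr("Name")

  genes <- df$type == "gene"
  gene_name <- setNames(ifelse(is.na(namecol[genes]), ids[genes],
                               namecol[genes]), ids[genes])
  istx <- df$type %in% c("mRNA", "transcript")
  out <- list()
  for (i in which(istx)) {
    tid <- ids[i]
    kids <- which(!is.na(parents) & parents == tid)
    ex <- kids[df$type[kids] == "exon"]
    cds <- kids[df$type[kids] == "CDS"]
    tx <- list(
      transcript_id = tid,
      gene_name = unname(gene_name[parents[i]]) %||% parents[i],
      contig = df$seqnames[i],
      strand = as.character(df$strand[i]),
      exons = data.frame(start = df$start[ex] - 1L, end = df$end[ex]),
      cds_start = if (length(cds)) min(df$start[cds]) - 1L else NA_integer_,
      cds_end = if (length(cds)) max(df$end[cds]) else NA_integer_,
      phenotype_terms = character(0))
    if (is.na(tx$gene_name)) tx$gene_name <- tid
    tx$exons <- tx$exons[order(tx$exons$start), , drop = FALSE]
    rownames(tx$exons) <- NULL
    msg <- validate_transcript(tx)
    if (is.null(msg)) {
      class(tx) <- "transcript_model"
      out[[tid]] <- tx
    } else {
      warning("skipping transcript ", tid, ": ", msg, call. = FALSE)
    }
  }
  if (length(out) == 0) stop("no parseable transcript in ", gff_path)
  out
}

# NULL if valid, otherwise a message
validate_transcript <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) == 0) return("no exons")
  if (any(ex$start >= ex$end)) return("empty exon")
  if (is.unsorted(ex$start)) return("exons not sorted")
  if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
    return("overlapping exons")
  }
  if (!tx$strand %in% c("+", "-")) return("missing strand")
  if (is.na(tx$cds_start) || is.na(tx$cds_end)) return("no CDS")
  if (tx$cds_start < min(ex$start) || tx$cds_end > max(ex$end)) {
    return("CDS outside exon span")
  }
  if (spliced_cds_length(tx) %% 3L != 0L) {
    return("spliced CDS length not divisible by 3")
  }
  NULL
}

# exon/CDS intersection lengths, in genomic order
cds_intervals <- function(tx) {
  s <- pmax(tx$exons$start, tx$cds_start)
  e <- pmin(tx$exons$end, tx$cds_end)
  keep <- s < e
  data.frame(start = s[keep], end = e[keep])
}

spliced_cds_length <- function(tx) {
  iv <- cds_intervals(tx)
  sum(iv$end - iv$start)
}

# genomic 0-based positions of the spliced CDS in transcription order
cds_position_map <- function(tx) {
  iv <- cds_intervals(tx)
  pos <- unlist(mapply(function(s, e) seq.int(s, e - 1L), iv$start, iv$end,
                       SIMPLIFY = FALSE), use.names = FALSE)
  if (tx$strand == "-") pos <- rev(pos)
  pos
}

# spliced CDS sequence in transcription order (revcomp for minus strand)
spliced_cds_seq <- function(tx, ref) {
  iv <- cds_intervals(tx)
  seqs <- substring(ref[[tx$contig]], iv$start + 1L, iv$end)
  s <- paste(seqs, collapse = "")
  if (tx$strand == "-") revcomp(s) else s
}

#' Write a gene model as GFF3
#' @param transcripts list of transcript models.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(transcripts, path) {
  lines <- "##gff-version 3"
  seen_genes <- character(0)
  for (tx in transcripts) {
    gid <- paste0("gene:", tx$gene_name)
    span <- c(min(tx$exons$start), max(tx$exons$end))
    if (!gid %in% seen_genes) {
      lines <- c(lines, paste(tx$contig, "diagseq", "gene", span[1] + 1L,
                              span[2], ".", tx$strand, ".",
                              sprintf("ID=%s;Name=%s", gid, tx$gene_name),
                              sep = "\t"))
      seen_genes <- c(seen_genes, gid)
    }
    lines <- c(lines, paste(tx$contig, "diagseq", "mRNA", span[1] + 1L,
                            span[2], ".", tx$strand, ".",
                            sprintf("ID=%s;Parent=%s", tx$transcript_id, gid),
                            sep = "\t"))
    for (j in seq_len(nrow(tx$exons))) {
      lines <- c(lines, paste(tx$contig, "diagseq", "exon",
                              tx$exons$start[j] + 1L, tx$exons$end[j], ".",
                              tx$strand, ".",
                              sprintf("ID=%s.exon%d;Parent=%s",
                                      tx$transcript_id, j, tx$transcript_id),
                              sep = "\t"))
    }
    iv <- cds_intervals(tx)
    for (j in seq_len(nrow(iv))) {
      lines <- c(lines, paste(tx$contig, "diagseq", "CDS", iv$start[j] + 1L,
                              iv$end[j], ".", tx$strand, "0",
                              sprintf("ID=%s.cds%d;Parent=%s",
                                      tx$transcript_id, j, tx$transcript_id),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
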