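# simdata: deterministic synthetic-data generator — reference, gene model,
# diploid sample genomes with a truth set, and reads with errors, adapters
# and barcodes. Every generator is byte-deterministic under its seed.

#' Generate a uniform-random reference genome
#'
#' @param contigs named integer vector: contig name -> length.
#' @param seed RNG seed.
#' @param path optional FASTA output path.
#' @return named character vector of contig sequences.
#' @export
make_reference <- function(contigs = c(chr1 = 10000L), seed = 1L,
                           path = NULL) {
  if (is.null(names(contigs)) || any(!nzchar(names(contigs)))) {
    stop("contigs must be a named vector (name -> length)")
  }
  set.seed(seed)
  ref <- vapply(contigs, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
  if (!is.null(path)) write_reference(ref, path)
  ref
}

# write base b at spliced-CDS index i (1-based, transcription order) of tx
# into the reference copy; strand-aware
write_cds_base <- function(ref, tx, i, b) {
  map <- cds_position_map(tx)
  g <- map[i]
  if (tx$strand == "-") b <- revcomp(b)
  s <- ref[[tx$contig]]
  substr(s, g + 1L, g + 1L) <- b
  ref[[tx$contig]] <- s
  ref
}

#' Generate a transcript gene model and write it into a reference copy
#'
#' Places `n_genes` non-overlapping genes (2-4 exons each, alternating
#' strands, introns of at least 30 bp) on the reference. Each gene's
#' spliced CDS is made a valid ORF by writing an ATG start, a TAA stop and
#' by clearing internal stop codons in the returned reference copy; the
#' spliced CDS length is divisible by 3 by construction.
#'
#' @param ref reference genome.
#' @param n_genes number of genes.
#' @param seed RNG seed.
#' @param gff_path optional GFF3 output path.
#' @return list with `ref` (modified reference), `transcripts` (list of
#'   transcript models) and `manifest` (one row per gene).
#' @export
make_gene_model <- function(ref, n_genes = 2L, seed = 1L, gff_path = NULL) {
  set.seed(seed)
  contig_names <- names(ref)
  cursors <- setNames(rep(100L, length(ref)), contig_names)
  transcripts <- list()
  manifest <- NULL
  for (g in seq_len(n_genes)) {
    ci <- ((g - 1L) %% length(ref)) + 1L
    contig <- contig_names[ci]
    clen <- nchar(ref[[contig]])
    n_ex <- sample(2:4, 1)
    ex_lens <- sample(90:240, n_ex, replace = TRUE)
    in_lens <- if (n_ex > 1) sample(30:120, n_ex - 1L, replace = TRUE)
               else integer(0)
    span <- sum(ex_lens) + sum(in_lens)
    start <- cursors[[contig]]
    if (start + span + 100L > clen) {
      stop("insufficient space on ", contig, " for gene ", g)
    }
    cursors[[contig]] <- start + span + sample(150:400, 1)
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    p <- start
    for (e in seq_len(n_ex)) {
      ex_start[e] <- p
      ex_end[e] <- p + ex_lens[e]
      p <- ex_end[e] + if (e < n_ex) in_lens[e] else 0L
    }
    strand <- if (g %% 2L == 1L) "+" else "-"
    # UTRs: leave 9-30 bases at each spliced end outside the CDS
    utr5 <- sample(9:30, 1); utr3 <- sample(9:30, 1)
    cds_start <- ex_start[1] + utr5
    cds_end <- ex_end[n_ex] - utr3
    tx <- list(transcript_id = sprintf("tx%03d", g),
               gene_name = sprintf("GENE%03d", g), contig = contig,
               strand = strand,
               exons = data.frame(start = ex_start, end = ex_end),
               cds_start = cds_start, cds_end = cds_end,
               phenotype_terms = character(0))
    # trim cds_end so the spliced CDS length is divisible by 3
    rem <- spliced_cds_length(tx) %% 3L
    tx$cds_end <- tx$cds_end - rem
    stopifnot(spliced_cds_length(tx) %% 3L == 0L,
              spliced_cds_length(tx) >= 60L)
    # make it an ORF: start codon, terminal stop, no internal stops
    L <- spliced_cds_length(tx)
    for (i in 1:3) ref <- write_cds_base(ref, tx, i, c("A", "T", "G")[i])
    for (i in 1:3) ref <- write_cds_base(ref, tx, L - 3L + i,
                                         c("T", "A", "A")[i])
    cds <- spliced_cds_seq(tx, ref)
    for (cd in seq_len(L / 3L - 1L)[-1]) {
      codon <- substr(cds, cd * 3L - 2L, cd * 3L)
      if (codon %in% c("TAA", "TAG", "TGA")) {
        ref <- write_cds_base(ref, tx, cd * 3L - 1L, "C")  # TAx->TCx, TGA->TCA
      }
    }
    class(tx) <- "transcript_model"
    stopifnot(is.null(validate_transcript(tx)))
    transcripts[[tx$transcript_id]] <- tx
    manifest <- rbind(manifest, data.frame(
      gene = tx$gene_name, transcript = tx$transcript_id, contig = contig,
      strand = strand, n_exons = n_ex, cds_len = spliced_cds_length(tx),
      stringsAsFactors = FALSE))
  }
  if (!is.null(gff_path)) write_gene_model(transcripts, gff_path)
  list(ref = ref, transcripts = transcripts, manifest = manifest)
}

# apply VCF-style variants (1-based, anchored indels) to one contig string
apply_variants_to_seq <- function(seq, pos, ref_allele, alt_allele) {
  ord <- order(pos, decreasing = TRUE)
  for (i in ord) {
    before <- substr(seq, 1L, pos[i] - 1L)
    after <- substr(seq, pos[i] + nchar(ref_allele[i]), nchar(seq))
    seq <- paste0(before, alt_allele[i], after)
  }
  seq
}

#' Implant variants into a diploid pair of haplotypes
#'
#' Homozygous variants are applied to both haplotypes, heterozygous ones
#' to haplotype 1 only. Indels shift downstream coordinates consistently;
#' the returned truth set records VCF-style normalized coordinates.
#'
#' @param ref reference genome.
#' @param variants data.frame with contig, pos (1-based), ref, alt,
#'   genotype ("het"/"hom"); indels left-anchored as in VCF.
#' @return list with `haplotypes` (list of two genomes), `truth`
#'   (the validated variant table) and `shifts` (per haplotype/contig
#'   coordinate-shift tables for projecting haplotype positions back to
#'   the reference).
#' @export
implant_variants <- function(ref, variants) {
  stopifnot(all(variants$genotype %in% c("het", "hom")))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    seen <- substr(ref[[v$contig]], v$pos, v$pos + nchar(v$ref) - 1L)
    if (seen != v$ref) {
      stop(sprintf("ref allele mismatch at %s:%d (expected %s, found %s)",
                   v$contig, v$pos, v$ref, seen))
    }
  }
  key <- paste(variants$contig, variants$pos)
  if (anyDuplicated(key)) stop("multiple variants at one position")
  # the truth set reports VCF-normalized (left-aligned) representations
  truth <- variants
  for (i in seq_len(nrow(truth))) {
    la <- left_align_variant(ref[[truth$contig[i]]], truth$pos[i],
                             truth$ref[i], truth$alt[i])
    truth$pos[i] <- la$pos; truth$ref[i] <- la$ref; truth$alt[i] <- la$alt
  }
  haps <- list(ref, ref)
  shifts <- list(list(), list())
  for (h in 1:2) {
    use <- variants[variants$genotype == "hom" | h == 1L, , drop = FALSE]
    for (contig in unique(use$contig)) {
      vc <- use[use$contig == contig, , drop = FALSE]
      vc <- vc[order(vc$pos), , drop = FALSE]
      haps[[h]][[contig]] <- apply_variants_to_seq(
        ref[[contig]], vc$pos, vc$ref, vc$alt)
      # hap coordinate of each variant anchor and cumulative ref-hap delta
      delta <- nchar(vc$alt) - nchar(vc$ref)
      cum <- cumsum(delta)
      shifts[[h]][[contig]] <- data.frame(
        hap_after = vc$pos + nchar(vc$alt) - 1L + c(0L, cum[-length(cum)]),
        shift = cum)
    }
  }
  list(haplotypes = haps, truth = truth, shifts = shifts)
}

# project a 0-based haplotype position back to the reference
project_position <- function(shifts, hap, contig, pos0) {
  tab <- shifts[[hap]][[contig]]
  if (is.null(tab) || nrow(tab) == 0) return(pos0)
  i <- findInterval(pos0 + 1L, tab$hap_after + 1L)
  if (i == 0L) pos0 else pos0 - tab$shift[i]
}

#' Simulate reads from a diploid sample
#'
#' Fragments are drawn uniformly across contigs (weighted by length), each
#' from a uniformly chosen haplotype and strand. Substitution errors are
#' i.i.d. at `error_rate`; base quality is a constant 37, lowered to 22 at
#' error positions. When a fragment is shorter than the read length the 3'
#' adapter (when given) is appended. Inline 5' barcodes are prepended when
#' `barcodes` is given, assigning fragments to samples uniformly.
#'
#' @param haplotypes list of two genomes (from [implant_variants()]), or a
#'   single genome for a haploid simulation.
#' @param read_length read length.
#' @param coverage mean depth over the genome.
#' @param paired simulate read pairs (fragment ends) or single reads.
#' @param insert_mean,insert_sd fragment-length distribution for paired
#'   mode.
#' @param error_rate per-base substitution error rate.
#' @param adapter optional 3' adapter sequence.
#' @param barcodes optional named vector sample -> barcode.
#' @param seed RNG seed.
#' @param shifts optional shift tables from [implant_variants()] used to
#'   project true positions onto the reference.
#' @return list with `reads1`, `reads2` (NULL if unpaired) and `manifest`
#'   (read_id, contig, hap, strand, sample, hap_pos0, ref_pos0, mate
#'   positions).
#' @export
simulate_reads <- function(haplotypes, read_length = 100L, coverage = 30,
                           paired = TRUE, insert_mean = 300L,
                           insert_sd = 30L, error_rate = 0.005,
                           adapter = NULL, barcodes = NULL, seed = 1L,
                           shifts = NULL) {
  stopifnot(coverage > 0)
  if (is.character(haplotypes)) haplotypes <- list(haplotypes, haplotypes)
  set.seed(seed)
  read_length <- as.integer(read_length)
  contigs <- names(haplotypes[[1]])
  clen1 <- nchar(haplotypes[[1]])
  if (read_length > max(clen1)) {
    stop("read_length exceeds every contig length")
  }
  genome_len <- sum(clen1)
  n_frag <- ceiling(coverage * genome_len /
                      (read_length * (if (paired) 2L else 1L)))
  samples <- if (is.null(barcodes)) rep(NA_character_, n_frag)
             else sample(names(barcodes), n_frag, replace = TRUE)

  hap <- sample(1:2, n_frag, replace = TRUE)
  contig <- sample(contigs, n_frag, replace = TRUE,
                   prob = clen1 / sum(clen1))
  flen <- if (paired) {
    # fragments may be shorter than a read (the 3' adapter is then read)
    pmax(20L, as.integer(round(rnorm(n_frag, insert_mean, insert_sd))))
  } else rep.int(read_length, n_frag)
  flip <- runif(n_frag) < 0.5  # fragment sequenced from the minus strand

  start0 <- integer(n_frag)
  fwd <- character(n_frag); rev <- character(n_frag)
  for (h in 1:2) for (ct in contigs) {
    idx <- which(hap == h & contig == ct)
    if (length(idx) == 0) next
    g <- haplotypes[[h]][[ct]]
    cl <- nchar(g)
    fl <- pmin(flen[idx], cl)
    flen[idx] <- fl
    st <- as.integer(floor(runif(length(idx)) * (cl - fl + 1L)))
    start0[idx] <- st
    fwd[idx] <- substring(g, st + 1L, st + pmin(read_length, fl))
    rev[idx] <- revcomp(substring(g, st + pmax(0L, fl - read_length) + 1L,
                                  st + fl))
  }

  # substitution errors: constant Q37, Q22 at error positions
  bases <- c("A", "C", "G", "T")
  add_errors <- function(seqs) {
    len <- nchar(seqs)
    qual <- strrep(phred_encode(37L), len)
    k <- rbinom(length(seqs), len, error_rate)
    for (i in which(k > 0L)) {
      ps <- sample.int(len[i], k[i])
      for (p in ps) {
        old <- substr(seqs[i], p, p)
        substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1)
        substr(qual[i], p, p) <- phred_encode(22L)
      }
    }
    list(seq = seqs, qual = qual)
  }
  fill_adapter <- function(seqs) {
    if (is.null(adapter)) return(seqs)
    short <- nchar(seqs) < read_length
    seqs[short] <- substr(paste0(seqs[short], adapter), 1L, read_length)
    seqs
  }

  ids <- sprintf("sim_%06d", seq_len(n_frag))
  posf <- start0                                  # leftmost of fwd read
  posr <- start0 + flen - pmin(read_length, flen) # leftmost of rev read
  man <- data.frame(read_id = ids, contig = contig, hap = hap,
                    strand = ifelse(flip, "-", "+"), sample = samples,
                    hap_pos0 = ifelse(flip, posr, posf),
                    ref_pos0 = NA_integer_,
                    hap_pos0_mate = if (paired) ifelse(flip, posf, posr)
                                    else NA_integer_,
                    ref_pos0_mate = NA_integer_, stringsAsFactors = FALSE)
  if (is.null(shifts)) {
    man$ref_pos0 <- man$hap_pos0
    if (paired) man$ref_pos0_mate <- man$hap_pos0_mate
  } else {
    man$ref_pos0 <- as.integer(vapply(seq_len(n_frag), function(i)
      project_position(shifts, hap[i], contig[i], man$hap_pos0[i]),
      numeric(1)))
    if (paired) {
      man$ref_pos0_mate <- as.integer(vapply(seq_len(n_frag), function(i)
        project_position(shifts, hap[i], contig[i], man$hap_pos0_mate[i]),
        numeric(1)))
    }
  }

  if (!paired) {
    r1 <- add_errors(fill_adapter(ifelse(flip, rev, fwd)))
    s1 <- r1$seq; q1 <- r1$qual
    s2 <- q2 <- NULL
  } else {
    r1 <- add_errors(fill_adapter(ifelse(flip, rev, fwd)))
    r2 <- add_errors(fill_adapter(ifelse(flip, fwd, rev)))
    s1 <- r1$seq; q1 <- r1$qual
    s2 <- r2$seq; q2 <- r2$qual
  }
  if (!is.null(barcodes)) {
    bc <- unname(barcodes[samples])
    s1 <- paste0(bc, s1)
    q1 <- paste0(strrep(phred_encode(37L), nchar(bc)), q1)
  }
  reads1 <- new_reads(if (paired) paste0(ids, "/1") else ids, s1, q1,
                      mate = if (paired) "first" else "none")
  reads2 <- if (paired) {
    new_reads(paste0(ids, "/2"), s2, q2, mate = "second")
  } else NULL
  list(reads1 = reads1, reads2 = reads2, manifest = man)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: reference, random non-colliding het/hom SNPs and
#' 1-3 bp indels, diploid haplotypes, paired reads, and (optionally) all
#' files on disk. Variant positions keep a margin from contig ends and
#' from each other so truth-set evaluation is unambiguous.
#'
#' @param contigs named vector contig -> length.
#' @param n_snps,n_indels number of implanted SNPs / indels.
#' @param snp_genotype,indel_genotype "het" or "hom" (recycled).
#' @param coverage,read_length,paired,insert_mean,insert_sd,error_rate,adapter,barcodes
#'   passed to [simulate_reads()].
#' @param seed master seed for every stage.
#' @param out_dir optional directory for FASTA/GFF/FASTQ/VCF-truth/TSV
#'   files.
#' @param n_genes genes in the generated model.
#' @return list: ref, gene model, truth, reads1/reads2, manifest, paths.
#' @export
simulate_dataset <- function(contigs = c(chr1 = 20000L), n_snps = 20L,
                             n_indels = 5L, snp_genotype = "het",
                             indel_genotype = "het", coverage = 50,
                             read_length = 100L, paired = TRUE,
                             insert_mean = 300L, insert_sd = 30L,
                             error_rate = 0.005, adapter = NULL,
                             barcodes = NULL, seed = 1L, out_dir = NULL,
                             n_genes = 2L) {
  ref0 <- make_reference(contigs, seed = seed)
  gm <- make_gene_model(ref0, n_genes = n_genes, seed = seed + 1L)
  ref <- gm$ref
  set.seed(seed + 2L)
  margin <- 300L; spacing <- 50L
  n_var <- n_snps + n_indels
  pool <- unlist(lapply(names(ref), function(ct) {
    cand <- seq.int(margin, nchar(ref[[ct]]) - margin)
    paste(ct, cand)
  }))
  vars <- NULL
  taken <- list()
  tries <- 0L
  while ((is.null(vars) || nrow(vars) < n_var) && tries < 50000L) {
    tries <- tries + 1L
    pick <- sample(pool, 1)
    ct <- sub(" .*", "", pick)
    pos <- as.integer(sub(".* ", "", pick))
    near <- taken[[ct]]
    if (!is.null(near) && any(abs(near - pos) < spacing)) next
    i <- if (is.null(vars)) 1L else nrow(vars) + 1L
    is_snp <- i <= n_snps
    refb <- substr(ref[[ct]], pos, pos)
    if (is_snp) {
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      v <- data.frame(contig = ct, pos = pos, ref = refb, alt = altb,
                      genotype = rep_len(snp_genotype, n_snps)[i],
                      stringsAsFactors = FALSE)
    } else {
      ilen <- sample(1:3, 1)
      if (runif(1) < 0.5) {  # insertion
        ins <- paste(sample(c("A", "C", "G", "T"), ilen, replace = TRUE),
                     collapse = "")
        v <- data.frame(contig = ct, pos = pos, ref = refb,
                        alt = paste0(refb, ins),
                        genotype = rep_len(indel_genotype,
                                           n_indels)[i - n_snps],
                        stringsAsFactors = FALSE)
      } else {               # deletion
        del <- substr(ref[[ct]], pos, pos + ilen)
        v <- data.frame(contig = ct, pos = pos, ref = del, alt = refb,
                        genotype = rep_len(indel_genotype,
                                           n_indels)[i - n_snps],
                        stringsAsFactors = FALSE)
      }
    }
    vars <- rbind(vars, v)
    taken[[ct]] <- c(taken[[ct]], pos)
  }
  if (is.null(vars) || nrow(vars) < n_var) {
    stop("could not place ", n_var, " variants with the requested spacing")
  }
  vars <- vars[order(match(vars$contig, names(ref)), vars$pos), ,
               drop = FALSE]
  rownames(vars) <- NULL
  imp <- implant_variants(ref, vars)
  sim <- simulate_reads(imp$haplotypes, read_length = read_length,
                        coverage = coverage, paired = paired,
                        insert_mean = insert_mean, insert_sd = insert_sd,
                        error_rate = error_rate, adapter = adapter,
                        barcodes = barcodes, seed = seed + 3L,
                        shifts = imp$shifts)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      ref = file.path(out_dir, "reference.fasta"),
      gff = file.path(out_dir, "genes.gff3"),
      fastq1 = file.path(out_dir, "reads_R1.fastq"),
      fastq2 = if (paired) file.path(out_dir, "reads_R2.fastq") else NULL,
      truth = file.path(out_dir, "truth.tsv"),
      manifest = file.path(out_dir, "manifest.tsv"))
    write_reference(ref, paths$ref)
    write_gene_model(gm$transcripts, paths$gff)
    write_fastq(sim$reads1, paths$fastq1)
    if (paired) write_fastq(sim$reads2, paths$fastq2)
    write.table(imp$truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(sim$manifest, paths$manifest, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(ref = ref, transcripts = gm$transcripts,
       gene_manifest = gm$manifest, truth = imp$truth,
       haplotypes = imp$haplotypes, shifts = imp$shifts,
       reads1 = sim$reads1, reads2 = sim$reads2, manifest = sim$manifest,
       paths = paths)
}
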