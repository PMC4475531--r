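# Hash index, candidate selection, Gotoh alignment, read/pair placement,
# BAM emission.

test_that("the k-mer index records every occurrence and masks repeats", {
  ref <- c(c1 = "ACGTACGTACGTACGT", c2 = "TTTTTTTTTTTT")
  idx <- build_index(ref, k = 8, max_hits = 64)
  # brute-force scan oracle
  for (ct in names(ref)) {
    n <- nchar(ref[[ct]])
    for (off in 0:(n - 8)) {
      km <- substr(ref[[ct]], off + 1, off + 8)
      hits <- index_lookup(idx, km)
      found <- any(hits[, "contig"] == match(ct, names(ref)) &
                     hits[, "offset"] == off)
      expect_true(found, label = paste("hit", ct, off))
    }
  }
  expect_equal(index_lookup(idx, "ACGTACGT")[, "offset"],
               c(0, 4, 8))

  idx2 <- build_index(ref, k = 8, max_hits = 2)
  expect_null(index_lookup(idx2, "ACGTACGT"))  # 3 hits > 2: masked

  expect_warning(build_index(c(c1 = strrep("N", 20), c2 = "ACGTACGTCCAT"),
                             k = 12), NA)
  riN <- build_index(c(c1 = strrep("N", 20)), k = 8)
  expect_length(ls(riN$env), 0)  # k-mers containing N are skipped
})

test_that("candidate selection votes on diagonals and ranks by seed count", {
  set.seed(21)
  ref <- c(chr1 = random_dna(3000))
  idx <- build_index(ref, k = 11)
  read_seq <- substr(ref[[1]], 101, 130)  # unique 30 bp substring
  cand <- candidate_positions(read_seq, idx)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$seed_count, 30 - 11 + 1)  # every k-mer votes
  expect_equal(cand$strand, "+")
  expect_true(cand$window_start <= 100 && cand$window_end >= 130)

  # reverse-complement reads are found on the minus strand
  cand_rc <- candidate_positions(revcomp(read_seq), idx)
  expect_equal(cand_rc$strand[1], "-")

  # absent sequence yields no candidates
  expect_equal(nrow(candidate_positions(strrep("ACGT", 8), idx)), 0)
})

test_that("equal two-locus matches tie and are ordered by position", {
  set.seed(22)
  unit <- random_dna(40)
  ref <- c(chrA = paste0(random_dna(200), unit, random_dna(300), unit,
                         random_dna(200)))
  idx <- build_index(ref, k = 11, max_hits = 64)
  cand <- candidate_positions(unit, idx)
  top <- cand[cand$seed_count == max(cand$seed_count), ]
  expect_equal(nrow(top), 2)
  expect_true(top$band_start[1] < top$band_start[2])
  r <- new_reads("rep", unit, phred_encode(rep(37L, 40)))
  rec <- align_read(r, ref, idx)
  expect_equal(rec$mapq, 0L)  # best == second best
  expect_equal(rec$pos, 200L) # lower coordinate wins the tie
})

test_that("gotoh alignment matches hand-computed and trivial cases", {
  sc <- scoring_scheme(2L, -4L, -6L, -1L)
  perfect <- gotoh_align("ACGTACGT", "ACGTACGT", sc)
  expect_equal(perfect$score, 16)
  expect_equal(perfect$cigar, "8M")
  expect_equal(perfect$target_offset, 0L)

  mm <- gotoh_align("ACGTACGT", "ACGAACGT", sc)  # one mismatch
  expect_equal(mm$score, 7 * 2 - 4)
  expect_equal(mm$cigar, "8M")

  ins <- gotoh_align("ACGTTACGT", "ACGTACGT", sc)  # 1-base insertion
  expect_equal(ins$score, 8 * 2 - 6)

  # free target overhang on both sides
  over <- gotoh_align("ACGTACGT", "GGGGGACGTACGTGGGGG", sc)
  expect_equal(over$score, 16)
  expect_equal(over$target_offset, 5L)

  # window shorter than query/2 yields a no-alignment result
  none <- gotoh_align("ACGTACGTACGT", "ACG", sc)
  expect_equal(none$score, -Inf)
})

test_that("gotoh equals the exhaustive path-enumeration oracle", {
  set.seed(23)
  for (i in 1:20) {
    sc <- random_scoring()
    q <- random_dna(sample(2:5, 1))
    t <- random_dna(sample(max(1, ceiling(nchar(q) / 2)):5, 1))
    got <- gotoh_align(q, t, sc)
    expect_equal(got$score, oracle_glocal_enum(q, t, sc),
                 label = sprintf("q=%s t=%s", q, t))
  }
})

test_that("gotoh equals an independent affine-gap implementation", {
  set.seed(24)
  for (i in 1:200) {
    sc <- random_scoring()
    q <- random_dna(sample(1:12, 1))
    t <- random_dna(sample(max(1, ceiling(nchar(q) / 2)):12, 1))
    expect_equal(gotoh_align(q, t, sc)$score,
                 oracle_glocal_biostrings(q, t, sc),
                 label = sprintf("q=%s t=%s", q, t))
  }
})

test_that("CIGARs are consistent with read and reference spans", {
  set.seed(25)
  ref <- c(chr1 = random_dna(5000))
  idx <- build_index(ref)
  sim <- simulate_reads(ref, read_length = 80, coverage = 3,
                        paired = FALSE, error_rate = 0.01, seed = 25)
  for (i in seq_len(min(60, nrow(sim$reads1)))) {
    rec <- align_read(sim$reads1[i, ], ref, idx)
    if (!rec$mapped) next
    ops <- regmatches(rec$cigar, gregexpr("[0-9]+[MIDS]", rec$cigar))[[1]]
    lens <- as.integer(sub("[MIDS]", "", ops))
    kinds <- sub("[0-9]+", "", ops)
    expect_equal(sum(lens[kinds %in% c("M", "I", "S")]), 80)
    expect_true(rec$pos + sum(lens[kinds %in% c("M", "D")]) <=
                  nchar(ref[[1]]))
  }
})

test_that("error-free unique reads are recovered at the true position", {
  set.seed(26)
  ref <- c(chr1 = random_dna(8000), chr2 = random_dna(4000))
  idx <- build_index(ref)
  sim <- simulate_reads(ref, read_length = 100, coverage = 2,
                        paired = FALSE, error_rate = 0, seed = 26)
  n <- nrow(sim$reads1)
  hits <- 0L
  for (i in seq_len(n)) {
    rec <- align_read(sim$reads1[i, ], ref, idx)
    ok <- rec$mapped && rec$contig == sim$manifest$contig[i] &&
      rec$pos == sim$manifest$hap_pos0[i] &&
      rec$strand == sim$manifest$strand[i] && rec$cigar == "100M" &&
      rec$mapq == 60L
    hits <- hits + ok
  }
  expect_equal(hits, n)  # 100% recovery
})

test_that("random reads are reported unmapped", {
  set.seed(27)
  ref <- c(chr1 = random_dna(5000))
  idx <- build_index(ref)
  r <- new_reads("rnd", random_dna(100), phred_encode(rep(37L, 100)))
  rec <- align_read(r, ref, idx)
  expect_false(rec$mapped)
})

test_that("pairs within the insert range become proper pairs", {
  set.seed(28)
  ref <- c(chr1 = random_dna(6000))
  idx <- build_index(ref)
  sim <- simulate_reads(ref, read_length = 100, coverage = 2,
                        paired = TRUE, insert_mean = 300, insert_sd = 20,
                        error_rate = 0, seed = 28)
  for (i in seq_len(min(25, nrow(sim$reads1)))) {
    p <- align_pair(sim$reads1[i, ], sim$reads2[i, ], ref, idx)
    expect_true(p$proper)
    expect_equal(p$r1$pos, sim$manifest$hap_pos0[i])
    expect_equal(p$r2$pos, sim$manifest$hap_pos0_mate[i])
  }
})

test_that("a pair violating the insert bounds is mapped but not proper", {
  set.seed(29)
  ref <- c(chr1 = random_dna(6000))
  idx <- build_index(ref)
  r1seq <- substr(ref[[1]], 101, 200)
  r2seq <- revcomp(substr(ref[[1]], 4001, 4100))  # 4 kb apart
  r1 <- new_reads("p/1", r1seq, phred_encode(rep(37L, 100)), mate = "first")
  r2 <- new_reads("p/2", r2seq, phred_encode(rep(37L, 100)),
                  mate = "second")
  p <- align_pair(r1, r2, ref, idx)
  expect_false(p$proper)
  expect_true(p$r1$mapped && p$r2$mapped)
  expect_equal(p$r1$pos, 100L)
  expect_equal(p$r2$pos, 4000L)

  # one unmappable mate keeps the other at its position
  rx <- new_reads("q/2", random_dna(100), phred_encode(rep(37L, 100)))
  p2 <- align_pair(r1, rx, ref, idx)
  expect_true(p2$r1$mapped)
  expect_false(p2$r2$mapped)
})

test_that("align_all writes a valid sorted BAM identical across workers", {
  set.seed(30)
  ds <- simulate_dataset(contigs = c(chr1 = 8000L), n_snps = 4,
                         n_indels = 1, coverage = 10, seed = 30)
  reads1 <- ds$reads1[1:150, ]; reads2 <- ds$reads2[1:150, ]
  b1 <- tmpfile(".bam"); b2 <- tmpfile(".bam")
  r1 <- align_all(reads1, ds$ref, output = b1, reads2 = reads2,
                  n_workers = 1)
  cfg <- align_config(chunk_size = 37L)
  r2 <- align_all(reads1, ds$ref, output = b2, reads2 = reads2, cfg = cfg,
                  n_workers = 4)
  expect_equal(unname(tools::md5sum(r1$bam)), unname(tools::md5sum(r2$bam)))
  expect_equal(r1$stats$mapped, r2$stats$mapped)

  # emitted BAM parses under the standard reader and is coordinate-sorted
  aln <- Rsamtools::scanBam(r1$bam)[[1]]
  mapped_pos <- aln$pos[!bitwAnd(aln$flag, 4L)]
  expect_false(is.unsorted(mapped_pos))
  expect_equal(r1$stats$mapped + r1$stats$unmapped, 300L)
  expect_equal(sum(r1$stats$per_contig), r1$stats$mapped)

  # empty read set yields a valid header-only BAM
  empty <- align_all(ds$reads1[0, ], ds$ref, output = tmpfile(".bam"))
  expect_equal(length(Rsamtools::scanBam(empty$bam)[[1]]$pos), 0)
})
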