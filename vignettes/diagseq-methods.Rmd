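---
title: "diagseq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{diagseq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

diagseq implements a diagnostic resequencing workflow — read QC and
preprocessing, seed-and-extend alignment, coverage QC, pileup variant
calling, consequence annotation, and a filtering/classification/report
layer — together with a synthetic-data generator that provides every
fixture its evaluation needs. This vignette records the models, the
parameters that matter, and the design decisions that were genuinely
open, so a maintainer can see why the code is the way it is.

## Read representation and import

Reads live in an ordinary data.frame (one row per read) with the
quality kept as a Phred+33 string; this keeps a lane of a few million
reads compact and makes FASTQ round-trips exact by construction.
FASTA input carries no qualities, so each base receives a uniform
default of **Q30** (flag-overridable). Q30 was chosen as a neutral
"good" call: it is high enough not to trip the caller's base-quality
gate (15) yet low enough not to outrank real FASTQ qualities. All
internal intervals are 0-based half-open; conversion to and from the
1-based conventions of SAM, VCF and GFF happens only at the format
boundary, which a coordinate round-trip test pins down.

## Read QC and preprocessing

`compute_read_stats()` reports length, per-read mean quality
(arithmetic mean of Phred scores — the convention of common QC tools,
not the error-probability mean, which would be dominated by the worst
base), GC percent of non-N bases in 1%-wide bins (floor; all-N reads in
bin 0), per-position base composition and mean quality, and k-mer
counts over the first and last **W = 10** bases with **k = 5**.
Overrepresentation is reported as an observed/expected ratio under the
read set's own base composition; with no published statistic to match,
the simplest composition-corrected ratio was preferred over a formal
test.

`process_read()` applies a fixed operation order: 5' trim → 3' adapter
removal → 3' trim → length cap → length/quality gates. Adapters lie 3'
of the insert, so 5' trimming first cannot destroy adapter signal.
Adapter matching is the classic end-anchored overlap: the best (longest)
read suffix that is a prefix of the adapter, requiring at least 8
overlapping bases and at most a 10% mismatch rate. Anchoring at the
read end is what makes `insert + adapter-prefix` reads (the only kind a
short fragment produces) trim exactly; a full adapter followed by
read-through junk is not handled and is documented as out of scope.
Rejected reads carry the *first* failing rule so filter summaries are
reproducible, and kept + rejected always partitions the input — both
are property-tested.

Demultiplexing compares the 5' L bases against equal-length inline
barcodes and requires pairwise barcode Hamming distance
> 2·max_mismatches, which makes every assignment provably unambiguous;
dual indexing is not supported.

## Aligner

The reference is indexed by every k-mer position (**k = 11**, N-free
k-mers only); k-mers with more than **max_hits = 64** positions are
masked so repeats do not flood seeding. Each read k-mer (both strands)
votes for its diagonal `reference_offset − read_offset`; votes are
binned into diagonal bands of width **band = 16**, bands with
**min_seed_hits = 2** become candidates, ranked by votes and capped at
**max_candidates = 32**. A true placement contributes ~`L − k + 1`
co-diagonal votes, so these defaults are permissive; they follow common
seed-and-extend practice and are all configurable. A diagonal falling
on a band boundary can split its votes; both neighbouring bands then
qualify, their windows overlap the true position, and duplicate
placements are collapsed after extension.

Extension is the Gotoh three-state recurrence (match state plus one
affine gap state per sequence) under (match +2, mismatch −4, gap open
−6, gap extend −1), where a gap of length *g* costs
`open + (g−1)·extend`. The contract is glocal: the read aligns fully,
the window overhangs for free on both sides. Glocal was preferred over
local alignment because a diagnostic caller must know that every read
base was either placed or explicitly clipped; terminal read gaps are
emitted as soft clips (S), never as insertions. The DP core is ~100
lines of Rcpp; traceback prefers diagonal moves, yielding a
deterministic CIGAR.

Mapping quality is `min(60, 2·(S_best − S_second))` with `S_second = 0`
when there is no second candidate. This is an invented separation
heuristic, not a probability — a read from an exact two-copy repeat
gets mapq 0, a clean unique hit gets 60. Reads whose best score falls
below `0.4 · match · read_length` are reported unmapped. Base
qualities are not used in alignment scoring (they pass through to the
caller). Pairs are scored jointly: same contig, opposite strands,
insert in [**100, 600**] → proper pair by summed score; otherwise both
mates keep their independent best placements.

`align_all()` processes reads in fixed-size chunks combined in input
order, so output is byte-identical for any worker count (tested by BAM
md5). SAM text is rendered by the package; BAM conversion, sorting and
indexing are delegated to Rsamtools/htslib.

## Variant caller

The pileup is decoded directly from CIGARs in Rcpp: M gives base
observations; I gives a `+SEQ` allele anchored at the preceding
reference base; D gives `−SEQ` anchored before the deleted run, whose
observation quality is the anchor base quality. Overlapping mates both
count — fragment de-duplication is deliberately not done, and the
choice is stated rather than hidden, because it only inflates depth
symmetrically at 300 bp inserts with 100 bp reads.

For each non-reference allele the support test builds the 2×2 table of
observed (ref, alt) counts against the expectation under an error rate
ε (**0.001**): `expected_alt = round(depth·ε)` (R's round; the
reference implementation's rounding is unprinted), and computes the
one-tailed Fisher exact probability of alt support at least as large
as observed with margins fixed — evaluated directly as a hypergeometric
tail. The test suite pins this against an exhaustive `choose()`
enumeration for every table with depth ≤ 30 at 1e−9.

Gates (all exposed): depth ≥ 8, alt reads ≥ 2, mean alt base quality
≥ 15 (indel alleles exempt — their "base quality" is only a proxy),
VAF ≥ 0.01, p ≤ 0.01, and strand balance `min(fwd, rev)/alt ≥ 0.1`.
"Read balance" is interpreted as strand balance of alt-supporting
reads, the standard artifact filter; position-in-read balance is a
plausible alternative reading and is noted as such. One subtlety of
the p ≤ 0.01 default: at depth 10 even a perfect 5/5 heterozygote has
p ≈ 0.016, so sites that shallow cannot pass — at the 30–70× depths
this pipeline targets the gate costs nothing and is what keeps
two-error piles (p ≈ 0.25 at 50×) out of the output. VAF ≥ 0.75 is
called homozygous. Emitted indels are left-aligned (VCF
normalization), which makes truth-set comparison representation-free;
multi-allelic sites produce one record per alternate allele.

## Annotation

Consequence prediction walks a fixed decision order per transcript:
outside span → intergenic; the **2** intronic bases flanking each exon
boundary (transcription-direction aware) → splice_donor /
splice_acceptor — the canonical GT/AG positions; an extended splice
region à la VEP is out of scope; deeper intron → intronic; exon outside
CDS → UTR; CDS indel → frameshift vs in-frame by length mod 3; CDS SNV
→ translate the reference and alternate codons of the spliced
(strand-adjusted) CDS. Strand correctness is property-tested by
mirroring whole fixtures onto the reverse complement. The worst-overall
term uses a fixed severity order (stop_gained > start_lost > stop_lost
> frameshift > splice_donor > splice_acceptor > missense > inframe_* >
synonymous > utr > intronic > intergenic) — invented but stable, in the
spirit of common effect-predictor orderings. SIFT/PolyPhen values are
consumed from local tables, never computed; on conflict the most severe
is displayed, ties report both. HGVS-like strings are best effort and
labelled as such. Known-variant joins left-trim shared ref/alt
prefixes before exact matching; complex-representation normalization
beyond that is out of scope.

## Filtering, classification, reporting

`apply_filters()` keeps a variant iff every *set* bound passes; unset
bounds pass vacuously. A missing population frequency is treated as 0
— novel variants are the diagnostic interest, so a max-frequency gate
must not discard them. Rejections are attributed to the first failing
rule in a fixed order. Classifications use the five ACMG tiers plus
`artefact` and `false_reference` and are persisted in an append-only
TSV journal — a deliberate small-lab choice over a database server;
recurrence lookup is an exact-key scan that also flags
artefact-classified variants for the filter layer. Reports (JSON
schema-versioned, HTML self-contained) always include the coverage
section with regions below the reporting depth listed explicitly, so a
report with zero variants still justifies its negative finding.

## Synthetic data: what it does and does not emulate

The generator produces uniform-random references, gene models with 2–4
exons and valid ORFs written into the sequence (ATG start, terminal
stop, internal stops cleared), diploid haplotypes with het/hom SNPs and
anchored indels (truth recorded in left-aligned VCF coordinates), and
reads with: uniform fragment positions, normal insert sizes, uniform
haplotype and strand choice, i.i.d. substitution errors, constant Q37
with Q22 at error positions, 3' adapter read-through for short
fragments, and inline 5' barcodes. Everything is deterministic under
its seed (byte equality is tested).

It deliberately does **not** model GC-dependent coverage bias,
platform-specific error profiles, quality decay along the read,
sequencing indel errors (substitution-only by default, to keep the
caller's truth evaluation clean), PCR duplicates, or repetitive genome
structure. Passing the end-to-end tests therefore demonstrates the
pipeline's internal correctness — placement, decoding, statistics,
coordinate conventions — not robustness to real-instrument artifacts.

## Problem sizes and numerical choices

The test suite and acceptance script use a 20 kb single-contig genome
at 50× paired 100 bp coverage (5000 pairs) for the end-to-end truth
check, 6–12 kb genomes at 10–50× for module tests, 1000 random pairs of
length ≤ 12 for the alignment-core cross-check, and all ~1500 tables of
depth ≤ 30 for the p-value check — sizes chosen so the whole suite runs
in a few minutes on one CPU while every claim stays a computation, not
a constant. Alignment-score equality is exact (integer scores);
p-value agreement is required to 1e−9; the stochastic coverage bound
(≥ 90% of bases ≥ 20× at 30×) uses a fixed seed. Degenerate inputs are
defined, not special-cased: empty read sets yield zeroed statistics and
header-only BAMs, empty VCFs round-trip, a window shorter than half the
query is a no-alignment result, and depth-0 p-values are an error
rather than a silent 1.

## Known limitations

No base-quality-aware alignment scoring or recalibration; no local
indel realignment; mapq is a heuristic, not a probability; no somatic
paired mode or CNV detection; the splice model is the 2-base canonical
window only; HGVS strings are unvalidated; the variant store is a
single-writer journal. These match the package's scope — a compact,
fully testable diagnostic pipeline — rather than a production WGS
toolchain.
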