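# Shared low-level helpers: Phred encoding, reverse complement, translation.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual character scalar, Phred+33 encoded.
#' @return integer vector of per-base Phred scores.
#' @export
phred_decode <- function(qual) {
  if (!nzchar(qual)) return(integer(0))
  utf8ToInt(qual) - 33L
}

#' Encode integer Phred scores as a Phred+33 string
#'
#' @param scores integer vector in \[0, 93\].
#' @return character scalar.
#' @export
phred_encode <- function(scores) {
  if (length(scores) == 0) return("")
  if (any(scores < 0L | scores > 93L)) {
    stop("Phred scores must lie in [0, 93]")
  }
  intToUtf8(as.integer(scores) + 33L)
}

#' Reverse-complement DNA sequences
#'
#' Vectorised over `x`; alphabet {A,C,G,T,N}.
#'
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

reverse_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Translate a DNA string (length divisible by 3) to amino acids; stop = "*".
translate_dna <- function(x) {
  if (nchar(x) %% 3 != 0) stop("sequence length not divisible by 3")
  if (nchar(x) == 0) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     if.fuzzy.codon = "X"))
}

codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) "X" else aa
}

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming: unequal lengths")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# cheap data.frame constructor for hot paths (no name/type checking)
quick_df <- function(lst) {
  n <- if (length(lst)) length(lst[[1]]) else 0L
  structure(lst, class = "data.frame", row.names = c(NA_integer_, -n))
}

# VCF-style left-alignment of an anchored indel against its contig sequence;
# SNVs and non-shiftable records are returned unchanged
left_align_variant <- function(contig_seq, pos, ref, alt) {
  if (nchar(ref) == nchar(alt)) return(list(pos = pos, ref = ref, alt = alt))
  repeat {
    changed <- FALSE
    while (nchar(ref) > 0 && nchar(alt) > 0 &&
           substr(ref, nchar(ref), nchar(ref)) ==
             substr(alt, nchar(alt), nchar(alt))) {
      dropped <- substr(ref, nchar(ref), nchar(ref))
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      changed <- TRUE
      if (!nzchar(ref) || !nzchar(alt)) {
        if (pos <= 1L) {  # cannot extend left of the contig; undo
          ref <- paste0(ref, dropped); alt <- paste0(alt, dropped)
          changed <- FALSE
          break
        }
        pos <- pos - 1L
        b <- substr(contig_seq, pos, pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
        break
      }
    }
    while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  list(pos = pos, ref = ref, alt = alt)
}

validate_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T%s} (record %d)",
                 what, if (allow_n) ",N" else "", which(bad)[1]))
  }
  invisible(TRUE)
}
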