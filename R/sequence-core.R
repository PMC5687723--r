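# IUPAC nucleotide alphabet, reverse complement, and the degeneracy-aware
# Hamming distance every other module consumes.
#
# Each IUPAC letter is represented internally as a 4-bit mask over {A,C,G,T};
# two letters "match" iff their base sets intersect, i.e. the bitwise AND of
# their masks is non-zero. All coordinates in the package are 1-based and
# inclusive.

.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

.IUPAC_LETTERS <- names(.IUPAC_BITS)

# lookup table indexed by character code for fast string -> mask conversion
.BITS_BY_CODE <- local({
  tab <- integer(128L)
  tab[utf8ToInt(paste(names(.IUPAC_BITS), collapse = ""))] <- unname(.IUPAC_BITS)
  tab
})

# concrete base for each mask value 1..15: lexicographically first member
.FIRST_BASE <- local({
  out <- character(15L)
  for (i in 1:15) {
    for (b in c("A", "C", "G", "T")) {
      if (bitwAnd(i, .IUPAC_BITS[[b]]) != 0L) { out[i] <- b; break }
    }
  }
  out
})

seq_bits <- function(s) {
  codes <- utf8ToInt(s)
  bad <- codes > 127L
  bits <- integer(length(codes))
  bits[!bad] <- .BITS_BY_CODE[codes[!bad]]
  bits
}

bits_to_seq <- function(bits) {
  intToUtf8(utf8ToInt(paste(.IUPAC_LETTERS, collapse = ""))[match(bits, unname(.IUPAC_BITS))])
}

#' Normalize raw text into an IUPAC nucleotide sequence
#'
#' Uppercases the input, strips whitespace and digits (so sequence blocks
#' pasted from FASTA or GenBank flat files are accepted), and maps U to T.
#' Any residual character outside the 15-letter IUPAC alphabet
#' (`ACGTRYSWKMBDHVN`) is an error naming the character and its position.
#'
#' @param raw A single character string.
#' @return A single uppercase string over the IUPAC alphabet.
#' @examples
#' normalize_sequence("gc at\n1 gatc")
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop_dcaps("invalid_alphabet", "input must be a single character string")
  }
  s <- gsub("[[:space:][:digit:]]", "", toupper(raw))
  if (!nzchar(s)) stop_dcaps("invalid_alphabet", "input contains no sequence characters")
  s <- chartr("U", "T", s)
  bits <- seq_bits(s)
  if (any(bits == 0L)) {
    i <- which(bits == 0L)[1L]
    stop_dcaps("invalid_alphabet", "invalid character '%s' at position %d",
               substr(s, i, i), i)
  }
  s
}

#' Reverse complement of an IUPAC sequence
#'
#' Degenerate codes complement set-wise (R to Y, S to S, W to W, K to M,
#' B to V, D to H, N to N). The operation is an involution.
#'
#' @param s An IUPAC nucleotide string (see [normalize_sequence()]).
#' @return The reverse complement, same length.
#' @examples
#' reverse_complement("GYTT")  # "AARC"
#' @export
reverse_complement <- function(s) {
  if (length(s) != 1L) stop_dcaps("invalid_alphabet", "expected a single string")
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", s)
  intToUtf8(rev(utf8ToInt(comp)))
}

#' Degeneracy-aware Hamming distance
#'
#' Counts the positions at which the IUPAC base sets of the two sequences do
#' not intersect. A degenerate code therefore matches any letter whose set
#' overlaps its own: `GCAT` vs `GYTT` has distance 1 because Y (C/T) matches
#' C. On plain ACGT strings this reduces to the classic Hamming distance.
#'
#' @param a,b IUPAC nucleotide strings of equal length.
#' @return Integer distance in `[0, nchar(a)]`.
#' @examples
#' degenerate_distance("GCAT", "GGTT")  # 2
#' degenerate_distance("GCAT", "GYTT")  # 1
#' @export
degenerate_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop_dcaps("length_mismatch", "sequences differ in length (%d vs %d)",
               nchar(a), nchar(b))
  }
  sum(bitwAnd(seq_bits(a), seq_bits(b)) == 0L)
}

# Vector of mismatch counts of `motif` slid across `subject` (both as bit
# vectors) at every start position 1..length(subject)-length(motif)+1.
slide_mismatch_counts <- function(subject_bits, motif_bits) {
  n <- length(subject_bits)
  m <- length(motif_bits)
  np <- n - m + 1L
  if (np < 1L) return(integer(0L))
  mm <- integer(np)
  for (j in seq_len(m)) {
    mm <- mm + (bitwAnd(subject_bits[j:(j + np - 1L)], motif_bits[j]) == 0L)
  }
  mm
}

# Start positions where `motif_bits` matches exactly (set-intersection at
# every offset) within subject_bits.
exact_match_starts <- function(subject_bits, motif_bits) {
  which(slide_mismatch_counts(subject_bits, motif_bits) == 0L)
}

#' Read sequences from a FASTA file or accept a bare sequence string
#'
#' A convenience reader for the command line: if `x` is a path to an existing
#' file it is parsed as FASTA (one or more records); otherwise `x` itself is
#' treated as a raw sequence. Sequences are normalized.
#'
#' @param x File path or sequence string.
#' @return Named character vector of normalized sequences.
#' @export
read_sequences <- function(x) {
  if (length(x) != 1L || !is.character(x)) {
    stop_dcaps("invalid_alphabet", "expected a single path or sequence string")
  }
  if (!file.exists(x)) {
    return(stats::setNames(normalize_sequence(x), "seq1"))
  }
  lines <- readLines(x, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_dcaps("invalid_alphabet", "empty FASTA file: %s", x)
  if (!startsWith(lines[[1L]], ">")) {
    return(stats::setNames(normalize_sequence(paste(lines, collapse = "")), "seq1"))
  }
  hdr <- grepl("^>", lines)
  rec <- cumsum(hdr)
  names <- sub("^>\\s*", "", lines[hdr])
  names <- vapply(strsplit(names, "\\s+"), `[[`, character(1L), 1L)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, character(1L), collapse = "")
  stats::setNames(vapply(seqs, normalize_sequence, character(1L)), names)
}
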