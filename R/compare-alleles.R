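# Decompose two allele sequences into shared upstream, per-sequence unshared,
# and shared downstream regions. The last base of the shared upstream region
# ("last shared base") anchors the 3' end of every diagnostic primer.

#' Compare two allele sequences
#'
#' Decomposes the two sequences into the longest common prefix (shared
#' upstream region), the longest common suffix of the remainders (shared
#' downstream region), and whatever is left in each sequence (the unshared
#' regions). For a SNP both unshared regions have length 1; for a pure indel
#' one has length 0 and the other the indel length. Matching is
#' degeneracy-aware (IUPAC set intersection). Ambiguity at homopolymers is
#' resolved by maximizing the prefix first, pushing the unshared region as
#' far 3' as possible; when prefix and suffix claims overlap the suffix is
#' truncated (the prefix anchors the primer 3' end, which is what matters
#' downstream).
#'
#' No assumption is made about which sequence is wild type: swapping the
#' inputs swaps the unshared regions and leaves the shared regions unchanged.
#'
#' @param seq1,seq2 Allele sequences (raw text; normalized internally).
#'   Flanks of at least 20 nt on each side of the mutation are recommended;
#'   shorter inputs produce a warning.
#' @param min_flank Flank length below which a warning is issued (default 20).
#' @return An object of class `allele_comparison`: a list with `seq1`,
#'   `seq2`, `shared_upstream`, `unshared1`, `unshared2`,
#'   `shared_downstream`, and `last_shared` (1-based position of the final
#'   upstream shared base; equal in both sequences' coordinates).
#' @export
compare_alleles <- function(seq1, seq2, min_flank = 20L) {
  s1 <- normalize_sequence(seq1)
  s2 <- normalize_sequence(seq2)
  if (identical(s1, s2)) {
    stop_dcaps("identical_sequences", "the two sequences are identical; no assay is needed")
  }
  b1 <- seq_bits(s1); b2 <- seq_bits(s2)
  n1 <- length(b1); n2 <- length(b2)
  k <- min(n1, n2)
  match_fwd <- bitwAnd(b1[seq_len(k)], b2[seq_len(k)]) != 0L
  U <- if (all(match_fwd)) k else which(!match_fwd)[1L] - 1L
  # longest common suffix of the remainders (capped so it cannot reclaim
  # prefix bases: suffix wins only what the prefix left over)
  max_d <- min(n1, n2) - U
  D <- 0L
  if (max_d > 0L) {
    match_rev <- bitwAnd(b1[n1 - seq_len(max_d) + 1L], b2[n2 - seq_len(max_d) + 1L]) != 0L
    D <- if (all(match_rev)) max_d else which(!match_rev)[1L] - 1L
  }
  k1 <- n1 - U - D
  k2 <- n2 - U - D
  if (k1 == 0L && k2 == 0L) {
    stop_dcaps("identical_sequences",
               "sequences are indistinguishable under IUPAC matching; no assay is possible")
  }
  un1 <- substr(s1, U + 1L, U + k1)
  un2 <- substr(s2, U + 1L, U + k2)
  # two separated SNPs masquerading as one variant region: equal-length
  # unshared blocks >1 nt that still agree somewhere in the middle
  if (k1 > 1L && k1 == k2) {
    inner <- bitwAnd(seq_bits(un1), seq_bits(un2)) != 0L
    if (any(inner)) {
      stop_dcaps("multiple_variant_regions",
                 "inputs differ at more than one separated locus; supply one variant region per run")
    }
  }
  if (U == 0L || D == 0L) {
    warn_dcaps("no_shared_flank",
               "a shared flank is empty (%s); primer design on that side is impossible",
               if (U == 0L) "upstream" else "downstream")
  } else if (U < min_flank || D < min_flank) {
    warn_dcaps("short_flank",
               "shared flank shorter than %d nt (upstream %d, downstream %d); assays may be limited",
               min_flank, U, D)
  }
  structure(list(
    seq1 = s1, seq2 = s2,
    shared_upstream = substr(s1, 1L, U),
    unshared1 = un1, unshared2 = un2,
    shared_downstream = if (D > 0L) substr(s1, n1 - D + 1L, n1) else "",
    last_shared = U
  ), class = "allele_comparison")
}

#' @export
print.allele_comparison <- function(x, ...) {
  k1 <- nchar(x$unshared1); k2 <- nchar(x$unshared2)
  kind <- if (k1 == 1L && k2 == 1L) "SNP"
          else if (min(k1, k2) == 0L) sprintf("%d-bp indel", abs(k1 - k2))
          else sprintf("complex variant (%d vs %d nt)", k1, k2)
  cat("Allele comparison:", kind, "\n")
  cat(sprintf("  shared upstream : %d nt (last shared base at position %d)\n",
              nchar(x$shared_upstream), x$last_shared))
  cat(sprintf("  unshared        : '%s' (seq1) | '%s' (seq2)\n", x$unshared1, x$unshared2))
  cat(sprintf("  shared downstream: %d nt\n", nchar(x$shared_downstream)))
  invisible(x)
}
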