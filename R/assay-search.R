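# Scan a pair of decomposed alleles for restriction motifs that can
# discriminate them: CAPS sites directly, dCAPS sites via primer mismatches.
# Two constraints govern every candidate: primers must lie wholly in the
# shared region, and a putative site must overlap both the shared and the
# unshared region (a site fully inside one allele's unshared region is a
# plain CAPS site and is also accepted). Scanning runs on the inputs as
# given and on their reverse complements.

# Motif alignments to try: the motif itself, plus its reverse complement
# when that is a different string.
motif_variants <- function(motif) {
  rc <- reverse_complement(motif)
  if (identical(rc, motif)) {
    list(list(seq = motif, bits = seq_bits(motif), strand = "+"))
  } else {
    list(list(seq = motif, bits = seq_bits(motif), strand = "+"),
         list(seq = rc, bits = seq_bits(rc), strand = "-"))
  }
}

# Exact (degeneracy-aware) occurrences of an enzyme's motif on either strand:
# data frame of start, end, strand.
exact_sites <- function(subject_bits, variants) {
  out <- lapply(variants, function(v) {
    p <- exact_match_starts(subject_bits, v$bits)
    if (!length(p)) return(NULL)
    data.frame(start = p, end = p + length(v$bits) - 1L, strand = v$strand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(start = integer(), end = integer(),
                               strand = character(), stringsAsFactors = FALSE)
  else out
}

.empty_candidates <- function() {
  out <- data.frame(
    enzyme = character(), motif = character(), orientation = character(),
    cleaved_allele = character(), scanned_allele = integer(),
    motif_start = integer(), motif_strand = character(),
    mismatch_count = integer(), is_caps = logical(),
    overlap_shared = integer(), overlap_unshared = integer(),
    stringsAsFactors = FALSE
  )
  out$mismatch_positions <- list()
  out$patch_bases <- list()
  class(out) <- c("candidate_assays", "data.frame")
  out
}

# Scan one oriented, decomposed pair for sites cleaving allele "a".
# Sa/Sb: full oriented sequences; U: last shared base; ka/kb: unshared
# lengths. Returns a list of candidate rows.
.scan_one_allele <- function(Sa, Sb, U, ka, kb, enzyme_row, max_mismatch,
                             amplicon_len, orientation, allele_a) {
  Sa_bits <- seq_bits(Sa); Sb_bits <- seq_bits(Sb)
  len_a <- length(Sa_bits); len_b <- length(Sb_bits)
  variants <- motif_variants(enzyme_row$motif)
  rows <- list()
  for (v in variants) {
    m <- length(v$bits)
    lo <- max(1L, U + 2L - m)
    hi <- min(if (ka > 0L) U + ka else U, len_a - m + 1L)
    if (hi < lo) next
    counts <- slide_mismatch_counts(Sa_bits, v$bits)
    for (p in lo:hi) {
      if (counts[p] > max_mismatch) next
      offs <- which(bitwAnd(Sa_bits[p:(p + m - 1L)], v$bits) == 0L)
      mm_pos <- p + offs - 1L
      if (length(mm_pos) && any(mm_pos > U)) next  # not patchable by a primer
      patches <- .FIRST_BASE[v$bits[offs]]
      # apply patches to the other allele (patched positions are shared)
      Sbp <- Sb_bits
      if (length(mm_pos)) Sbp[mm_pos] <- unname(.IUPAC_BITS[patches])
      hits_b <- exact_sites(Sbp, variants)
      near_b <- hits_b[hits_b$end >= U + 1L &
                         hits_b$start <= (if (kb > 0L) U + kb else U), , drop = FALSE]
      cleaved <- as.character(allele_a)
      if (nrow(near_b) > 0L) {
        # both alleles carry a site near the junction: only keep the assay
        # when the two digests are distinguishable on a gel (>= 5 bp band
        # difference); otherwise the candidate is useless
        if (is.na(enzyme_row$cut_top)) next
        Sap <- Sa_bits
        if (length(mm_pos)) Sap[mm_pos] <- unname(.IUPAC_BITS[patches])
        a_start <- max(1L, U - 35L)
        amp_a <- bits_to_seq(Sap[a_start:min(len_a, U + amplicon_len)])
        amp_b <- bits_to_seq(Sbp[a_start:min(len_b, U + amplicon_len)])
        ok <- !is_concrete(amp_a) || !is_concrete(amp_b)
        if (ok) next
        fr <- tryCatch(list(a = predict_fragments(amp_a, enzyme_row),
                            b = predict_fragments(amp_b, enzyme_row)),
                       dcaps_error = function(e) NULL)
        if (is.null(fr) || gel_equivalent(fr$a, fr$b)) next
        cleaved <- "both_differently"
      }
      ov_sh <- max(0L, min(p + m - 1L, U) - p + 1L)
      ov_un <- if (ka > 0L) max(0L, min(p + m - 1L, U + ka) - max(p, U + 1L) + 1L) else 0L
      row <- data.frame(
        enzyme = enzyme_row$name, motif = v$seq, orientation = orientation,
        cleaved_allele = cleaved, scanned_allele = allele_a,
        motif_start = p, motif_strand = v$strand,
        mismatch_count = length(mm_pos), is_caps = length(mm_pos) == 0L,
        overlap_shared = ov_sh, overlap_unshared = ov_un,
        stringsAsFactors = FALSE
      )
      row$mismatch_positions <- list(mm_pos)
      row$patch_bases <- list(patches)
      rows[[length(rows) + 1L]] <- row
    }
  }
  rows
}

is_concrete <- function(s) all(seq_bits(s) %in% c(1L, 2L, 4L, 8L))

# Two fragment multisets are gel-equivalent when they have the same number of
# bands and every sorted band differs by less than `resolution` bp.
gel_equivalent <- function(f1, f2, resolution = 5L) {
  if (length(f1) != length(f2)) return(FALSE)
  all(abs(sort(f1) - sort(f2)) < resolution)
}

#' Scan for candidate CAPS/dCAPS assays
#'
#' For every enzyme, every alignment of its motif (and of the
#' reverse-complement motif when non-palindromic) against a window around
#' the last shared base of each allele is scored with the degeneracy-aware
#' distance. A position is a candidate when the distance to one allele is at
#' most `max_mismatch`, every mismatching base lies in the shared upstream
#' region (so a primer can patch it), and the completed site is absent from
#' the corresponding region of the other allele. Both input orientations are
#' scanned. Candidates are sorted by mismatch count, enzyme name, then
#' position.
#'
#' @param cmp An [compare_alleles()] result.
#' @param enzymes An `enzyme_table` (default: packaged catalogue).
#' @param max_mismatch Maximum engineered primer mismatches (default 1).
#' @param amplicon_len Amplicon window, used only to bound the fragment
#'   comparison for sites present in both alleles (default 150).
#' @return A `candidate_assays` data frame; zero rows is a legal result.
#' @export
scan_assays <- function(cmp, enzymes = load_enzymes(), max_mismatch = 1L,
                        amplicon_len = 150L) {
  stopifnot(inherits(cmp, "allele_comparison"), max_mismatch >= 0L)
  cmp_rev <- reverse_comparison(cmp)
  rows <- list()
  for (ctx in list(list(cmp = cmp, orientation = "forward"),
                   list(cmp = cmp_rev, orientation = "reverse_complement"))) {
    cc <- ctx$cmp
    U <- cc$last_shared
    k1 <- nchar(cc$unshared1); k2 <- nchar(cc$unshared2)
    for (i in seq_len(nrow(enzymes))) {
      e <- enzymes[i, , drop = FALSE]
      rows <- c(rows,
                .scan_one_allele(cc$seq1, cc$seq2, U, k1, k2, e, max_mismatch,
                                 amplicon_len, ctx$orientation, 1L),
                .scan_one_allele(cc$seq2, cc$seq1, U, k2, k1, e, max_mismatch,
                                 amplicon_len, ctx$orientation, 2L))
    }
  }
  if (!length(rows)) return(.empty_candidates())
  out <- do.call(rbind, rows)
  out <- out[order(out$mismatch_count, out$enzyme, out$motif_start,
                   out$scanned_allele, out$orientation, out$motif_strand,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_assays", "data.frame")
  out
}

# The same decomposition viewed from the other end: reverse-complement both
# sequences and re-decompose (prefix maximization then applies to what was
# the downstream flank).
reverse_comparison <- function(cmp) {
  suppressWarnings(compare_alleles(reverse_complement(cmp$seq1),
                                   reverse_complement(cmp$seq2)))
}

#' Reject candidates whose enzyme cuts the shared downstream region
#'
#' An enzyme with an exact site in the shared downstream region (within
#' `amplicon_len` of the primer anchor) would cut both alleles' amplicons and
#' muddy the diagnostic digest; such candidates are removed. Rejection uses
#' exact matches only. When the supplied sequence is shorter than the
#' amplicon window, the entire remaining sequence is examined and the
#' surviving candidate carries a `truncated_window` flag so the report can
#' warn that bases beyond the submitted sequence were not checked.
#'
#' @param candidates A `candidate_assays` data frame.
#' @param cmp The [compare_alleles()] result the candidates came from.
#' @param amplicon_len Amplicon window in nt, measured downstream from the
#'   primer 3' anchor (default 150).
#' @return The filtered `candidate_assays` with a `truncated_window` column.
#' @export
reject_downstream_cutters <- function(candidates, cmp, amplicon_len = 150L) {
  if (!nrow(candidates)) {
    candidates$truncated_window <- logical(0L)
    return(candidates)
  }
  cmp_rev <- reverse_comparison(cmp)
  keep <- logical(nrow(candidates))
  truncated <- logical(nrow(candidates))
  enz_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(candidates))) {
    row <- candidates[i, , drop = FALSE]
    cc <- if (row$orientation == "forward") cmp else cmp_rev
    Sa <- if (row$scanned_allele == 1L) cc$seq1 else cc$seq2
    ka <- nchar(if (row$scanned_allele == 1L) cc$unshared1 else cc$unshared2)
    U <- cc$last_shared
    len_a <- nchar(Sa)
    ds_lo <- U + ka + 1L
    win_hi <- min(len_a, U + amplicon_len)
    truncated[i] <- len_a < U + amplicon_len
    key <- paste0(row$motif, "|", row$orientation, "|", row$scanned_allele)
    hits <- if (!is.null(enz_cache[[key]])) enz_cache[[key]] else {
      h <- exact_sites(seq_bits(Sa), motif_variants(row$motif))
      enz_cache[[key]] <- h
      h
    }
    downstream <- hits[hits$start >= ds_lo & hits$end <= win_hi, , drop = FALSE]
    keep[i] <- nrow(downstream) == 0L
  }
  out <- candidates[keep, , drop = FALSE]
  out$truncated_window <- truncated[keep]
  rownames(out) <- NULL
  class(out) <- c("candidate_assays", "data.frame")
  out
}

#' Predict restriction fragment lengths
#'
#' Cuts the amplicon at the top-strand cleavage bond of every exact motif
#' occurrence on either strand and returns the fragment lengths 5' to 3'.
#' Fragment lengths always sum to the amplicon length; an amplicon with no
#' site yields a single fragment.
#'
#' @param amplicon A concrete (non-degenerate) nucleotide sequence.
#' @param enzyme A single-row `enzyme_table` slice (or a list with `motif`,
#'   `cut_top`, `cut_bottom`).
#' @return Integer vector of fragment lengths.
#' @export
predict_fragments <- function(amplicon, enzyme) {
  amplicon <- normalize_sequence(amplicon)
  if (!is_concrete(amplicon)) {
    stop_dcaps("degenerate_amplicon", "amplicon contains degenerate bases")
  }
  if (is.na(enzyme$cut_top)) {
    stop_dcaps("unknown_cut_offset",
               "enzyme %s has no cut offsets; presence/absence calls only",
               enzyme$name)
  }
  bits <- seq_bits(amplicon)
  len <- length(bits)
  m <- nchar(enzyme$motif)
  variants <- motif_variants(enzyme$motif)
  bonds <- integer(0L)
  for (v in variants) {
    starts <- exact_match_starts(bits, v$bits)
    if (!length(starts)) next
    if (v$strand == "+") {
      bonds <- c(bonds, starts - 1L + enzyme$cut_top)
    } else {
      if (is.na(enzyme$cut_bottom)) {
        stop_dcaps("unknown_cut_offset",
                   "enzyme %s: bottom-strand cut offset unknown", enzyme$name)
      }
      bonds <- c(bonds, starts - 1L + m - enzyme$cut_bottom)
    }
  }
  bonds <- sort(unique(bonds[bonds >= 1L & bonds <= len - 1L]))
  diff(c(0L, bonds, len))
}

#' @export
print.candidate_assays <- function(x, ...) {
  cat(sprintf("%d candidate assay(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- as.data.frame(x)[, c("enzyme", "motif", "orientation",
                                 "cleaved_allele", "motif_start",
                                 "mismatch_count", "is_caps")]
    print(utils::head(show, 20L), ...)
    if (nrow(x) > 20L) cat(sprintf("... and %d more\n", nrow(x) - 20L))
  }
  invisible(x)
}
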