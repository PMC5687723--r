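# Rule-based audit of a primer/enzyme/allele-pair combination: simulate the
# amplicon the primer would generate from each allele and decide whether the
# pair could be distinguished on a gel, and whether the PCR would plausibly
# work at all. Categories:
#   non_productive — no diagnostic digest exists (no site, or fragment
#                    patterns a gel cannot separate);
#   problematic    — a diagnostic digest exists but the primer has an
#                    amplification defect (3'-terminal mismatch, alignment
#                    gap, excessive mismatches);
#   productive     — diagnostic and free of amplification defects.

#' Classification policy
#'
#' @param max_scan_mismatches Beyond this many mismatches at the best
#'   ungapped placement the primer is considered unlocatable unless a gapped
#'   placement explains it (default 5).
#' @param gap_trigger Ungapped mismatch count above which a gapped check is
#'   attempted and, failing that, the mismatches count as excessive
#'   (default 3).
#' @param allow_3prime_GT Ignore a 3'-terminal G/T mispairing (default
#'   `FALSE`).
#' @param amplicon_len Simulated amplicon window (default 150).
#' @param gel_resolution Minimum band difference, bp, a gel resolves
#'   (default 5).
#' @return A list of class `classify_policy`.
#' @export
classify_policy <- function(max_scan_mismatches = 5L, gap_trigger = 3L,
                            allow_3prime_GT = FALSE, amplicon_len = 150L,
                            gel_resolution = 5L) {
  structure(list(max_scan_mismatches = as.integer(max_scan_mismatches),
                 gap_trigger = as.integer(gap_trigger),
                 allow_3prime_GT = isTRUE(allow_3prime_GT),
                 amplicon_len = as.integer(amplicon_len),
                 gel_resolution = as.integer(gel_resolution)),
            class = "classify_policy")
}

# Best ungapped placement of a primer on a template (one strand):
# list(start, mismatches, offsets). Ties resolve to the leftmost placement.
.best_placement <- function(template_bits, primer_bits) {
  counts <- slide_mismatch_counts(template_bits, primer_bits)
  if (!length(counts)) return(NULL)
  p <- which.min(counts)
  offs <- which(bitwAnd(template_bits[p:(p + length(primer_bits) - 1L)],
                        primer_bits) == 0L)
  list(start = p, mismatches = counts[p], offsets = offs)
}

# Gapped sanity check: do the primer halves place consistently, or do their
# best placements imply an insertion/deletion between them?
.implies_gap <- function(template_bits, primer_bits) {
  n <- length(primer_bits)
  if (n < 12L) return(FALSE)
  half <- n %/% 2L
  p1 <- .best_placement(template_bits, primer_bits[1:half])
  p2 <- .best_placement(template_bits, primer_bits[(half + 1L):n])
  if (is.null(p1) || is.null(p2)) return(FALSE)
  if (p1$mismatches > 1L || p2$mismatches > 1L) return(FALSE)
  shift <- p2$start - (p1$start + half)
  shift != 0L && abs(shift) <= 10L
}

#' Classify a primer/enzyme/allele-pair combination
#'
#' Places the primer on each allele (both strands, best ungapped placement),
#' substitutes it to build the simulated amplicons, digests both in silico,
#' and assigns `productive`, `problematic`, or `non_productive` with reason
#' tags (`no_diagnostic_site`, `indistinguishable_fragments`,
#' `terminal_3prime_mismatch`, `alignment_gap`, `excessive_mismatches`).
#'
#' @param primer Concrete primer sequence, 5' to 3'.
#' @param enzyme Single-row `enzyme_table` slice.
#' @param allele1,allele2 The two allele sequences.
#' @param policy A [classify_policy()].
#' @return A list of class `assay_verdict` with `category`, `reasons`, and
#'   per-allele placement/fragment details.
#' @export
classify_assay <- function(primer, enzyme, allele1, allele2,
                           policy = classify_policy()) {
  primer <- normalize_sequence(primer)
  if (!is_concrete(primer)) {
    stop_dcaps("degenerate_base_in_primer", "primer must be concrete")
  }
  pb <- seq_bits(primer)
  n <- length(pb)
  alleles <- list(normalize_sequence(allele1), normalize_sequence(allele2))
  placements <- vector("list", 2L)
  reasons <- character(0L)
  for (i in 1:2) {
    # try the primer against the template as given and reverse-complemented;
    # keep the better orientation
    best <- NULL
    for (orient in c("forward", "reverse_complement")) {
      s <- if (orient == "forward") alleles[[i]] else reverse_complement(alleles[[i]])
      pl <- .best_placement(seq_bits(s), pb)
      if (!is.null(pl) && (is.null(best) || pl$mismatches < best$mismatches)) {
        best <- c(pl, list(orientation = orient, template = s))
      }
    }
    if (is.null(best)) stop_dcaps("primer_not_locatable", "primer longer than allele %d", i)
    if (best$mismatches > policy$gap_trigger) {
      if (.implies_gap(seq_bits(best$template), pb)) {
        reasons <- c(reasons, "alignment_gap")
      } else if (best$mismatches > policy$max_scan_mismatches) {
        stop_dcaps("primer_not_locatable",
                   "primer does not place on allele %d (best %d mismatches)",
                   i, best$mismatches)
      } else {
        reasons <- c(reasons, "excessive_mismatches")
      }
    }
    # 3'-terminal mismatch against this template?
    if (n %in% best$offsets) {
      t_chr <- substr(best$template, best$start + n - 1L, best$start + n - 1L)
      gt <- setequal(c(substr(primer, n, n), .complement_base(t_chr)), c("G", "T"))
      if (!(policy$allow_3prime_GT && gt)) {
        reasons <- c(reasons, "terminal_3prime_mismatch")
      }
    }
    placements[[i]] <- best
  }
  # simulated amplicons: primer substituted at its footprint
  amplicons <- vapply(placements, function(pl) {
    tb <- seq_bits(pl$template)
    tb[pl$start:(pl$start + n - 1L)] <- pb
    hi <- min(length(tb), pl$start + policy$amplicon_len - 1L)
    bits_to_seq(tb[pl$start:hi])
  }, character(1L))
  diag <- .diagnostic_digest(amplicons[[1L]], amplicons[[2L]], enzyme, policy)
  reasons <- unique(c(reasons, diag$reasons))
  category <- if (any(c("no_diagnostic_site", "indistinguishable_fragments") %in% reasons)) {
    "non_productive"
  } else if (any(c("terminal_3prime_mismatch", "alignment_gap",
                   "excessive_mismatches") %in% reasons)) {
    "problematic"
  } else {
    "productive"
  }
  structure(list(category = category, reasons = reasons,
                 placements = placements, amplicons = amplicons,
                 fragments = diag$fragments),
            class = "assay_verdict")
}

.diagnostic_digest <- function(amp1, amp2, enzyme, policy) {
  if (!is_concrete(amp1) || !is_concrete(amp2) || is.na(enzyme$cut_top)) {
    # fall back to presence/absence of an exact site
    v <- motif_variants(enzyme$motif)
    cut1 <- nrow(exact_sites(seq_bits(amp1), v)) > 0L
    cut2 <- nrow(exact_sites(seq_bits(amp2), v)) > 0L
    reasons <- if (cut1 == cut2) "no_diagnostic_site" else character(0L)
    return(list(reasons = reasons, fragments = NULL))
  }
  f1 <- predict_fragments(amp1, enzyme)
  f2 <- predict_fragments(amp2, enzyme)
  cut1 <- length(f1) > 1L; cut2 <- length(f2) > 1L
  reasons <- if (!cut1 && !cut2) {
    "no_diagnostic_site"
  } else if (cut1 && cut2 && gel_equivalent(f1, f2, policy$gel_resolution)) {
    "indistinguishable_fragments"
  } else if (cut1 != cut2 &&
             gel_equivalent(f1, f2, policy$gel_resolution)) {
    "indistinguishable_fragments"  # unreachable guard; lengths differ
  } else {
    character(0L)
  }
  list(reasons = reasons, fragments = list(allele1 = f1, allele2 = f2))
}

#' @export
print.assay_verdict <- function(x, ...) {
  cat("Assay verdict:", x$category, "\n")
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  if (!is.null(x$fragments)) {
    cat("  fragments allele1:", paste(x$fragments$allele1, collapse = " + "), "bp\n")
    cat("  fragments allele2:", paste(x$fragments$allele2, collapse = " + "), "bp\n")
  }
  invisible(x)
}
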