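# Turn a candidate assay into a concrete oligonucleotide: 3' end anchored at
# the last shared base, bases under the motif footprint patched to complete
# the recognition site on the cleaved allele, spurious exact sites under the
# primer disrupted with additional mismatches, the whole thing kept inside
# the shared upstream region and inside the mismatch budget.

#' Primer design options
#'
#' @param mode `"target_tm"` (default) extends the primer 5' between
#'   `min_length` and `max_length` nt and returns the length whose melting
#'   temperature is closest to `target_tm` (ties break toward the shorter
#'   primer); `"fixed_length"` returns exactly `length` nt.
#' @param target_tm Target melting temperature in Celsius (default 60).
#' @param length Primer length for `fixed_length` mode (default 25).
#' @param max_mismatch Total mismatch budget, engineered patches plus
#'   disruptions (default 1).
#' @param allow_3prime_GT Accept a 3'-terminal mismatch when the mispaired
#'   duplex bases are G and T (default `FALSE`: any 3' mismatch rejects the
#'   design).
#' @param min_length,max_length Search bounds for `target_tm` mode
#'   (defaults 18 and 36 nt, standard oligo practice).
#' @param tm A [tm_parameters()] object.
#' @return A list of class `primer_options`.
#' @export
primer_options <- function(mode = c("target_tm", "fixed_length"),
                           target_tm = 60, length = 25L, max_mismatch = 1L,
                           allow_3prime_GT = FALSE,
                           min_length = 18L, max_length = 36L,
                           tm = tm_parameters()) {
  mode <- match.arg(mode)
  structure(list(mode = mode, target_tm = target_tm, length = as.integer(length),
                 max_mismatch = as.integer(max_mismatch),
                 allow_3prime_GT = isTRUE(allow_3prime_GT),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length), tm = tm),
            class = "primer_options")
}

# Oriented sequences and decomposition for one candidate row.
.oriented_context <- function(cmp, row) {
  cc <- if (row$orientation == "forward") cmp else reverse_comparison(cmp)
  a <- row$scanned_allele
  list(
    Sa = if (a == 1L) cc$seq1 else cc$seq2,
    Sb = if (a == 1L) cc$seq2 else cc$seq1,
    ka = nchar(if (a == 1L) cc$unshared1 else cc$unshared2),
    kb = nchar(if (a == 1L) cc$unshared2 else cc$unshared1),
    U = cc$last_shared
  )
}

.complement_base <- function(b) chartr("ACGT", "TGCA", b)

# Replacement bases to try when disrupting a site: transversions of the
# current base first, then the transition, each lexicographically ordered.
.disruption_order <- function(base) {
  purine <- c("A", "G"); pyrimidine <- c("C", "T")
  others <- setdiff(c("A", "C", "G", "T"), base)
  trv <- if (base %in% purine) intersect(others, pyrimidine) else intersect(others, purine)
  c(trv, setdiff(others, trv))
}

#' Build the core of a diagnostic primer
#'
#' Anchors the 3' end at the last shared base and patches every mismatching
#' base under the motif footprint so the recognition site is completed on
#' the cleaved allele. The returned core spans only from the 5'-most patched
#' base (or the anchor itself for CAPS candidates); [extend_primer()] grows
#' it to a usable oligo.
#'
#' @param assay A single-row slice of a `candidate_assays` frame.
#' @param cmp The [compare_alleles()] result the assay came from.
#' @param opts A [primer_options()] object.
#' @return A list of class `primer_core`.
#' @export
build_primer <- function(assay, cmp, opts = primer_options()) {
  ctx <- .oriented_context(cmp, assay)
  if (assay$mismatch_count > opts$max_mismatch) {
    stop_dcaps("mismatch_budget_exceeded",
               "assay needs %d mismatches, budget is %d",
               assay$mismatch_count, opts$max_mismatch)
  }
  U <- ctx$U
  mm_pos <- assay$mismatch_positions[[1L]]
  patches <- assay$patch_bases[[1L]]
  if (length(mm_pos) && any(mm_pos > U)) {
    stop_dcaps("primer_outside_shared_region",
               "a required mismatch lies outside the shared upstream region")
  }
  # 3'-terminal mismatch policy
  if (U %in% mm_pos) {
    b <- patches[match(U, mm_pos)]
    t_chr <- substr(ctx$Sa, U, U)
    gt <- setequal(c(b, .complement_base(t_chr)), c("G", "T"))
    if (!(opts$allow_3prime_GT && gt)) {
      stop_dcaps("terminal_mismatch_rejected",
                 "3'-terminal mismatch (%s over template %s) is rejected%s",
                 b, t_chr,
                 if (opts$allow_3prime_GT) " (not a G/T pairing)" else "")
    }
  }
  core_start <- if (length(mm_pos)) min(mm_pos) else U
  structure(list(assay = assay, ctx = ctx, core_start = core_start,
                 anchor_3prime = U, mismatch_positions = mm_pos,
                 patch_bases = patches), class = "primer_core")
}

#' Extend a primer core to a reportable oligonucleotide
#'
#' Extends 5' from the anchor, disrupting any spurious exact occurrence of
#' the assay's motif that falls wholly under the primer footprint with one
#' additional mismatch each (preferring transversions that create no new
#' site for any catalogue enzyme under the primer), keeping the total
#' mismatch count within budget, and verifying the definitional dCAPS
#' invariant: the primer substituted into the cleaved allele creates an
#' exact site at the diagnostic position, substituted into the other allele
#' it creates none.
#'
#' @param core A [build_primer()] result.
#' @param cmp The originating [compare_alleles()] result.
#' @param opts A [primer_options()] object.
#' @param enzymes Catalogue used for the no-new-site preference (default:
#'   packaged catalogue).
#' @return A list of class `primer_design`.
#' @export
extend_primer <- function(core, cmp, opts = primer_options(),
                          enzymes = load_enzymes()) {
  ctx <- core$ctx
  assay <- core$assay
  U <- ctx$U
  cover <- U - core$core_start + 1L
  if (opts$mode == "fixed_length") {
    if (opts$length > U) {
      stop_dcaps("shared_region_too_short",
                 "requested length %d exceeds the %d-nt shared upstream region",
                 opts$length, U)
    }
    if (opts$length < cover) {
      stop_dcaps("primer_outside_shared_region",
                 "requested length %d cannot cover the patched position at %d",
                 opts$length, core$core_start)
    }
    lengths <- opts$length
  } else {
    lo <- max(opts$min_length, cover)
    hi <- min(opts$max_length, U)
    if (hi < lo) {
      stop_dcaps("shared_region_too_short",
                 "shared upstream region (%d nt) cannot host an %d-%d nt primer",
                 U, opts$min_length, opts$max_length)
    }
    lengths <- lo:hi
  }
  best <- NULL; best_score <- Inf; first_failure <- NULL
  for (L in lengths) {
    cand <- tryCatch(
      .finalize_primer(assay, ctx, U, L, core$mismatch_positions,
                       core$patch_bases, opts, enzymes),
      dcaps_error = function(e) e
    )
    if (inherits(cand, "dcaps_error")) {
      if (is.null(first_failure)) first_failure <- cand
      next
    }
    score <- if (opts$mode == "target_tm") abs(cand$tm_celsius - opts$target_tm) else 0
    if (score < best_score - 1e-9) { best <- cand; best_score <- score }
    # ties break toward the shorter primer: lengths ascend, strict improvement required
  }
  if (is.null(best)) {
    if (!is.null(first_failure)) stop(first_failure)
    stop_dcaps("shared_region_too_short", "no viable primer length")
  }
  best
}

# Assemble and validate one primer at one concrete length.
.finalize_primer <- function(assay, ctx, U, L, mm_pos, patches, opts, enzymes) {
  start <- U - L + 1L
  Sa_bits <- seq_bits(ctx$Sa)
  Sb_bits <- seq_bits(ctx$Sb)
  work <- Sa_bits
  if (length(mm_pos)) work[mm_pos] <- unname(.IUPAC_BITS[patches])
  warnings <- character(0L)
  # concretize degenerate template bases under the primer (not mismatches:
  # the oligo simply commits to one member of the user's ambiguity set)
  amb <- which(!(work[start:U] %in% c(1L, 2L, 4L, 8L))) + start - 1L
  amb <- setdiff(amb, mm_pos)
  if (length(amb)) {
    work[amb] <- unname(.IUPAC_BITS[.FIRST_BASE[work[amb]]])
    warnings <- c(warnings, sprintf(
      "degenerate template base(s) at %s concretized in the primer",
      paste(amb, collapse = ",")))
  }
  variants <- motif_variants(assay$motif)
  all_mm <- mm_pos
  diag_fp <- assay$motif_start:(assay$motif_start + nchar(assay$motif) - 1L)
  # iteratively disrupt spurious exact sites wholly under the primer
  for (iter in 1:5) {
    occ <- exact_sites(work[start:U], variants)
    if (!nrow(occ)) break
    occ$start <- occ$start + start - 1L
    occ$end <- occ$end + start - 1L
    # every site wholly inside [start, U] is spurious (the diagnostic site
    # always reaches past the anchor into the unshared region)
    if (!nrow(occ)) break
    o <- occ[1L, ]
    hit <- .disrupt_site(work, o, start, U, all_mm, diag_fp, variants, enzymes)
    if (is.null(hit)) {
      stop_dcaps("mismatch_budget_exceeded",
                 "cannot disrupt a spurious %s site at %d under the primer",
                 assay$enzyme, o$start)
    }
    work[hit$pos] <- unname(.IUPAC_BITS[hit$base])
    all_mm <- sort(c(all_mm, hit$pos))
  }
  if (length(all_mm) > opts$max_mismatch) {
    stop_dcaps("mismatch_budget_exceeded",
               "%d mismatches needed, budget is %d", length(all_mm), opts$max_mismatch)
  }
  primer <- bits_to_seq(work[start:U])
  # definitional validation: site on the cleaved allele, none on the other
  amp_a <- Sa_bits; amp_a[start:U] <- work[start:U]
  ok_a <- any(vapply(variants, function(v)
    assay$motif_start %in% exact_match_starts(amp_a, v$bits), logical(1L)))
  if (!ok_a) {
    stop_dcaps("mismatch_budget_exceeded",
               "disruption destroyed the diagnostic site")  # defensive; not expected
  }
  amp_b <- Sb_bits
  amp_b[start:U] <- work[start:U]
  hits_b <- exact_sites(amp_b, variants)
  kb <- ctx$kb
  near_b <- hits_b[hits_b$end >= U + 1L &
                     hits_b$start <= (if (kb > 0L) U + kb else U), , drop = FALSE]
  # "wt" marks screening mode, where Sb is the wild type itself and the
  # per-event validation happens in the caller
  if (!(assay$cleaved_allele %in% c("both_differently", "wt")) && nrow(near_b) > 0L) {
    stop_dcaps("mismatch_budget_exceeded",
               "patched site is not absent from the other allele")
  }
  tm <- melting_temperature(primer, opts$tm)
  structure(list(
    sequence = primer, length = L, start = start, anchor_3prime = U,
    mismatch_positions = all_mm - start + 1L, mismatch_count = length(all_mm),
    tm_celsius = tm, enzyme = assay$enzyme, motif = assay$motif,
    motif_start = assay$motif_start, motif_strand = assay$motif_strand,
    orientation = assay$orientation, cleaved_allele = assay$cleaved_allele,
    scanned_allele = assay$scanned_allele, is_caps = assay$is_caps,
    warnings = warnings
  ), class = "primer_design")
}

# Pick (position, base) disrupting occurrence `o`. Prefers a substitution
# creating no new exact site, for any catalogue enzyme, under the primer.
.disrupt_site <- function(work, o, start, U, all_mm, diag_fp, variants, enzymes) {
  cand_pos <- setdiff(o$start:o$end, c(all_mm, diag_fp, U))
  cand_pos <- cand_pos[cand_pos >= start & cand_pos < U]
  if (!length(cand_pos)) return(NULL)
  occ_bits <- if (o$strand == "+") variants[[1L]]$bits else variants[[length(variants)]]$bits
  fallback <- NULL
  cat_variants <- lapply(enzymes$motif, motif_variants)
  for (pos in cand_pos) {
    off <- pos - o$start + 1L
    for (base in .disruption_order(bits_to_seq(work[pos]))) {
      if (bitwAnd(.IUPAC_BITS[[base]], occ_bits[off]) != 0L) next  # does not break the site
      trial <- work
      trial[pos] <- .IUPAC_BITS[[base]]
      win <- trial[start:U]
      creates <- FALSE
      for (vs in cat_variants) {
        for (v in vs) {
          st <- exact_match_starts(win, v$bits)
          if (length(st)) {
            st_abs <- st + start - 1L
            new_only <- setdiff(st_abs, exact_match_starts(work[start:U], v$bits) + start - 1L)
            if (any(pos >= new_only & pos <= new_only + length(v$bits) - 1L)) {
              creates <- TRUE; break
            }
          }
        }
        if (creates) break
      }
      if (!creates) return(list(pos = pos, base = base))
      if (is.null(fallback)) fallback <- list(pos = pos, base = base)
    }
  }
  fallback
}

#' Design a primer for a candidate assay
#'
#' Convenience wrapper: [build_primer()] then [extend_primer()].
#'
#' @inheritParams build_primer
#' @param enzymes Catalogue for the disruption no-new-site check.
#' @return A `primer_design` object.
#' @export
design_primer <- function(assay, cmp, opts = primer_options(),
                          enzymes = load_enzymes()) {
  extend_primer(build_primer(assay, cmp, opts), cmp, opts, enzymes)
}

#' @export
print.primer_design <- function(x, ...) {
  cat(sprintf("Primer (%s, %s): 5'-%s-3'\n", x$enzyme, x$orientation, x$sequence))
  cat(sprintf("  length %d nt, Tm %.1f C, %d mismatch(es)%s\n",
              x$length, x$tm_celsius, x$mismatch_count,
              if (x$mismatch_count)
                paste0(" at primer position(s) ",
                       paste(x$mismatch_positions, collapse = ",")) else ""))
  cat(sprintf("  cleaves allele %s via %s (%s)\n", x$cleaved_allele, x$enzyme, x$motif))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}
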