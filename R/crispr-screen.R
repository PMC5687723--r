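# Screening mode: before any editing outcome is known, simulate the indel
# spectrum at a Cas9 cut site, find the last base the wild type shares with
# every simulated variant, and design assays whose site is cleaved in wild
# type but destroyed by the edits. The simplifying assumption throughout:
# cleavage occurs in wild type and is disrupted in mutants.

#' An editing-event profile
#'
#' The default profile holds the five single-base events: insertion of each
#' of A, C, G, T at the cut bond and deletion of the base immediately 5' of
#' it, with equal weights (0.2 each). Custom profiles may use any insertion
#' payloads and deletion lengths; weights are normalized to sum to 1.
#'
#' @param kind Character vector, each `"insertion"` or `"deletion"`.
#' @param payload For insertions the inserted base(s); for deletions the
#'   deletion length.
#' @param weight Numeric event weights (normalized internally).
#' @return A data frame of class `edit_profile`.
#' @export
edit_profile <- function(kind = c(rep("insertion", 4L), "deletion"),
                         payload = c("A", "C", "G", "T", "1"),
                         weight = rep(1 / 5, 5L)) {
  stopifnot(length(kind) == length(payload), length(kind) == length(weight),
            all(kind %in% c("insertion", "deletion")), all(weight > 0))
  out <- data.frame(kind = kind, payload = as.character(payload),
                    weight = weight / sum(weight), stringsAsFactors = FALSE)
  class(out) <- c("edit_profile", "data.frame")
  out
}

#' Locate the Cas9 cut bond from a protospacer
#'
#' The 20-nt protospacer (5' to 3', PAM not included) must occur exactly
#' once in the wild-type sequence, on either strand. Cleavage is placed at
#' the -3 position, i.e. the bond between protospacer bases 17 and 18.
#'
#' @param wt Wild-type sequence.
#' @param protospacer 20-nt target sequence.
#' @return A list: `cut_pos` (number of wild-type bases 5' of the cut bond)
#'   and `strand` (`"+"` or `"-"`).
#' @export
locate_cut_site <- function(wt, protospacer) {
  wt <- normalize_sequence(wt)
  protospacer <- normalize_sequence(protospacer)
  if (nchar(protospacer) != 20L) {
    stop_dcaps("protospacer_not_found", "protospacer must be 20 nt (got %d)",
               nchar(protospacer))
  }
  fwd <- gregexpr(protospacer, wt, fixed = TRUE)[[1L]]
  fwd <- fwd[fwd > 0L]
  rc <- reverse_complement(protospacer)
  rev <- gregexpr(rc, wt, fixed = TRUE)[[1L]]
  rev <- rev[rev > 0L]
  if (identical(protospacer, rc)) rev <- integer(0L)  # palindromic guide: one physical site
  n_hits <- length(fwd) + length(rev)
  if (n_hits == 0L) {
    stop_dcaps("protospacer_not_found", "protospacer not found on either strand")
  }
  if (n_hits > 1L) {
    stop_dcaps("multiple_protospacer_hits",
               "protospacer occurs %d times; the cut site is ambiguous", n_hits)
  }
  if (length(fwd)) {
    list(cut_pos = fwd + 16L, strand = "+")
  } else {
    # protospacer runs right-to-left on the plus strand: bases 18-20 lie at
    # wt positions rev..rev+2, so the -3 bond sits after position rev+2
    list(cut_pos = rev + 2L, strand = "-")
  }
}

#' Simulate editing outcomes at a cut site
#'
#' Insertions add their payload at the cut bond; deletions remove bases
#' immediately 5' of it.
#'
#' @param wt Wild-type sequence.
#' @param cut_pos Number of wild-type bases 5' of the cut bond (see
#'   [locate_cut_site()]).
#' @param profile An [edit_profile()].
#' @return Character vector of edited sequences, one per event, named by
#'   event label.
#' @export
simulate_edits <- function(wt, cut_pos, profile = edit_profile()) {
  wt <- normalize_sequence(wt)
  n <- nchar(wt)
  stopifnot(cut_pos >= 1L, cut_pos < n)
  if (!nrow(profile)) return(character(0L))
  out <- character(nrow(profile))
  labels <- character(nrow(profile))
  for (i in seq_len(nrow(profile))) {
    if (profile$kind[i] == "insertion") {
      ins <- profile$payload[i]
      out[i] <- paste0(substr(wt, 1L, cut_pos), ins, substr(wt, cut_pos + 1L, n))
      labels[i] <- paste0("+", ins)
    } else {
      d <- as.integer(profile$payload[i])
      stopifnot(d >= 1L, d <= cut_pos)
      out[i] <- paste0(substr(wt, 1L, cut_pos - d), substr(wt, cut_pos + 1L, n))
      labels[i] <- paste0("-", d)
    }
  }
  stats::setNames(out, labels)
}

#' Last base shared by the wild type and all variants
#'
#' The maximal prefix length L such that every variant begins with
#' `substr(wt, 1, L)`; inside a homopolymer this moves 5' of the naive cut
#' position.
#'
#' @param wt Wild-type sequence.
#' @param variants Character vector of variant sequences (at least one).
#' @return L, the 1-based position of the last shared base (0 when nothing
#'   is shared).
#' @export
last_shared_base_all <- function(wt, variants) {
  stopifnot(length(variants) >= 1L)
  wb <- seq_bits(normalize_sequence(wt))
  L <- length(wb)
  for (v in variants) {
    vb <- seq_bits(normalize_sequence(v))
    k <- min(L, length(vb))
    ok <- bitwAnd(wb[seq_len(k)], vb[seq_len(k)]) != 0L
    L <- if (all(ok)) k else which(!ok)[1L] - 1L
    if (L == 0L) break
  }
  L
}

#' Design screening assays for unknown editing events
#'
#' Scans the wild-type sequence (both orientations) for enzyme motifs that
#' span the last base shared with all simulated edits, builds primers as in
#' the known-allele mode, simulates every event's amplicon, and reports per
#' assay the weighted fraction of events it would miss (events whose edited
#' amplicon still contains an exact site anywhere — an insertion inside a
#' degenerate motif position can restore a site in a shifted register).
#' Results with `loss_fraction` above `loss_threshold` are discarded
#' (comparison is inclusive: a loss exactly at the threshold is kept);
#' survivors are sorted by loss, mismatch count, then enzyme name.
#'
#' @param wt Wild-type sequence (>= 20 nt on each side of the cut
#'   recommended).
#' @param protospacer 20-nt CRISPR target, 5' to 3', no PAM, either strand.
#' @param enzymes An `enzyme_table`.
#' @param max_mismatch Primer mismatch budget (default 1).
#' @param loss_threshold Acceptable fraction of missed events in `[0, 1]`
#'   (default 0).
#' @param amplicon_len Amplicon window downstream of the primer anchor
#'   (default 150).
#' @param profile An [edit_profile()].
#' @param opts A [primer_options()] object.
#' @return A data frame of class `screening_results` with one row per
#'   surviving assay: enzyme, orientation, primer sequence and Tm, mismatch
#'   count, `loss_fraction`, and a `per_event_calls` list column mapping
#'   each event to `"cut"` or `"uncut"`.
#' @export
screen_assays <- function(wt, protospacer, enzymes = load_enzymes(),
                          max_mismatch = 1L, loss_threshold = 0,
                          amplicon_len = 150L, profile = edit_profile(),
                          opts = primer_options()) {
  stopifnot(loss_threshold >= 0, loss_threshold <= 1)
  wt <- normalize_sequence(wt)
  cut <- locate_cut_site(wt, protospacer)
  variants <- simulate_edits(wt, cut$cut_pos, profile)
  n <- nchar(wt)
  rows <- list()
  for (orientation in c("forward", "reverse_complement")) {
    if (orientation == "forward") {
      W <- wt; V <- variants; weights <- profile$weight
    } else {
      W <- reverse_complement(wt)
      V <- stats::setNames(vapply(variants, reverse_complement, character(1L)),
                           names(variants))
      weights <- profile$weight
    }
    L <- last_shared_base_all(W, V)
    if (L < 1L) next
    rows <- c(rows, .screen_orientation(W, V, weights, L, enzymes, max_mismatch,
                                        loss_threshold, amplicon_len, opts,
                                        orientation))
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_screening()
  if (nrow(out)) {
    out <- out[order(out$loss_fraction, out$mismatch_count, out$enzyme,
                     out$motif_start, method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("screening_results", "data.frame")
  out
}

.empty_screening <- function() {
  out <- data.frame(
    enzyme = character(), motif = character(), orientation = character(),
    motif_start = integer(), motif_strand = character(),
    primer = character(), primer_start = integer(), anchor_3prime = integer(),
    primer_length = integer(),
    mismatch_count = integer(), tm_celsius = numeric(),
    loss_fraction = numeric(), truncated_window = logical(),
    stringsAsFactors = FALSE
  )
  out$mismatch_positions <- list()
  out$per_event_calls <- list()
  out
}

.screen_orientation <- function(W, V, weights, L, enzymes, max_mismatch,
                                loss_threshold, amplicon_len, opts, orientation) {
  Wb <- seq_bits(W)
  len <- length(Wb)
  rows <- list()
  for (i in seq_len(nrow(enzymes))) {
    e <- enzymes[i, , drop = FALSE]
    variants_e <- motif_variants(e$motif)
    for (v in variants_e) {
      m <- length(v$bits)
      lo <- max(1L, L + 2L - m)
      hi <- min(L, len - m + 1L)
      if (hi < lo) next
      counts <- slide_mismatch_counts(Wb, v$bits)
      for (p in lo:hi) {
        if (counts[p] > max_mismatch) next
        offs <- which(bitwAnd(Wb[p:(p + m - 1L)], v$bits) == 0L)
        mm_pos <- p + offs - 1L
        if (length(mm_pos) && any(mm_pos > L)) next
        patches <- .FIRST_BASE[v$bits[offs]]
        res <- tryCatch(
          .screen_candidate(W, Wb, V, weights, L, e, v, p, mm_pos, patches,
                            max_mismatch, amplicon_len, opts, orientation),
          dcaps_error = function(err) NULL
        )
        if (is.null(res)) next
        if (res$loss_fraction <= loss_threshold) rows[[length(rows) + 1L]] <- res
      }
    }
  }
  rows
}

.screen_candidate <- function(W, Wb, V, weights, L, enzyme_row, variant, p,
                              mm_pos, patches, max_mismatch, amplicon_len,
                              opts, orientation) {
  m <- length(variant$bits)
  len <- length(Wb)
  variants_e <- motif_variants(enzyme_row$motif)
  # downstream rejection: an exact site past the edit region, inside the
  # amplicon window, would cut every genotype and ruin the readout
  ds_lo <- max(p + m - 1L, L + 2L) + 1L
  win_hi <- min(len, L + amplicon_len)
  if (ds_lo <= win_hi) {
    hits <- exact_sites(Wb, variants_e)
    if (any(hits$start >= ds_lo & hits$end <= win_hi)) return(NULL)
  }
  # build the primer through the known-allele machinery: fake assay row
  assay <- data.frame(
    enzyme = enzyme_row$name, motif = variant$seq, orientation = orientation,
    cleaved_allele = "wt", scanned_allele = 1L, motif_start = p,
    motif_strand = variant$strand, mismatch_count = length(mm_pos),
    is_caps = length(mm_pos) == 0L, stringsAsFactors = FALSE
  )
  assay$mismatch_positions <- list(mm_pos)
  assay$patch_bases <- list(patches)
  ctx <- list(Sa = W, Sb = W, ka = 0L, kb = 0L, U = L)
  core <- local({
    # inline build_primer checks (no allele_comparison object in this mode)
    if (length(mm_pos) > opts$max_mismatch) {
      stop_dcaps("mismatch_budget_exceeded", "over budget")
    }
    if (L %in% mm_pos) {
      b <- patches[match(L, mm_pos)]
      t_chr <- substr(W, L, L)
      gt <- setequal(c(b, .complement_base(t_chr)), c("G", "T"))
      if (!(opts$allow_3prime_GT && gt)) {
        stop_dcaps("terminal_mismatch_rejected", "3'-terminal mismatch")
      }
    }
    list(assay = assay, ctx = ctx,
         core_start = if (length(mm_pos)) min(mm_pos) else L,
         anchor_3prime = L, mismatch_positions = mm_pos, patch_bases = patches)
  })
  class(core) <- "primer_core"
  design <- .extend_screen_primer(core, opts, enzyme_row, variant, p)
  # per-event digestion: substitute the primer, window the amplicon, look
  # for any exact site of the enzyme anywhere in it
  start <- design$start
  primer_bits <- seq_bits(design$sequence)
  wt_call <- .amplicon_cut(Wb, start, L, primer_bits, amplicon_len, variants_e)
  if (!wt_call) return(NULL)  # definitional: wild type must be cleaved
  calls <- vapply(V, function(vseq) {
    vb <- seq_bits(vseq)
    .amplicon_cut(vb, start, L, primer_bits, amplicon_len, variants_e)
  }, logical(1L))
  loss <- sum(weights[calls]) / sum(weights)
  row <- data.frame(
    enzyme = enzyme_row$name, motif = variant$seq, orientation = orientation,
    motif_start = p, motif_strand = variant$strand,
    primer = design$sequence, primer_start = design$start,
    anchor_3prime = design$anchor_3prime, primer_length = design$length,
    mismatch_count = design$mismatch_count, tm_celsius = design$tm_celsius,
    loss_fraction = loss, truncated_window = len < L + amplicon_len,
    stringsAsFactors = FALSE
  )
  row$mismatch_positions <- list(design$mismatch_positions)
  row$per_event_calls <- list(ifelse(calls, "cut", "uncut"))
  row
}

# Extension for screening primers: same length search and disruption logic
# as extend_primer, but validation is per-event (done by the caller).
.extend_screen_primer <- function(core, opts, enzyme_row, variant, p) {
  ctx <- core$ctx
  L <- ctx$U
  cover <- L - core$core_start + 1L
  lengths <- if (opts$mode == "fixed_length") {
    if (opts$length > L) stop_dcaps("shared_region_too_short", "primer would overrun the sequence start")
    if (opts$length < cover) stop_dcaps("primer_outside_shared_region", "patch not covered")
    opts$length
  } else {
    lo <- max(opts$min_length, cover)
    hi <- min(opts$max_length, L)
    if (hi < lo) stop_dcaps("shared_region_too_short", "no viable primer length")
    lo:hi
  }
  best <- NULL; best_score <- Inf; first_failure <- NULL
  for (Ln in lengths) {
    cand <- tryCatch(
      .finalize_primer(core$assay, ctx, L, Ln, core$mismatch_positions,
                       core$patch_bases, opts, enzymes = .screen_disruption_catalogue()),
      dcaps_error = function(e) e
    )
    if (inherits(cand, "dcaps_error")) {
      if (is.null(first_failure)) first_failure <- cand
      next
    }
    score <- if (opts$mode == "target_tm") abs(cand$tm_celsius - opts$target_tm) else 0
    if (score < best_score - 1e-9) { best <- cand; best_score <- score }
  }
  if (is.null(best)) stop(if (!is.null(first_failure)) first_failure
                          else dcaps_error("shared_region_too_short", "no viable primer"))
  best
}

# Catalogue used by the disruption no-new-site preference during screening;
# cached because screening visits many candidates.
.screen_catalogue_env <- new.env(parent = emptyenv())
.screen_disruption_catalogue <- function() {
  if (is.null(.screen_catalogue_env$enzymes)) {
    .screen_catalogue_env$enzymes <- load_enzymes()
  }
  .screen_catalogue_env$enzymes
}

# Does the primer-substituted, windowed amplicon contain an exact site?
.amplicon_cut <- function(template_bits, start, L, primer_bits, amplicon_len,
                          variants_e) {
  tb <- template_bits
  tb[start:L] <- primer_bits
  win_hi <- min(length(tb), start + amplicon_len - 1L)
  amp <- tb[start:win_hi]
  for (v in variants_e) {
    if (length(exact_match_starts(amp, v$bits))) return(TRUE)
  }
  FALSE
}

#' @export
print.screening_results <- function(x, ...) {
  cat(sprintf("%d screening assay(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- as.data.frame(x)[, c("enzyme", "orientation", "primer",
                                 "mismatch_count", "tm_celsius", "loss_fraction")]
    print(utils::head(show, 20L), digits = 4L, ...)
    if (nrow(x) > 20L) cat(sprintf("... and %d more\n", nrow(x) - 20L))
  }
  invisible(x)
}
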