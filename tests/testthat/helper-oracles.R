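# Independent oracles: character-set reimplementations of the primitives,
# deliberately avoiding the package's bitmask machinery so agreement is
# evidence, not tautology.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_match <- function(x, y) length(intersect(ORACLE_SETS[[x]], ORACLE_SETS[[y]])) > 0L

oracle_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(!mapply(oracle_match, ca, cb))
}

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")
oracle_revcomp <- function(s) {
  paste(rev(ORACLE_COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# IUPAC motif -> regex character classes; exact-occurrence search on a
# concrete subject via gregexpr (lookahead keeps overlapping hits)
motif_regex <- function(motif) {
  cls <- vapply(strsplit(motif, "")[[1]], function(ch) {
    set <- ORACLE_SETS[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1))
  paste(cls, collapse = "")
}

oracle_exact_starts <- function(subject, motif) {
  hits <- gregexpr(paste0("(?=", motif_regex(motif), ")"), subject, perl = TRUE)[[1]]
  hits[hits > 0L]
}

oracle_site_anywhere <- function(subject, motif) {
  length(oracle_exact_starts(subject, motif)) > 0L ||
    length(oracle_exact_starts(subject, oracle_revcomp(motif))) > 0L
}

# Independent prefix/suffix decomposition (plain character loops).
oracle_decompose <- function(s1, s2) {
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  k <- min(length(c1), length(c2))
  U <- 0L
  while (U < k && oracle_match(c1[U + 1L], c2[U + 1L])) U <- U + 1L
  D <- 0L
  while (D < k - U &&
         oracle_match(c1[length(c1) - D], c2[length(c2) - D])) D <- D + 1L
  list(U = U, D = D, k1 = length(c1) - U - D, k2 = length(c2) - U - D)
}

# Brute-force candidate enumerator: all enzymes x all positions x both
# motif alignments x both input orientations x both alleles, using the
# documented rules only. Both-cut ("both_differently") positions are
# skipped; the comparison filters them from the scanner output too.
oracle_scan <- function(s1, s2, enzymes, max_mismatch) {
  keys <- character(0)
  for (orientation in c("forward", "reverse_complement")) {
    if (orientation == "forward") { a1 <- s1; a2 <- s2 }
    else { a1 <- oracle_revcomp(s1); a2 <- oracle_revcomp(s2) }
    dec <- oracle_decompose(a1, a2)
    U <- dec$U
    for (al in 1:2) {
      Sa <- if (al == 1L) a1 else a2
      Sb <- if (al == 1L) a2 else a1
      ka <- if (al == 1L) dec$k1 else dec$k2
      kb <- if (al == 1L) dec$k2 else dec$k1
      ca <- strsplit(Sa, "")[[1]]
      for (ei in seq_len(nrow(enzymes))) {
        e <- enzymes[ei, ]
        mots <- unique(c(e$motif, oracle_revcomp(e$motif)))
        strands <- if (length(mots) == 2L) c("+", "-") else "+"
        for (vi in seq_along(mots)) {
          mot <- mots[vi]
          cm <- strsplit(mot, "")[[1]]
          m <- length(cm)
          for (p in seq_len(length(ca) - m + 1L)) {
            hi_un <- if (ka > 0L) U + ka else U
            if (p > hi_un) next
            if (p + m - 1L < U + 1L) next
            offs <- which(!mapply(oracle_match, ca[p:(p + m - 1L)], cm))
            if (length(offs) > max_mismatch) next
            mm_pos <- p + offs - 1L
            if (length(mm_pos) && any(mm_pos > U)) next
            patch <- vapply(offs, function(j) intersect(c("A", "C", "G", "T"),
                                                        ORACLE_SETS[[cm[j]]])[1],
                            character(1))
            cb <- strsplit(Sb, "")[[1]]
            if (length(mm_pos)) cb[mm_pos] <- patch
            Sbp <- paste(cb, collapse = "")
            near <- FALSE
            for (mv in mots) {
              st <- oracle_exact_starts(Sbp, mv)
              mlen <- nchar(mv)
              hit <- st[st + mlen - 1L >= U + 1L &
                          st <= (if (kb > 0L) U + kb else U)]
              if (length(hit)) { near <- TRUE; break }
            }
            if (near) next   # both-cut cases excluded from the equivalence
            keys <- c(keys, paste(orientation, al, e$name, strands[vi], p,
                                  length(mm_pos), sep = "|"))
          }
        }
      }
    }
  }
  sort(unique(keys))
}

scan_keys <- function(cands) {
  cands <- cands[cands$cleaved_allele != "both_differently", , drop = FALSE]
  sort(unique(paste(cands$orientation, cands$scanned_allele, cands$enzyme,
                    cands$motif_strand, cands$motif_start,
                    cands$mismatch_count, sep = "|")))
}

# Per-event digest oracle for screening results: substitutes the primer by
# string surgery and looks for an exact site by regex on either strand.
oracle_event_calls <- function(row, wt, profile, amplicon_len) {
  W <- if (row$orientation == "forward") wt else oracle_revcomp(wt)
  cut <- locate_cut_site(wt, attr(wt, "protospacer"))
  variants <- simulate_edits(wt, cut$cut_pos, profile)
  V <- if (row$orientation == "forward") variants
       else vapply(variants, oracle_revcomp, character(1))
  vapply(V, function(v) {
    cv <- strsplit(v, "")[[1]]
    cv[row$primer_start:row$anchor_3prime] <- strsplit(row$primer, "")[[1]]
    hi <- min(length(cv), row$primer_start + amplicon_len - 1L)
    amp <- paste(cv[row$primer_start:hi], collapse = "")
    oracle_site_anywhere(amp, row$motif)
  }, logical(1))
}
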