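# Deterministic synthetic fixtures: random allele pairs with a planted SNP
# or small indel, CRISPR loci with a unique protospacer, and allele pairs
# with a planted near-site for a chosen enzyme. These are first-class test
# machinery: the test suite and the acceptance checks build their inputs
# here. Functions draw from R's RNG; callers seed.

#' Random concrete DNA sequence
#' @param n Length in nt.
#' @return A string over ACGT.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Random allele pair differing by one interior SNP
#'
#' @param len Sequence length (default 60).
#' @param interior Margin kept free of the SNP at each end (default 20).
#' @return A list: `seq1`, `seq2`, `pos` (SNP position, 1-based).
#' @export
make_snp_pair <- function(len = 60L, interior = 20L) {
  s <- random_dna(len)
  pos <- sample((interior + 1L):(len - interior), 1L)
  old <- substr(s, pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  s2 <- s
  substr(s2, pos, pos) <- new
  list(seq1 = s, seq2 = s2, pos = pos)
}

#' Random allele pair differing by a small insertion
#'
#' `seq2` carries `k` extra bases at an interior position of `seq1`.
#'
#' @param len Length of the shorter allele (default 60).
#' @param k Indel size in bp (default 1).
#' @param interior End margin (default 20).
#' @return A list: `seq1`, `seq2`, `pos` (insertion point: the inserted
#'   bases follow `seq1[pos]`), `inserted`.
#' @export
make_indel_pair <- function(len = 60L, k = 1L, interior = 20L) {
  s <- random_dna(len)
  pos <- sample(interior:(len - interior), 1L)
  ins <- random_dna(k)
  s2 <- paste0(substr(s, 1L, pos), ins, substr(s, pos + 1L, len))
  list(seq1 = s, seq2 = s2, pos = pos, inserted = ins)
}

#' Random CRISPR locus with a unique protospacer
#'
#' Draws a random sequence and takes its central 20-mer as the protospacer,
#' redrawing until the protospacer is unique across both strands (virtually
#' always the first draw).
#'
#' @param len Locus length (default 120).
#' @return A list: `wt`, `protospacer`, `cut_pos`.
#' @export
make_crispr_locus <- function(len = 120L) {
  stopifnot(len >= 60L)
  repeat {
    wt <- random_dna(len)
    start <- (len - 20L) %/% 2L + 1L
    proto <- substr(wt, start, start + 19L)
    fwd_hits <- gregexpr(proto, wt, fixed = TRUE)[[1L]]
    rc_hits <- gregexpr(reverse_complement(proto), wt, fixed = TRUE)[[1L]]
    n_hits <- sum(fwd_hits > 0L) + sum(rc_hits > 0L)
    if (n_hits == 1L) {
      return(list(wt = wt, protospacer = proto, cut_pos = start + 16L))
    }
  }
}

#' Allele pair with a planted dCAPS opportunity
#'
#' Constructs a SNP pair in which the given enzyme's motif, concretized,
#' overlaps the SNP: allele 1 matches the motif everywhere except at one
#' shared upstream position (the future primer mismatch), and the SNP base
#' in allele 2 is incompatible with the motif. `scan_assays` must therefore
#' recover the planted (enzyme, position) with `mismatch_count` 1.
#'
#' @param enzyme Single-row `enzyme_table` slice with a motif whose first
#'   and third positions are not N (the default EcoRI-style planting needs
#'   definite bases there).
#' @param flank Shared flank length on each side (default 25).
#' @return A list: `seq1`, `seq2`, `enzyme`, `motif_start`,
#'   `mismatch_pos`, `snp_pos`.
#' @export
plant_assay_pair <- function(enzyme, flank = 25L) {
  motif <- enzyme$motif
  m <- nchar(motif)
  bits <- seq_bits(motif)
  definite <- which(bits != 15L)
  stopifnot(length(definite) >= 2L)
  j_mm <- definite[1L]            # primer mismatch: shared, 5' of the SNP
  j_snp <- definite[length(definite)]
  stopifnot(j_snp > j_mm)
  concrete <- vapply(seq_len(m), function(j) {
    picks <- c("A", "C", "G", "T")[bitwAnd(.IUPAC_BITS[c("A", "C", "G", "T")], bits[j]) != 0L]
    sample(picks, 1L)
  }, character(1L))
  site1 <- concrete
  # break the motif at j_mm in both alleles (the primer will restore it)
  off <- c("A", "C", "G", "T")[bitwAnd(.IUPAC_BITS[c("A", "C", "G", "T")], bits[j_mm]) == 0L]
  site1[j_mm] <- sample(off, 1L)
  site2 <- site1
  # the SNP: allele 2 incompatible with the motif at j_snp
  snp_off <- setdiff(
    c("A", "C", "G", "T")[bitwAnd(.IUPAC_BITS[c("A", "C", "G", "T")], bits[j_snp]) == 0L],
    site1[j_snp])
  stopifnot(length(snp_off) >= 1L)
  site2[j_snp] <- sample(snp_off, 1L)
  left <- random_dna(flank)
  right <- random_dna(flank)
  list(seq1 = paste0(left, paste(site1, collapse = ""), right),
       seq2 = paste0(left, paste(site2, collapse = ""), right),
       enzyme = enzyme$name,
       motif_start = flank + 1L,
       mismatch_pos = flank + j_mm,
       snp_pos = flank + j_snp)
}

#' Write deterministic fixture files
#'
#' Writes `n` FASTA fixtures of the requested kind plus a JSON sidecar with
#' the ground truth, under `dir`. Byte-identical across runs for the same
#' seed (the caller's RNG state is restored on exit).
#'
#' @param seed Integer seed.
#' @param n Number of fixtures.
#' @param kind One of `"snp_pair"`, `"indel_pair"`, `"crispr_locus"`,
#'   `"planted_assay"`.
#' @param dir Output directory (created if needed).
#' @return Character vector of FASTA paths, invisibly.
#' @export
generate_fixtures <- function(seed, n, kind = c("snp_pair", "indel_pair",
                                                "crispr_locus", "planted_assay"),
                              dir = ".") {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  enz <- if (kind == "planted_assay") {
    filter_enzymes(load_enzymes(), include = "EcoRI")[1L, , drop = FALSE]
  }
  paths <- character(n)
  for (i in seq_len(n)) {
    fx <- switch(kind,
      snp_pair = make_snp_pair(),
      indel_pair = make_indel_pair(k = sample(1:3, 1L)),
      crispr_locus = make_crispr_locus(),
      planted_assay = plant_assay_pair(enz))
    stem <- file.path(dir, sprintf("%s_%03d", kind, i))
    fasta <- paste0(stem, ".fasta")
    if (kind == "crispr_locus") {
      writeLines(c(">wt", fx$wt), fasta)
    } else {
      writeLines(c(">allele1", fx$seq1, ">allele2", fx$seq2), fasta)
    }
    truth <- fx[setdiff(names(fx), c("seq1", "seq2", "wt"))]
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE), paste0(stem, ".json"))
    paths[i] <- fasta
  }
  invisible(paths)
}
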