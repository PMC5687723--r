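# Shared fixtures. A 20-enzyme sub-catalogue (mix of concrete and
# degenerate motifs, 4-10 nt) keeps oracle comparisons affordable.

SUBCAT_NAMES <- c("EcoRI", "BamHI", "HindIII", "BsaBI", "DraI", "AluI",
                  "RsaI", "HaeIII", "TaqI", "HinfI", "DdeI", "MseI",
                  "NlaIII", "AvaI", "AccI", "StyI", "HincII", "XmnI",
                  "ApoI", "BstNI")

subcatalogue <- function() filter_enzymes(load_enzymes(), include = SUBCAT_NAMES)

# SYNTHETIC stand-in for the AHK3 first-exon locus (the real genomic
# sequence is not bundled): random flanks around the published protospacer,
# with the two bases 3' of it fixed to "TG" so that a BsaBI site
# (GATNN^NNATC) spans the Cas9 cut bond and needs exactly one engineered
# mismatch, reachable only from the reverse-complement side. Geometry
# mirrors the published assay: 36-nt primer, 90-bp amplicon, 36+54 digest.
synthetic_ahk3_locus <- function(seed = 7L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  proto <- "GGTTGAGATCAAGATAGACA"
  repeat {
    wt <- paste0(random_dna(60L), proto, "TG", random_dna(38L))
    sites <- gregexpr("GAT[ACGT]{4}ATC", wt)[[1]]
    clean <- sum(sites > 0L) == 0L
    unique_proto <- sum(gregexpr(proto, wt, fixed = TRUE)[[1]] > 0L) == 1L &&
      gregexpr(reverse_complement(proto), wt, fixed = TRUE)[[1]][1] == -1L
    if (clean && unique_proto) break
  }
  list(wt = wt, protospacer = proto)
}

random_pair <- function() {
  if (stats::runif(1) < 0.5) {
    fx <- make_snp_pair(len = 60L)
  } else {
    fx <- make_indel_pair(len = 60L, k = sample(1:3, 1L))
  }
  fx
}

quiet_compare <- function(s1, s2) suppressWarnings(compare_alleles(s1, s2))
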