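LEFT25 <- "TGCCAGTCAGGTACCTGGACTGCAG"
RIGHT25 <- "CTGGACCTGGTGACAGTGCAAGTCC"
ECORI <- filter_enzymes(load_enzymes(), include = "EcoRI")

caps_fixture <- function() {
  s1 <- paste0(LEFT25, "GAATTC", RIGHT25)
  s2 <- paste0(LEFT25, "GACTTC", RIGHT25)
  cmp <- compare_alleles(s1, s2)
  cands <- scan_assays(cmp, ECORI, 0L)
  list(cmp = cmp, row = cands[cands$orientation == "forward", ][1L, ])
}

test_that("a CAPS candidate degenerates to a plain, mismatch-free primer", {
  fx <- caps_fixture()
  d <- design_primer(fx$row, fx$cmp, primer_options(mode = "fixed_length", length = 20L))
  expect_identical(d$mismatch_count, 0L)
  expect_identical(d$length, 20L)
  expect_identical(d$anchor_3prime, fx$cmp$last_shared)
  U <- fx$cmp$last_shared
  expect_identical(d$sequence, substr(fx$cmp$seq1, U - 19L, U))
})

test_that("mismatch budget and shared-region bounds are enforced", {
  s1 <- paste0(LEFT25, "GTTTTC", RIGHT25)  # two shared-region fixes for GAATTC
  s2 <- paste0(LEFT25, "GTTTAC", RIGHT25)
  cmp <- compare_alleles(s1, s2)
  cands <- scan_assays(cmp, ECORI, 2L)
  row <- cands[cands$orientation == "forward" & cands$mismatch_count == 2L, ][1L, ]
  expect_false(is.na(row$enzyme))
  expect_error(design_primer(row, cmp, primer_options(max_mismatch = 1L)),
               class = "dcaps_mismatch_budget_exceeded")
  d <- design_primer(row, cmp, primer_options(max_mismatch = 2L))
  expect_identical(d$mismatch_count, 2L)

  fx <- caps_fixture()
  expect_error(
    design_primer(fx$row, fx$cmp, primer_options(mode = "fixed_length", length = 40L)),
    class = "dcaps_shared_region_too_short")
})

test_that("Tm-targeted primers come out shorter on GC-rich templates", {
  gc_left <- "GCGGCAGCCGCGGCAGGCGCCGGCAGGCTGCCG"
  at_left <- "ATTATAATCTATTAATGTATAATCTAGTCATTA"
  make <- function(left) {
    s1 <- paste0(left, "GAATTC", RIGHT25)
    s2 <- paste0(left, "GACTTC", RIGHT25)
    cmp <- compare_alleles(s1, s2)
    row <- scan_assays(cmp, ECORI, 0L)
    row <- row[row$orientation == "forward", ][1L, ]
    design_primer(row, cmp, primer_options(mode = "target_tm", target_tm = 60))
  }
  expect_lt(make(gc_left)$length, make(at_left)$length)
})

test_that("3'-terminal mismatches reject the design unless they are allowed G/T pairings", {
  # patch G over template A at the anchor: a G/T pairing in the duplex
  s1 <- paste0(LEFT25, "AAATTC", RIGHT25)
  s2 <- paste0(LEFT25, "ACATTC", RIGHT25)
  cmp <- compare_alleles(s1, s2)
  cands <- scan_assays(cmp, ECORI, 1L)
  row <- cands[cands$orientation == "forward" & cands$cleaved_allele == "1", ][1L, ]
  expect_identical(row$mismatch_positions[[1L]], cmp$last_shared)
  expect_error(design_primer(row, cmp, primer_options()),
               class = "dcaps_terminal_mismatch_rejected")
  d <- design_primer(row, cmp, primer_options(allow_3prime_GT = TRUE))
  expect_identical(substr(d$sequence, d$length, d$length), "G")
  expect_identical(max(d$mismatch_positions), d$length)

  # patch C over template A pairs C:T - rejected even when G/T is allowed
  bstni <- filter_enzymes(load_enzymes(), include = "BstNI")
  s3 <- paste0(LEFT25, "ACAGG", RIGHT25)
  s4 <- paste0(LEFT25, "AAAGG", RIGHT25)
  cmp2 <- compare_alleles(s3, s4)
  cands2 <- scan_assays(cmp2, bstni, 1L)
  row2 <- cands2[cands2$orientation == "forward" & cands2$cleaved_allele == "1" &
                   cands2$mismatch_count == 1L, ][1L, ]
  expect_identical(row2$mismatch_positions[[1L]], cmp2$last_shared)
  expect_error(design_primer(row2, cmp2, primer_options(allow_3prime_GT = TRUE)),
               class = "dcaps_terminal_mismatch_rejected")
})

test_that("an exact second site under the primer is disrupted at the cost of one mismatch", {
  left <- paste0("TGCCAGTCAG", "GAATTC", "CTGGACTG")  # spurious site in the flank
  s1 <- paste0(left, "GAATTC", RIGHT25)
  s2 <- paste0(left, "GACTTC", RIGHT25)
  cmp <- quiet_compare(s1, s2)
  cands <- scan_assays(cmp, ECORI, 1L)
  row <- cands[cands$orientation == "forward" & cands$is_caps, ][1L, ]
  d <- design_primer(row, cmp, primer_options(mode = "fixed_length", length = 25L,
                                              max_mismatch = 1L))
  expect_identical(d$mismatch_count, 1L)  # the disruption
  # the spurious site is gone: the cleaved amplicon has exactly one site
  amp1 <- s1
  substr(amp1, d$start, d$anchor_3prime) <- d$sequence
  expect_identical(length(oracle_exact_starts(amp1, "GAATTC")), 1L)
  expect_identical(oracle_exact_starts(amp1, "GAATTC"), row$motif_start)
  # no budget for the disruption -> design refused
  expect_error(
    design_primer(row, cmp, primer_options(mode = "fixed_length", length = 25L,
                                           max_mismatch = 0L)),
    class = "dcaps_mismatch_budget_exceeded")
})

test_that("every emitted design satisfies the defining dCAPS invariant", {
  set.seed(51)
  enz <- subcatalogue()
  n_checked <- 0L
  for (i in 1:30) {
    fx <- random_pair()
    cmp <- tryCatch(quiet_compare(fx$seq1, fx$seq2), dcaps_error = function(e) NULL)
    if (is.null(cmp)) next
    cands <- scan_assays(cmp, enz, 1L)
    cands <- reject_downstream_cutters(cands, cmp, 150L)
    for (j in seq_len(min(nrow(cands), 5L))) {
      row <- cands[j, , drop = FALSE]
      if (row$cleaved_allele == "both_differently") next
      d <- tryCatch(design_primer(row, cmp, primer_options(), enz),
                    dcaps_error = function(e) NULL)
      if (is.null(d)) next
      cc <- if (row$orientation == "forward") cmp else dcaps:::reverse_comparison(cmp)
      Sa <- if (row$scanned_allele == 1L) cc$seq1 else cc$seq2
      Sb <- if (row$scanned_allele == 1L) cc$seq2 else cc$seq1
      amp_a <- Sa; substr(amp_a, d$start, d$anchor_3prime) <- d$sequence
      amp_b <- Sb; substr(amp_b, d$start, d$anchor_3prime) <- d$sequence
      expect_true(d$motif_start %in%
                    c(oracle_exact_starts(amp_a, d$motif),
                      oracle_exact_starts(amp_a, oracle_revcomp(d$motif))))
      U <- cc$last_shared
      kb <- nchar(if (row$scanned_allele == 1L) cc$unshared2 else cc$unshared1)
      for (mv in unique(c(d$motif, oracle_revcomp(d$motif)))) {
        st <- oracle_exact_starts(amp_b, mv)
        st <- st[st + nchar(mv) - 1L >= U + 1L & st <= (if (kb > 0L) U + kb else U)]
        expect_identical(length(st), 0L)
      }
      expect_lte(d$mismatch_count, 1L)
      expect_gte(d$start, 1L)
      expect_identical(d$anchor_3prime, U)  # never overlaps an unshared base
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 20L)
})
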