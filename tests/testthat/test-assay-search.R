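LEFT25 <- "TGCCAGTCAGGTACCTGGACTGCAG"
RIGHT25 <- "CTGGACCTGGTGACAGTGCAAGTCC"

test_that("a SNP breaking an EcoRI site is found as CAPS at zero mismatches", {
  s1 <- paste0(LEFT25, "GAATTC", RIGHT25)
  s2 <- paste0(LEFT25, "GACTTC", RIGHT25)
  cmp <- compare_alleles(s1, s2)
  ecori <- filter_enzymes(load_enzymes(), include = "EcoRI")
  cands <- scan_assays(cmp, ecori, max_mismatch = 0L)
  fwd <- cands[cands$orientation == "forward", ]
  expect_identical(nrow(fwd), 1L)
  expect_identical(fwd$cleaved_allele, "1")
  expect_true(fwd$is_caps)
  expect_identical(fwd$mismatch_count, 0L)
  expect_identical(fwd$motif_start, 26L)  # site spans the SNP at position 30
  # nothing at zero mismatches when the discriminating base is untouched
  s3 <- paste0(LEFT25, "TTTTTT", RIGHT25)
  s4 <- paste0(LEFT25, "TTATTT", RIGHT25)
  expect_identical(nrow(scan_assays(compare_alleles(s3, s4), ecori, 0L)), 0L)
})

test_that("a near-site one mismatch away yields a dCAPS candidate", {
  s1 <- paste0(LEFT25, "GTATTC", RIGHT25)  # GAATTC with A2->T (shared side)
  s2 <- paste0(LEFT25, "GTATAC", RIGHT25)  # SNP at motif position 5
  cmp <- compare_alleles(s1, s2)
  ecori <- filter_enzymes(load_enzymes(), include = "EcoRI")
  expect_identical(nrow(scan_assays(cmp, ecori, 0L)), 0L)
  cands <- scan_assays(cmp, ecori, 1L)
  fwd <- cands[cands$orientation == "forward" & cands$cleaved_allele == "1", ]
  expect_identical(nrow(fwd), 1L)
  expect_identical(fwd$mismatch_count, 1L)
  expect_false(fwd$is_caps)
  expect_identical(fwd$mismatch_positions[[1]], 27L)  # the engineered base
})

test_that("planted assays are recovered from generated fixtures", {
  set.seed(31)
  ecori <- filter_enzymes(load_enzymes(), include = "EcoRI")
  for (i in 1:25) {
    fx <- plant_assay_pair(ecori[1L, ])
    cmp <- quiet_compare(fx$seq1, fx$seq2)
    cands <- scan_assays(cmp, ecori, 1L)
    hit <- cands[cands$orientation == "forward" & cands$cleaved_allele == "1" &
                   cands$motif_start == fx$motif_start, ]
    expect_gte(nrow(hit), 1L)
    expect_identical(hit$mismatch_count[1L], 1L)
    expect_identical(hit$mismatch_positions[[1L]], fx$mismatch_pos)
  }
})

test_that("scanner equals the brute-force enumerator on random planted pairs", {
  set.seed(32)
  sub <- subcatalogue()
  for (i in 1:50) {
    fx <- random_pair()
    cmp <- tryCatch(quiet_compare(fx$seq1, fx$seq2), dcaps_error = function(e) NULL)
    if (is.null(cmp)) next
    got <- scan_keys(scan_assays(cmp, sub, 1L))
    want <- oracle_scan(fx$seq1, fx$seq2, sub, 1L)
    expect_identical(got, want)
  }
})

test_that("raising the mismatch allowance never removes a candidate", {
  set.seed(33)
  sub <- subcatalogue()
  for (i in 1:20) {
    fx <- random_pair()
    cmp <- tryCatch(quiet_compare(fx$seq1, fx$seq2), dcaps_error = function(e) NULL)
    if (is.null(cmp)) next
    k0 <- scan_keys(scan_assays(cmp, sub, 0L))
    k1 <- scan_keys(scan_assays(cmp, sub, 1L))
    k2 <- scan_keys(scan_assays(cmp, sub, 2L))
    expect_true(all(k0 %in% k1))
    expect_true(all(k1 %in% k2))
  }
})

test_that("downstream exact sites reject a candidate within the amplicon window only", {
  # diagnostic EcoRI CAPS site at the SNP, second exact site 30 nt downstream
  mid <- "CTGGACCTGGTGACAGTGCAAGTCCAT"
  s1 <- paste0(LEFT25, "GAATTC", mid, "GAATTC", "TGGACCTG")
  s2 <- paste0(LEFT25, "GACTTC", mid, "GAATTC", "TGGACCTG")
  cmp <- compare_alleles(s1, s2)
  ecori <- filter_enzymes(load_enzymes(), include = "EcoRI")
  cands <- scan_assays(cmp, ecori, 0L)
  fwd <- cands[cands$orientation == "forward", ]
  expect_identical(nrow(fwd), 1L)
  kept100 <- reject_downstream_cutters(cands, cmp, amplicon_len = 100L)
  expect_false(any(kept100$orientation == "forward"))
  kept25 <- reject_downstream_cutters(cands, cmp, amplicon_len = 25L)
  expect_true(any(kept25$orientation == "forward"))
  expect_true(all(kept25$truncated_window[kept25$orientation == "forward"] == FALSE))
  # the reverse-complement pass has no downstream site and survives
  expect_true(any(kept100$orientation == "reverse_complement"))
})

test_that("fragment prediction: offsets, conservation, and the no-site case", {
  enz <- load_enzymes()
  ecori <- enz[enz$name == "EcoRI", ]
  amp <- paste0(strrep("A", 10), "GAATTC", strrep("T", 34))
  expect_identical(predict_fragments(amp, ecori), c(11L, 39L))
  expect_identical(predict_fragments(strrep("ACGT", 10), ecori), 40L)
  expect_error(predict_fragments("GAATTCNN", ecori), class = "dcaps_degenerate_amplicon")
  no_cut <- ecori; no_cut$cut_top <- NA_integer_
  expect_error(predict_fragments(amp, no_cut), class = "dcaps_unknown_cut_offset")
  set.seed(34)
  sub <- subcatalogue()
  for (i in 1:100) {
    a <- random_dna(sample(40:120, 1))
    e <- sub[sample(nrow(sub), 1), ]
    expect_identical(sum(predict_fragments(a, e)), nchar(a))
  }
})

test_that("scanning mirrored inputs yields the mirror-image candidate set", {
  set.seed(35)
  sub <- subcatalogue()
  for (i in 1:10) {
    fx <- random_pair()
    cmp <- quiet_compare(fx$seq1, fx$seq2)
    cmp_rc <- quiet_compare(reverse_complement(fx$seq1), reverse_complement(fx$seq2))
    a <- scan_assays(cmp, sub, 1L)
    b <- scan_assays(cmp_rc, sub, 1L)
    flip <- c(forward = "reverse_complement", reverse_complement = "forward")
    a_keys <- sort(paste(unname(flip[a$orientation]), a$scanned_allele, a$enzyme,
                         a$motif_start, a$mismatch_count, sep = "|"))
    b_keys <- sort(paste(b$orientation, b$scanned_allele, b$enzyme,
                         b$motif_start, b$mismatch_count, sep = "|"))
    expect_identical(a_keys, b_keys)
  }
})
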