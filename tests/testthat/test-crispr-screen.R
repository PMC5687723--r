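test_that("the cut bond is located at the -3 position on either strand", {
  set.seed(61)
  flank <- random_dna(40)
  proto <- "GGTTGAGATCAAGATAGACA"
  wt_fwd <- paste0(flank, proto, random_dna(40))
  cut <- locate_cut_site(wt_fwd, proto)
  expect_identical(cut$cut_pos, 40L + 17L)
  expect_identical(cut$strand, "+")
  # same protospacer supplied against the reverse strand
  wt_rev <- paste0(flank, reverse_complement(proto), random_dna(40))
  cut_r <- locate_cut_site(wt_rev, proto)
  expect_identical(cut_r$strand, "-")
  expect_identical(cut_r$cut_pos, 40L + 3L)  # 3 protospacer bases remain 5' of the bond
  expect_error(locate_cut_site(random_dna(80), proto),
               class = "dcaps_protospacer_not_found")
  wt_dup <- paste0(flank, proto, random_dna(10), proto)
  expect_error(locate_cut_site(wt_dup, proto),
               class = "dcaps_multiple_protospacer_hits")
})

test_that("the default profile simulates four insertions and one deletion at the bond", {
  v <- simulate_edits("AAAATTTT", 4L)
  expect_identical(length(v), 5L)
  expect_identical(unname(v[["+A"]]), "AAAAATTTT")
  expect_identical(unname(v[["+C"]]), "AAAACTTTT")
  expect_identical(unname(v[["-1"]]), "AAATTTT")
  empty <- edit_profile(character(0), character(0), numeric(0))
  expect_identical(length(simulate_edits("AAAATTTT", 4L, empty)), 0L)
  v2 <- simulate_edits("ACGTACGTACGT", 6L,
                       edit_profile(kind = "deletion", payload = "2", weight = 1))
  expect_identical(nchar(v2[["-2"]]), 10L)
})

test_that("the last shared base accounts for homopolymer run-back", {
  wt <- "AACCGGTTAA"
  expect_identical(last_shared_base_all(wt, wt), 10L)
  expect_identical(last_shared_base_all(wt, c("AACCGATTAA", "AACCGGTAA")), 5L)
  # deleting a base inside a run: the naive cut position overestimates sharing
  wt2 <- "ACGTTTTACG"
  del <- "ACGTTTACG"   # one T gone; prefix agreement ends inside the run,
                       # one base 5' of the last T of the wild type
  expect_identical(last_shared_base_all(wt2, del), 6L)
  set.seed(62)
  for (i in 1:50) {
    locus <- make_crispr_locus(100L)
    v <- simulate_edits(locus$wt, locus$cut_pos)
    L <- last_shared_base_all(locus$wt, v)
    wchars <- strsplit(locus$wt, "")[[1]]
    brute <- function(variant) {
      vc <- strsplit(variant, "")[[1]]
      k <- 0L
      while (k < min(length(wchars), length(vc)) && wchars[k + 1L] == vc[k + 1L]) k <- k + 1L
      k
    }
    expect_identical(L, min(vapply(v, brute, integer(1))))
    expect_lte(L, locus$cut_pos)
  }
})

test_that("loss fractions come in fifths, wild type is always cut, and calls match the digest oracle", {
  set.seed(63)
  sub <- subcatalogue()
  profile <- edit_profile()
  n_assays <- 0L
  for (i in 1:15) {
    locus <- make_crispr_locus(120L)
    wt <- locus$wt
    attr(wt, "protospacer") <- locus$protospacer
    res <- screen_assays(wt, locus$protospacer, sub, max_mismatch = 1L,
                         loss_threshold = 1, amplicon_len = 150L)
    for (j in seq_len(nrow(res))) {
      row <- res[j, , drop = FALSE]
      expect_true(any(abs(row$loss_fraction - c(0, .2, .4, .6, .8, 1)) < 1e-9))
      calls <- oracle_event_calls(row, wt, profile, 150L)
      expect_identical(unname(row$per_event_calls[[1]]),
                       unname(ifelse(calls, "cut", "uncut")))
      expect_equal(row$loss_fraction, mean(calls))
      n_assays <- n_assays + 1L
    }
  }
  expect_gt(n_assays, 10L)
})

test_that("an enzyme whose site straddles the cut as TTT^AAA misses A/T insertions", {
  # engineer the cut bond to fall exactly between TTT and AAA: inserting A
  # or T regenerates a DraI site in a shifted register, C/G and the
  # deletion destroy it
  set.seed(64)
  drai <- filter_enzymes(load_enzymes(), include = "DraI")
  repeat {
    proto <- paste0(random_dna(14), "TTTAAA")
    locus <- paste0(random_dna(50), proto, random_dna(40))
    sites <- oracle_exact_starts(locus, "TTTAAA")
    if (identical(sites, 65L) && substr(locus, 64L, 64L) != "T" &&
        sum(gregexpr(proto, locus, fixed = TRUE)[[1]] > 0L) == 1L &&
        gregexpr(reverse_complement(proto), locus, fixed = TRUE)[[1]][1] == -1L) break
  }
  res0 <- screen_assays(locus, proto, drai, loss_threshold = 0)
  expect_identical(nrow(res0), 0L)  # 40% of events would be missed
  res <- screen_assays(locus, proto, drai, loss_threshold = 0.4)
  expect_gte(nrow(res), 1L)
  expect_identical(unique(res$loss_fraction), 0.4)
  calls <- res$per_event_calls[[1]]
  expect_identical(unname(calls[c("+A", "+T")]), c("cut", "cut"))
  expect_identical(unname(calls[c("+C", "+G", "-1")]), c("uncut", "uncut", "uncut"))
})

test_that("raising the loss threshold never shrinks the assay set, and reports are deterministic", {
  set.seed(65)
  sub <- subcatalogue()
  locus <- make_crispr_locus(120L)
  key <- function(res) paste(res$enzyme, res$orientation, res$motif_start,
                             res$motif_strand, sep = "|")
  prev <- character(0)
  for (thr in c(0, 0.2, 0.6, 1)) {
    res <- screen_assays(locus$wt, locus$protospacer, sub, loss_threshold = thr)
    expect_true(all(prev %in% key(res)))
    prev <- key(res)
  }
  a <- screen_assays(locus$wt, locus$protospacer, sub, loss_threshold = 1)
  b <- screen_assays(locus$wt, locus$protospacer, sub, loss_threshold = 1)
  expect_identical(a, b)
})
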