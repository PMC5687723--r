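# End-to-end pipelines behind the two CLI subcommands: known-allele assay
# design (compare -> scan -> reject -> primer -> Tm -> fragments) and
# CRISPR screening. Reports are plain data frames with a config attribute
# echoing every effective parameter, so repeated runs on the same inputs are
# byte-identical.

#' Run configuration
#'
#' Collects every user-facing option with its default. Defaults: 1 mismatch,
#' 150 nt amplicon window, Tm-targeted primers at 60 C, 3' mismatches
#' rejected, loss threshold 0, packaged enzyme catalogue.
#'
#' @param max_mismatch Maximum engineered primer mismatches (default 1).
#' @param amplicon_len Amplicon window in nt (default 150).
#' @param primer_mode `"target_tm"` or `"fixed_length"`.
#' @param target_tm Target Tm, Celsius (default 60).
#' @param primer_length Length for fixed-length mode (default 25).
#' @param allow_3prime_GT Allow 3' G/T mispairings (default `FALSE`).
#' @param loss_threshold Acceptable fraction of missed editing events
#'   (screening mode; default 0).
#' @param primer_conc,na_conc Tm parameters, mol/L.
#' @param include,exclude Enzyme name filters.
#' @return A list of class `run_config`.
#' @export
run_config <- function(max_mismatch = 1L, amplicon_len = 150L,
                       primer_mode = c("target_tm", "fixed_length"),
                       target_tm = 60, primer_length = 25L,
                       allow_3prime_GT = FALSE, loss_threshold = 0,
                       primer_conc = 50e-9, na_conc = 50e-3,
                       include = NULL, exclude = NULL) {
  primer_mode <- match.arg(primer_mode)
  structure(list(
    max_mismatch = as.integer(max_mismatch),
    amplicon_len = as.integer(amplicon_len),
    primer_mode = primer_mode, target_tm = target_tm,
    primer_length = as.integer(primer_length),
    allow_3prime_GT = isTRUE(allow_3prime_GT),
    loss_threshold = loss_threshold,
    primer_conc = primer_conc, na_conc = na_conc,
    include = include, exclude = exclude
  ), class = "run_config")
}

.opts_from_config <- function(cfg) {
  primer_options(
    mode = cfg$primer_mode, target_tm = cfg$target_tm,
    length = cfg$primer_length, max_mismatch = cfg$max_mismatch,
    allow_3prime_GT = cfg$allow_3prime_GT,
    tm = tm_parameters(cfg$primer_conc, cfg$na_conc)
  )
}

#' Design CAPS/dCAPS assays for two known alleles
#'
#' The full known-allele pipeline. Input order does not matter: no
#' assumption is made about which sequence is wild type, and the report
#' states which allele each assay cleaves.
#'
#' @param seq1,seq2 The two allele sequences (strings or FASTA paths via
#'   [read_sequences()] upstream).
#' @param cfg A [run_config()].
#' @param enzymes An `enzyme_table`; filtered by `cfg$include`/`exclude`.
#' @return A data frame of class `dcaps_report`: one row per designed assay
#'   with enzyme, orientation, cleaved allele, primer (5' to 3'), mismatch
#'   positions (1-based from the primer 5' end), Tm, and the predicted
#'   fragment sizes of each allele's amplicon. The effective configuration
#'   is attached as `attr(, "config")`.
#' @export
design_known <- function(seq1, seq2, cfg = run_config(),
                         enzymes = load_enzymes()) {
  enzymes <- filter_enzymes(enzymes, cfg$include, cfg$exclude)
  cmp <- compare_alleles(seq1, seq2)
  cands <- scan_assays(cmp, enzymes, cfg$max_mismatch, cfg$amplicon_len)
  cands <- reject_downstream_cutters(cands, cmp, cfg$amplicon_len)
  opts <- .opts_from_config(cfg)
  rows <- list()
  for (i in seq_len(nrow(cands))) {
    row <- cands[i, , drop = FALSE]
    design <- tryCatch(design_primer(row, cmp, opts, enzymes),
                       dcaps_error = function(e) NULL)
    if (is.null(design)) next
    frags <- .report_fragments(design, cmp, enzymes, cfg$amplicon_len)
    out <- data.frame(
      enzyme = design$enzyme, motif = design$motif,
      orientation = design$orientation, cleaved_allele = design$cleaved_allele,
      is_caps = design$is_caps, primer = design$sequence,
      primer_length = design$length, mismatch_count = design$mismatch_count,
      tm_celsius = round(design$tm_celsius, 2L),
      motif_start = design$motif_start,
      fragments_allele1 = frags$f1, fragments_allele2 = frags$f2,
      truncated_window = row$truncated_window,
      warnings = paste(design$warnings, collapse = "; "),
      stringsAsFactors = FALSE
    )
    out$mismatch_positions <- list(design$mismatch_positions)
    rows[[length(rows) + 1L]] <- out
  }
  report <- if (length(rows)) do.call(rbind, rows) else .empty_report()
  rownames(report) <- NULL
  attr(report, "config") <- cfg
  class(report) <- c("dcaps_report", "data.frame")
  report
}

.empty_report <- function() {
  out <- data.frame(
    enzyme = character(), motif = character(), orientation = character(),
    cleaved_allele = character(), is_caps = logical(), primer = character(),
    primer_length = integer(), mismatch_count = integer(),
    tm_celsius = numeric(), motif_start = integer(),
    fragments_allele1 = character(), fragments_allele2 = character(),
    truncated_window = logical(), warnings = character(),
    stringsAsFactors = FALSE
  )
  out$mismatch_positions <- list()
  out
}

# Fragment-size strings for the report: primer substituted into each
# allele's oriented sequence, windowed to the amplicon, digested.
.report_fragments <- function(design, cmp, enzymes, amplicon_len) {
  cc <- if (design$orientation == "forward") cmp else reverse_comparison(cmp)
  e <- enzymes[enzymes$name == design$enzyme, , drop = FALSE][1L, ]
  fr <- function(template) {
    tb <- seq_bits(template)
    tb[design$start:(design$start + design$length - 1L)] <- seq_bits(design$sequence)
    hi <- min(length(tb), design$start + amplicon_len - 1L)
    amp <- bits_to_seq(tb[design$start:hi])
    if (!is_concrete(amp) || is.na(e$cut_top)) return("site presence/absence only")
    paste(predict_fragments(amp, e), collapse = "+")
  }
  list(f1 = fr(cc$seq1), f2 = fr(cc$seq2))
}

#' Design screening assays for a CRISPR target
#'
#' Wrapper over [screen_assays()] with a [run_config()], producing a
#' `dcaps_report`-style data frame.
#'
#' @param wt Wild-type sequence.
#' @param protospacer 20-nt target, 5' to 3', no PAM.
#' @param cfg A [run_config()].
#' @param enzymes An `enzyme_table`.
#' @param profile An [edit_profile()].
#' @return A `screening_results` data frame (see [screen_assays()]) with the
#'   configuration attached.
#' @export
design_screen <- function(wt, protospacer, cfg = run_config(),
                          enzymes = load_enzymes(), profile = edit_profile()) {
  enzymes <- filter_enzymes(enzymes, cfg$include, cfg$exclude)
  res <- screen_assays(wt, protospacer, enzymes,
                       max_mismatch = cfg$max_mismatch,
                       loss_threshold = cfg$loss_threshold,
                       amplicon_len = cfg$amplicon_len,
                       profile = profile, opts = .opts_from_config(cfg))
  attr(res, "config") <- cfg
  res
}

#' Write a report as TSV or JSON
#'
#' TSV flattens list columns into comma-separated strings; JSON preserves
#' them. A header block (TSV comments / a `config` object in JSON) echoes
#' every effective parameter for provenance.
#'
#' @param report A `dcaps_report` or `screening_results` data frame.
#' @param path Output path or `""` for stdout.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path = "", format = c("tsv", "json")) {
  format <- match.arg(format)
  cfg <- attr(report, "config")
  df <- as.data.frame(report)
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], paste, character(1L), collapse = ",")
    }
  }
  if (format == "tsv") {
    con <- if (nzchar(path)) file(path, "w") else stdout()
    if (nzchar(path)) on.exit(close(con))
    if (!is.null(cfg)) {
      for (key in names(unclass(cfg))) {
        val <- cfg[[key]]
        writeLines(sprintf("# %s=%s", key,
                           if (is.null(val)) "" else paste(val, collapse = ",")), con)
      }
    }
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    payload <- list(config = if (is.null(cfg)) NULL else unclass(cfg),
                    assays = df)
    json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                             null = "null", pretty = TRUE)
    if (nzchar(path)) writeLines(json, path) else writeLines(json)
  }
  invisible(path)
}

#' @export
print.dcaps_report <- function(x, ...) {
  cat(sprintf("CAPS/dCAPS design report: %d assay(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- as.data.frame(x)[, c("enzyme", "orientation", "cleaved_allele",
                                 "primer", "mismatch_count", "tm_celsius",
                                 "fragments_allele1", "fragments_allele2")]
    print(utils::head(show, 15L), ...)
    if (nrow(x) > 15L) cat(sprintf("... and %d more\n", nrow(x) - 15L))
  }
  invisible(x)
}
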