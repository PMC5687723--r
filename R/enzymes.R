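# Restriction-enzyme catalogue: loading, validation, filtering, writing.
#
# TSV dialect (documented in the README):
#   name<TAB>site[<TAB>extra]
# where `site` is either a recognition motif with '^' marking the top-strand
# cut (e.g. G^AATTC; the bottom-strand cut of a palindromic motif is inferred
# symmetrically), or MOTIF(t/b) for enzymes cutting downstream of their motif
# (e.g. GGTCTC(1/5): top cut t bases after the motif, bottom cut b bases
# after). `extra` is a bottom-cut offset (0-based bond index from motif
# start), or one of the flags `nicking` / `double`. Lines starting with '#'
# are comments. A motif without cut annotation is usable for presence/absence
# calls only.

.default_enzyme_path <- function() {
  system.file("extdata", "restriction_enzymes.tsv", package = "dcaps", mustWork = TRUE)
}

parse_enzyme_site <- function(site, line_no = NA_integer_) {
  iis <- regmatches(site, regexec("^([A-Z]+)\\((-?[0-9]+)/(-?[0-9]+)\\)$", site))[[1L]]
  if (length(iis)) {
    motif <- iis[[2L]]
    m <- nchar(motif)
    return(list(motif = motif,
                cut_top = m + as.integer(iis[[3L]]),
                cut_bottom = m + as.integer(iis[[4L]])))
  }
  carets <- gregexpr("\\^", site)[[1L]]
  if (carets[1L] == -1L) {
    return(list(motif = site, cut_top = NA_integer_, cut_bottom = NA_integer_))
  }
  if (length(carets) > 1L) {
    stop_dcaps("malformed_enzyme_record",
               "line %d: more than one '^' in site '%s'", line_no, site)
  }
  motif <- sub("\\^", "", site)
  list(motif = motif, cut_top = carets[1L] - 1L, cut_bottom = NA_integer_)
}

#' Load a restriction-enzyme catalogue
#'
#' Parses the packaged snapshot (default) or a user TSV in the documented
#' dialect, validates motifs, and by default drops nicking and double-cutting
#' enzymes, which cannot produce a clean diagnostic digest. The result is
#' sorted by name (stable, C locale).
#'
#' @param path Path to an enzyme TSV; `NULL` for the packaged snapshot.
#' @param drop_flagged Drop nicking/double-cutting enzymes (default `TRUE`).
#' @return A data frame of class `enzyme_table` with columns `name`, `site`
#'   (the raw dialect string), `motif`, `cut_top`, `cut_bottom` (0-based bond
#'   offsets from motif start; `NA` when unknown), `is_nicking`,
#'   `is_double_cutter`, `is_palindromic`.
#' @export
load_enzymes <- function(path = NULL, drop_flagged = TRUE) {
  if (is.null(path)) path <- .default_enzyme_path()
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n <- length(fields)
  name <- character(n); site <- character(n); extra <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 2L || !nzchar(f[[1L]]) || !nzchar(f[[2L]])) {
      stop_dcaps("malformed_enzyme_record", "line %d: expected name<TAB>site",
                 line_no[[i]])
    }
    name[[i]] <- f[[1L]]; site[[i]] <- f[[2L]]
    extra[[i]] <- if (length(f) >= 3L) f[[3L]] else ""
  }
  motif <- character(n); cut_top <- integer(n); cut_bottom <- integer(n)
  for (i in seq_len(n)) {
    p <- parse_enzyme_site(site[[i]], line_no[[i]])
    motif[[i]] <- p$motif; cut_top[[i]] <- p$cut_top; cut_bottom[[i]] <- p$cut_bottom
  }
  bad <- vapply(motif, function(m) any(seq_bits(m) == 0L), logical(1L))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop_dcaps("malformed_enzyme_record", "line %d: invalid motif '%s'",
               line_no[[i]], motif[[i]])
  }
  if (any(nchar(motif) < 4L)) {
    i <- which(nchar(motif) < 4L)[1L]
    stop_dcaps("malformed_enzyme_record",
               "line %d: motif '%s' shorter than 4 nt", line_no[[i]], motif[[i]])
  }
  is_nicking <- extra == "nicking"
  is_double <- extra == "double"
  num_extra <- suppressWarnings(as.integer(extra))
  cut_bottom[!is.na(num_extra)] <- num_extra[!is.na(num_extra)]
  is_pal <- vapply(motif, function(m) identical(m, reverse_complement(m)), logical(1L))
  # palindromic motif with a known top cut: bottom cut is the mirror bond
  infer <- is_pal & !is.na(cut_top) & is.na(cut_bottom)
  cut_bottom[infer] <- nchar(motif)[infer] - cut_top[infer]
  out <- data.frame(
    name = name, site = site, motif = motif,
    cut_top = cut_top, cut_bottom = cut_bottom,
    is_nicking = is_nicking, is_double_cutter = is_double,
    is_palindromic = is_pal,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(out$name, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  if (drop_flagged) {
    out <- out[!(out$is_nicking | out$is_double_cutter), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("enzyme_table", "data.frame")
  out
}

#' Subset an enzyme catalogue by name
#'
#' `include`, when given, wins: the result is exactly the named enzymes (in
#' catalogue order). Otherwise `exclude` removes names from the default set.
#' Names resolve case-insensitively; unknown names raise a warning, not an
#' error.
#'
#' @param enzymes An `enzyme_table` from [load_enzymes()].
#' @param include,exclude Character vectors of enzyme names, or `NULL`.
#' @return The filtered `enzyme_table`.
#' @export
filter_enzymes <- function(enzymes, include = NULL, exclude = NULL) {
  have <- tolower(enzymes$name)
  check_known <- function(names) {
    unknown <- names[!(tolower(names) %in% have)]
    if (length(unknown)) {
      warn_dcaps("unknown_enzyme_name", "unknown enzyme name(s): %s",
                 paste(unknown, collapse = ", "))
    }
  }
  if (!is.null(include)) {
    check_known(include)
    out <- enzymes[have %in% tolower(include), , drop = FALSE]
  } else if (!is.null(exclude)) {
    check_known(exclude)
    out <- enzymes[!(have %in% tolower(exclude)), , drop = FALSE]
  } else {
    out <- enzymes
  }
  rownames(out) <- NULL
  class(out) <- c("enzyme_table", "data.frame")
  out
}

#' Write an enzyme catalogue in the canonical TSV dialect
#'
#' Inverse of [load_enzymes()] for the packaged dialect: writing the loaded
#' snapshot reproduces the file byte-for-byte (the snapshot carries no
#' comments and is stored name-sorted).
#'
#' @param enzymes An `enzyme_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enzyme_table <- function(enzymes, path) {
  extra <- character(nrow(enzymes))
  extra[enzymes$is_nicking] <- "nicking"
  extra[enzymes$is_double_cutter] <- "double"
  # an explicit bottom cut that could not be inferred from the site string
  needs_bottom <- !enzymes$is_nicking & !enzymes$is_double_cutter &
    !is.na(enzymes$cut_bottom) & !grepl("\\(", enzymes$site) &
    !(enzymes$is_palindromic & !is.na(enzymes$cut_top) &
        enzymes$cut_bottom == nchar(enzymes$motif) - enzymes$cut_top)
  extra[needs_bottom] <- as.character(enzymes$cut_bottom[needs_bottom])
  lines <- ifelse(nzchar(extra),
                  paste(enzymes$name, enzymes$site, extra, sep = "\t"),
                  paste(enzymes$name, enzymes$site, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.enzyme_table <- function(x, ...) {
  cat(sprintf("Restriction enzyme catalogue: %d enzymes\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}
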