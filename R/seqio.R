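#' @title FASTA input and report output
#' @name seqio
NULL

#' Extract the sequence identifier from a FASTA header
#'
#' The identifier is the first whitespace-delimited token of the
#' description line (without the leading `>`). Pipe-delimited tokens such
#' as `sp|P12345|NAME_BACT` are kept whole — the full token is the
#' identifier, never silently shortened.
#'
#' @param header FASTA description line without the leading `>`.
#' @return the identifier string.
#' @export
extract_seq_id <- function(header) {
  header <- trimws(header)
  if (!nzchar(header)) stop("empty FASTA header")
  strsplit(header, "[[:space:]]+")[[1L]][[1L]]
}

#' Read a proteome FASTA file
#'
#' Sequences are uppercased, trailing `*` stop glyphs are stripped, and any
#' remaining letter outside the 20 amino acids plus X is replaced by X with
#' a warning. Duplicate identifiers, empty sequences and text before the
#' first `>` are errors.
#'
#' @param path FASTA file path.
#' @return named list of [protein_record()]s in file order, keyed by seq_id.
#' @export
read_fasta <- function(path) {
  raw <- readLines(path, warn = FALSE)
  nonblank <- raw[nzchar(trimws(raw))]
  if (length(nonblank) == 0L) stop("no sequences in ", path)
  if (!startsWith(trimws(nonblank[[1L]]), ">"))
    stop("text before the first '>' in ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no sequences in ", path)
  headers <- names(aa)
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*+$", "", seqs)
  ids <- vapply(headers, extract_seq_id, character(1), USE.NAMES = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id: ", dup[[1L]])
  empty <- ids[!nzchar(seqs)]
  if (length(empty)) stop("empty sequence for id: ", empty[[1L]])
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad)) {
    warning("non-amino-acid letters replaced by X in: ",
            paste(ids[bad], collapse = ", "))
    seqs[bad] <- gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", seqs[bad])
  }
  desc <- vapply(seq_along(ids), function(i) {
    trimws(sub(paste0("^", gsub("([.|()\\^{}+$*?\\[\\]\\\\])", "\\\\\\1",
                                ids[[i]])), "", trimws(headers[[i]])))
  }, character(1))
  recs <- lapply(seq_along(ids), function(i)
    protein_record(ids[[i]], seqs[[i]], desc[[i]]))
  names(recs) <- ids
  recs
}

#' Write proteome FASTA
#'
#' @param proteins named list of [protein_record()]s.
#' @param path output file.
#' @param width residues per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in proteins) {
    header <- if (nzchar(p$description))
      paste(p$seq_id, p$description) else p$seq_id
    writeLines(paste0(">", header), con)
    starts <- seq(1L, p$length, by = width)
    writeLines(substring(p$sequence, starts,
                         pmin(starts + width - 1L, p$length)), con)
  }
  invisible(path)
}

# RFC 4180 cell quoting: quote only when the field needs it.
.csv_cell <- function(x) {
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Format localization calls as CSV text
#'
#' Columns `seqid,category,details,description`, one row per protein in
#' input order; `details` joined with `";"`; fields containing commas or
#' quotes are quoted per RFC 4180.
#'
#' @param calls list of [localization_call()]s.
#' @param proteins named list of [protein_record()]s (for descriptions).
#' @return character vector of CSV lines (header first).
#' @export
format_calls_csv <- function(calls, proteins) {
  rows <- vapply(calls, function(cl) {
    desc <- proteins[[cl$seq_id]]$description
    if (is.null(desc)) desc <- ""
    paste(.csv_cell(c(cl$seq_id, cl$category,
                      paste(cl$details, collapse = ";"), desc)),
          collapse = ",")
  }, character(1))
  c("seqid,category,details,description", rows)
}

#' Write localization calls to a CSV file
#'
#' @inheritParams format_calls_csv
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calls_csv <- function(calls, proteins, path) {
  writeLines(format_calls_csv(calls, proteins), path)
  invisible(path)
}

#' Plain-text category summary
#'
#' For the Gram-positive protocol the three PSE categories are rolled up
#' into a single `PSE(total)` row alongside `CYTOPLASM(non-PSE)`,
#' `MEMBRANE(non-PSE)` and `SECRETED`; for the Gram-negative protocol every
#' category gets its own row. The final `Total` row always equals the
#' number of input proteins.
#'
#' @param calls list of [localization_call()]s.
#' @param protocol `"gram_pos"` or `"gram_neg"`.
#' @return character vector of summary lines.
#' @export
format_summary <- function(calls, protocol = c("gram_pos", "gram_neg")) {
  protocol <- match.arg(protocol)
  cats <- vapply(calls, `[[`, character(1), "category")
  counts <- table(factor(cats, levels = protocol_categories(protocol)))
  if (protocol == "gram_pos") {
    pse <- sum(counts[c("PSE-Membrane", "PSE-Cellwall", "PSE-Lipoprotein")])
    rows <- c("CYTOPLASM(non-PSE)" = unname(counts["CYTOPLASM(non-PSE)"]),
              "MEMBRANE(non-PSE)" = unname(counts["MEMBRANE(non-PSE)"]),
              "PSE(total)" = pse,
              "SECRETED" = unname(counts["SECRETED"]))
  } else {
    rows <- stats::setNames(as.integer(counts), names(counts))
  }
  rows <- c(rows, Total = length(calls))
  w <- max(nchar(names(rows)))
  sprintf("%-*s %6d", w, names(rows), rows)
}

#' Write the category summary
#'
#' @inheritParams format_summary
#' @param file connection or path; defaults to standard output.
#' @return the summary lines, invisibly.
#' @export
write_summary <- function(calls, protocol = c("gram_pos", "gram_neg"),
                          file = stdout()) {
  lines <- format_summary(calls, protocol)
  writeLines(lines, file)
  invisible(lines)
}
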