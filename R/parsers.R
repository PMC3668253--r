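#' @title Predictor output parsers
#' @description
#' Each external predictor is wrapped as a plugin whose testable half is a
#' pure parser: raw output text (or a saved HTML result page) in,
#' annotation entries keyed by sequence id out. The exact output dialect
#' each parser targets is pinned by the bundled fixture files: SignalP 4.0
#' short format, LipoP 1.0 short format, TMHMM 2.0 long format, MEMSAT3
#' text output, HMMER 3.x hmmsearch tabular output, TatFind result text,
#' and the result pages of the BOMP, TMB-HUNT and TMBETADISC-RBF services.
#' Parsers never touch keys they do not own, so merging outputs of plugins
#' with disjoint keys is order-independent.
#' @name predictor_parsers
NULL

.split_fields <- function(line) strsplit(trimws(line), "[[:space:]]+")[[1L]]

#' Parse SignalP 4 short-format output
#'
#' One data row per sequence; `#` lines are comments. The decision column
#' (`?`) is `Y` or `N`; the `Ymax` position column reports the first
#' residue of the mature protein, so the stored cleavage position (last
#' residue of the signal peptide) is that value minus one.
#'
#' @param text character vector of lines, or a single string.
#' @return named list: seq_id -> list(is_signalp, signalp_cleave_pos);
#'   the cleavage entry is present only for positive predictions.
#' @export
parse_signalp <- function(text) {
  lines <- .as_lines(text)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "#")) next
    f <- .split_fields(ln)
    if (length(f) < 12L || is.na(suppressWarnings(as.integer(f[[5L]]))) ||
        !f[[10L]] %in% c("Y", "N"))
      stop("malformed SignalP data row at line ", i, ": '", ln, "'")
    id <- f[[1L]]
    if (f[[10L]] == "Y") {
      out[[id]] <- list(is_signalp = TRUE,
                        signalp_cleave_pos = as.integer(f[[5L]]) - 1L)
    } else {
      out[[id]] <- list(is_signalp = FALSE)
    }
  }
  out
}

#' Parse LipoP 1 short-format output
#'
#' A sequence is a lipoprotein iff its best class is `SpII`; the
#' `cleavage=a-b` field gives the last residue before the lipidated
#' cysteine (the mature protein starts at `a + 1`).
#'
#' @param text character vector of lines, or a single string.
#' @return named list: seq_id -> list(is_lipop, lipop_cleave_pos).
#' @export
parse_lipop <- function(text) {
  lines <- .as_lines(text)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- .split_fields(ln)
    if (length(f) < 3L || !grepl("LipoP", f[[2L]]))
      stop("malformed LipoP row at line ", i, ": '", ln, "'")
    id <- f[[1L]]
    if (f[[3L]] == "SpII") {
      m <- regmatches(ln, regexec("cleavage=([0-9]+)-([0-9]+)", ln))[[1L]]
      if (length(m) != 3L)
        stop("SpII prediction without a cleavage field at line ", i)
      out[[id]] <- list(is_lipop = TRUE,
                        lipop_cleave_pos = as.integer(m[[2L]]))
    } else {
      out[[id]] <- list(is_lipop = FALSE)
    }
  }
  out
}

#' Parse TMHMM 2 long-format output
#'
#' Data rows are `<id> TMHMM2.0 <inside|outside|TMhelix> <start> <stop>`.
#' The N-terminal side is the side of the first topology segment; proteins
#' whose rows contain no `TMhelix` get an empty helix list. Segments must
#' tile the sequence contiguously with sides alternating across each
#' helix; anything else is an error.
#'
#' @param text character vector of lines, or a single string.
#' @return named list: seq_id -> list(tmhmm_helices, tmhmm_n_side).
#' @export
parse_tmhmm <- function(text) {
  lines <- .as_lines(text)
  segs <- list()
  order_ids <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- .split_fields(ln)
    if (length(f) != 5L || !f[[3L]] %in% c("inside", "outside", "TMhelix"))
      stop("malformed TMHMM row at line ", i, ": '", ln, "'")
    id <- f[[1L]]
    if (is.null(segs[[id]])) order_ids <- c(order_ids, id)
    segs[[id]] <- rbind(segs[[id]],
                        data.frame(label = f[[3L]],
                                   start = as.integer(f[[4L]]),
                                   stop = as.integer(f[[5L]])))
  }
  out <- list()
  for (id in order_ids) {
    s <- segs[[id]]
    if (is.unsorted(s$start, strictly = TRUE) ||
        (nrow(s) > 1L && any(s$start[-1L] != s$stop[-nrow(s)] + 1L)))
      stop("overlapping or non-contiguous TMHMM segments for ", id)
    non_tm <- s$label[s$label != "TMhelix"]
    if (length(non_tm) > 1L && any(non_tm[-1L] == non_tm[-length(non_tm)]))
      stop("non-alternating TMHMM segments for ", id)
    helix <- s$label == "TMhelix"
    out[[id]] <- list(
      tmhmm_helices = .as_span_matrix(
        lapply(which(helix), function(k) c(s$start[[k]], s$stop[[k]]))),
      tmhmm_n_side = s$label[[1L]])
  }
  out
}

#' Parse MEMSAT3 output for one sequence
#'
#' MEMSAT3 writes one output file per query. The pinned dialect carries
#' the query id on a `# SEQ <id>` line, a `FINAL PREDICTION` block with
#' one `k: (start-stop)` line per helix, and an `N-terminal: in|out`
#' orientation line mapped onto `inside`/`outside`.
#'
#' @param text character vector of lines, or a single string (one sequence).
#' @return named list with one entry:
#'   seq_id -> list(memsat3_helices, memsat3_n_side).
#' @export
parse_memsat3 <- function(text) {
  lines <- .as_lines(text)
  id_line <- grep("^# SEQ[[:space:]]+", lines, value = TRUE)
  if (length(id_line) != 1L)
    stop("MEMSAT3 output lacks a '# SEQ <id>' line")
  id <- .split_fields(sub("^# SEQ", "", id_line))[[1L]]
  if (!any(grepl("FINAL PREDICTION", lines, fixed = TRUE)))
    stop("MEMSAT3 output for ", id, " lacks a FINAL PREDICTION block")
  hx <- regmatches(lines,
                   regexec("^[0-9]+:[[:space:]]*\\(([0-9]+)-([0-9]+)\\)",
                           lines))
  hx <- Filter(function(m) length(m) == 3L, hx)
  nt <- grep("^N-terminal:", lines, value = TRUE)
  if (length(nt) != 1L)
    stop("MEMSAT3 output for ", id, " lacks an N-terminal orientation line")
  side <- trimws(sub("^N-terminal:", "", nt))
  if (!side %in% c("in", "out"))
    stop("unrecognized MEMSAT3 orientation '", side, "' for ", id)
  res <- list(list(
    memsat3_helices = .as_span_matrix(
      lapply(hx, function(m) as.integer(m[2:3]))),
    memsat3_n_side = if (side == "in") "inside" else "outside"))
  names(res) <- id
  res
}

# split a concatenated multi-sequence MEMSAT3 cache file into blocks
split_memsat3_blocks <- function(text) {
  lines <- .as_lines(text)
  starts <- grep("^# SEQ[[:space:]]+", lines)
  if (length(starts) == 0L) return(list())
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(i) lines[starts[[i]]:ends[[i]]])
}

#' Parse HMMER3 hmmsearch tabular output for one profile
#'
#' Reads the `--tblout`-style per-sequence hits table of one profile
#' search. A hit is accepted when its full-sequence E-value is at most
#' `evalue_max` and its bit score at least `score_min`; accepted hits are
#' reported as `(profile_name, e_value, score)` triples. Scanning a
#' directory of profiles means calling this once per profile and
#' concatenating the per-sequence match lists.
#'
#' @param text character vector of lines, or a single string.
#' @param evalue_max maximum full-sequence E-value (default 0.1).
#' @param score_min minimum bit score (default 10).
#' @return named list: seq_id -> list(hmm_matches = list of triples).
#' @export
parse_hmmsearch <- function(text, evalue_max = 0.1, score_min = 10) {
  lines <- .as_lines(text)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- .split_fields(ln)
    ev <- suppressWarnings(as.numeric(f[5L]))
    sc <- suppressWarnings(as.numeric(f[6L]))
    if (length(f) < 6L || is.na(ev) || is.na(sc))
      stop("malformed hmmsearch hit at line ", i, ": '", ln, "'")
    if (ev > evalue_max || sc < score_min) next
    id <- f[[1L]]
    profile <- f[[3L]]
    prev <- if (is.null(out[[id]])) list() else out[[id]]$hmm_matches
    out[[id]] <- list(hmm_matches = c(prev,
      list(list(profile = profile, e_value = ev, score = sc))))
  }
  out
}

#' Parse TatFind result text
#'
#' Verdict lines have the form `><id> : TRUE ...` or `><id> : FALSE ...`;
#' a sequence is a twin-arginine translocase substrate iff its verdict is
#' TRUE.
#'
#' @param text character vector of lines, or a single string.
#' @return named list: seq_id -> list(is_tatfind).
#' @export
parse_tatfind <- function(text) {
  lines <- .as_lines(text)
  out <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!startsWith(ln, ">")) next
    m <- regmatches(ln, regexec("^>([^[:space:]]+)[[:space:]]*:[[:space:]]*(TRUE|FALSE)", ln))[[1L]]
    if (length(m) != 3L)
      stop("malformed TatFind verdict line: '", ln, "'")
    out[[m[[2L]]]] <- list(is_tatfind = m[[3L]] == "TRUE")
  }
  out
}

.result_table <- function(html, header_word, page_name) {
  doc <- xml2::read_html(paste(.as_lines(html), collapse = "\n"))
  tables <- xml2::xml_find_all(doc, "//table")
  for (tb in tables) {
    head_txt <- xml2::xml_text(xml2::xml_find_first(tb, ".//tr"))
    if (grepl(header_word, head_txt, ignore.case = TRUE)) {
      rows <- xml2::xml_find_all(tb, ".//tr[td]")
      return(lapply(rows, function(r)
        trimws(xml2::xml_text(xml2::xml_find_all(r, ".//td")))))
    }
  }
  stop("unrecognized page layout: no ", page_name, " results table found")
}

#' Parse a saved BOMP result page
#'
#' Extracts the integral beta-barrel category (an integer 1-5) per
#' reported sequence from the results table of a stored BOMP HTML page.
#' Sequences not listed on the page get no entry (negative downstream).
#'
#' @param html character vector of HTML lines, or a single string.
#' @return named list: seq_id -> list(bomp_score).
#' @export
parse_bomp_html <- function(html) {
  rows <- .result_table(html, "Category", "BOMP")
  out <- list()
  for (cells in rows) {
    if (length(cells) < 2L) next
    id <- extract_seq_id(cells[[length(cells) - 1L]])
    out[[id]] <- list(bomp_score = as.integer(cells[[length(cells)]]))
  }
  out
}

#' Parse a saved TMB-HUNT result page
#'
#' Extracts the probability that each sequence is a transmembrane
#' beta-barrel from the results table of a stored TMB-HUNT HTML page.
#'
#' @param html character vector of HTML lines, or a single string.
#' @return named list: seq_id -> list(tmbhunt_prob).
#' @export
parse_tmbhunt_html <- function(html) {
  rows <- .result_table(html, "Probability", "TMB-HUNT")
  out <- list()
  for (cells in rows) {
    if (length(cells) < 2L) next
    id <- extract_seq_id(cells[[1L]])
    out[[id]] <- list(tmbhunt_prob = as.numeric(cells[[length(cells)]]))
  }
  out
}

#' Parse a saved TMBETADISC-RBF result page
#'
#' Each row of the results table carries a verdict cell reading
#' `Outer Membrane Protein` or `Non-Outer Membrane Protein`.
#'
#' @param html character vector of HTML lines, or a single string.
#' @return named list: seq_id -> list(is_tmbetadisc_rbf).
#' @export
parse_tmbetadisc_html <- function(html) {
  rows <- .result_table(html, "Prediction", "TMBETADISC-RBF")
  out <- list()
  for (cells in rows) {
    if (length(cells) < 2L) next
    id <- extract_seq_id(cells[[1L]])
    verdict <- cells[[length(cells)]]
    out[[id]] <- list(
      is_tmbetadisc_rbf = !grepl("^Non-", verdict) &&
        grepl("Outer Membrane Protein", verdict, fixed = TRUE))
  }
  out
}

.as_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  text
}
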