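#' @title Core data structures
#' @description
#' The pipeline keeps one flat named list of proteins, keyed by sequence id.
#' Each protein is a `protein_record`; evidence gathered by the predictor
#' plugins lives in a parallel annotation list (an open key/value map per
#' protein). Topology models and protocol configurations are small classed
#' lists so they print readably and can be validated.
#' @name datamodel
NULL

#' Construct a protein record
#'
#' @param seq_id sequence identifier, unique within a run, no whitespace.
#' @param sequence amino-acid sequence (uppercase, 20 standard letters plus X).
#' @param description remainder of the FASTA header after the identifier.
#' @return a list of class `protein_record` with fields `seq_id`,
#'   `description`, `sequence` and `length`.
#' @export
protein_record <- function(seq_id, sequence, description = "") {
  if (!is.character(seq_id) || length(seq_id) != 1L || !nzchar(seq_id))
    stop("seq_id must be a non-empty string")
  if (grepl("[[:space:]]", seq_id))
    stop("seq_id must not contain whitespace: ", seq_id)
  if (!nzchar(sequence))
    stop("empty sequence for ", seq_id)
  structure(
    list(seq_id = seq_id, description = description,
         sequence = sequence, length = nchar(sequence)),
    class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein %s: %d aa> %s\n", x$seq_id, x$length, x$description))
  invisible(x)
}

# Annotation keys with reserved meaning; anything else is free-form.
.reserved_annotation_keys <- c(
  "is_signalp", "signalp_cleave_pos", "is_lipop", "lipop_cleave_pos",
  "hmm_matches", "tmhmm_helices", "tmhmm_n_side", "memsat3_helices",
  "memsat3_n_side", "bomp_score", "tmbhunt_prob", "is_tmbetadisc_rbf",
  "is_tatfind", "is_tat_hmm")

#' Construct a transmembrane topology model
#'
#' Ordered membrane-spanning helices plus the membrane side on which
#' residue 1 lies. The side of every loop between and beyond the helices
#' follows from `n_side` by alternation.
#'
#' @param helices two-column matrix (or list of length-2 vectors) of
#'   1-based inclusive `(start, stop)` helix spans, sorted by start,
#'   pairwise non-overlapping.
#' @param n_side side of residue 1: `"inside"` or `"outside"`.
#' @param protein_length total residue count.
#' @return list of class `topology_model`.
#' @export
topology_model <- function(helices, n_side, protein_length) {
  h <- .as_span_matrix(helices)
  n_side <- match.arg(n_side, c("inside", "outside"))
  if (!is.numeric(protein_length) || protein_length < 1)
    stop("protein_length must be a positive integer")
  protein_length <- as.integer(protein_length)
  if (nrow(h) > 0L) {
    if (any(h[, 1L] > h[, 2L])) stop("helix span with start > stop")
    if (any(h[, 1L] < 1L) || any(h[, 2L] > protein_length))
      stop("helix span outside [1, protein_length]")
    if (is.unsorted(h[, 1L], strictly = TRUE))
      stop("helix spans must be sorted by start")
    if (nrow(h) > 1L && any(h[-1L, 1L] <= h[-nrow(h), 2L]))
      stop("helix spans overlap")
  }
  structure(list(helices = h, n_side = n_side,
                 protein_length = protein_length),
            class = "topology_model")
}

#' @export
print.topology_model <- function(x, ...) {
  spans <- if (nrow(x$helices)) {
    paste(sprintf("%d-%d", x$helices[, 1L], x$helices[, 2L]), collapse = ", ")
  } else "none"
  cat(sprintf("<topology: %d helices [%s], N-terminus %s, length %d>\n",
              nrow(x$helices), spans, x$n_side, x$protein_length))
  invisible(x)
}

.as_span_matrix <- function(helices) {
  if (is.null(helices) || (is.matrix(helices) && nrow(helices) == 0L) ||
      (!is.matrix(helices) && length(helices) == 0L)) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "stop"))))
  }
  if (is.list(helices)) helices <- do.call(rbind, lapply(helices, as.integer))
  if (is.numeric(helices) && is.null(dim(helices)) && length(helices) == 2L)
    helices <- matrix(helices, ncol = 2L, byrow = TRUE)
  h <- matrix(as.integer(helices), ncol = 2L)
  colnames(h) <- c("start", "stop")
  h
}

.other_side <- function(side) if (side == "inside") "outside" else "inside"

#' Default protocol configuration
#'
#' Returns the fully-populated default configuration for one of the two
#' protocols. Loop-exposure thresholds follow the protocol defaults:
#' Gram-positive terminal/internal minima of 50/100 residues (calibrated
#' against cell-surface protease shaving through the peptidoglycan layer),
#' Gram-negative 30/30 (a conservative periplasmic/cytoplasmic domain
#' threshold). Barrel consensus bands: a BOMP category >= 3 or a TMB-HUNT
#' probability >= 0.95 is accepted alone; lower bands (BOMP >= 1,
#' TMB-HUNT >= 0.5, or a TMBETADISC-RBF positive) additionally require a
#' predicted signal sequence.
#'
#' @param protocol `"gram_pos"` or `"gram_neg"`.
#' @return list of class `protocol_config`.
#' @examples
#' default_config("gram_pos")$terminal_exposed_loop_min  # 50
#' default_config("gram_neg")$internal_exposed_loop_min  # 30
#' @export
default_config <- function(protocol) {
  if (!is.character(protocol) || length(protocol) != 1L ||
      !protocol %in% c("gram_pos", "gram_neg"))
    stop("unknown protocol '", paste(protocol, collapse = ","),
         "'; valid protocols: gram_pos, gram_neg")
  cfg <- list(
    protocol = protocol,
    terminal_exposed_loop_min = if (protocol == "gram_pos") 50L else 30L,
    internal_exposed_loop_min = if (protocol == "gram_pos") 100L else 30L,
    hmm_evalue_max = 0.1,
    hmm_score_min = 10,
    bomp_clearly_min = 3L,
    bomp_maybe_min = 1L,
    tmbhunt_clearly_min = 0.95,
    tmbhunt_maybe_min = 0.5,
    enabled_plugins = if (protocol == "gram_pos") {
      c("signalp", "lipop", "hmmsearch", "tmhmm")
    } else {
      c("signalp", "lipop", "tatfind", "tat_hmm", "tmhmm",
        "bomp", "tmbhunt", "tmbetadisc_rbf")
    },
    profiles_dir = system.file("extdata", "gram_pos_profiles",
                               package = "bacsurf"),
    results_dir = "results")
  structure(cfg, class = "protocol_config")
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf("<%s protocol config>\n", x$protocol))
  for (k in setdiff(names(x), "protocol"))
    cat(sprintf("  %s = %s\n", k, paste(x[[k]], collapse = ",")))
  invisible(x)
}

# per-key schema used by the key=value (de)serializer
.config_schema <- list(
  protocol = "character",
  terminal_exposed_loop_min = "integer",
  internal_exposed_loop_min = "integer",
  hmm_evalue_max = "numeric",
  hmm_score_min = "numeric",
  bomp_clearly_min = "integer",
  bomp_maybe_min = "integer",
  tmbhunt_clearly_min = "numeric",
  tmbhunt_maybe_min = "numeric",
  enabled_plugins = "character_list",
  profiles_dir = "character",
  results_dir = "character")

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "protocol_config"))
  num_keys <- c("terminal_exposed_loop_min", "internal_exposed_loop_min",
                "hmm_evalue_max", "hmm_score_min", "bomp_clearly_min",
                "bomp_maybe_min", "tmbhunt_clearly_min", "tmbhunt_maybe_min")
  for (k in num_keys)
    if (cfg[[k]] < 0) stop("config threshold ", k, " must be non-negative")
  if (cfg$bomp_maybe_min > cfg$bomp_clearly_min)
    stop("bomp_maybe_min must be <= bomp_clearly_min")
  if (cfg$tmbhunt_maybe_min > cfg$tmbhunt_clearly_min)
    stop("tmbhunt_maybe_min must be <= tmbhunt_clearly_min")
  invisible(cfg)
}

#' Write a protocol configuration to a flat key=value file
#'
#' One `key=value` pair per line; `#` starts a comment; list values are
#' comma-separated. [read_config()] reads the format back losslessly.
#'
#' @param cfg a `protocol_config`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  lines <- c("# protocol configuration",
             vapply(names(.config_schema), function(k) {
               sprintf("%s=%s", k, paste(cfg[[k]], collapse = ","))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protocol configuration file
#'
#' Parses the flat `key=value` format written by [write_config()]. Keys not
#' present in the file keep their protocol default; unknown keys are an
#' error naming the key.
#'
#' @param path configuration file path.
#' @return a validated `protocol_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)[[:space:]]*=(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad)) stop("unparseable config line: '", bad[[1L]], "'")
  keys <- vapply(kv, `[[`, character(1), 2L)
  vals <- trimws(vapply(kv, `[[`, character(1), 3L))
  unknown <- setdiff(keys, names(.config_schema))
  if (length(unknown))
    stop("unknown configuration key: '", unknown[[1L]], "'")
  if (anyDuplicated(keys))
    stop("duplicate configuration key: '", keys[duplicated(keys)][[1L]], "'")
  proto <- if ("protocol" %in% keys) vals[keys == "protocol"] else "gram_pos"
  cfg <- default_config(proto)
  for (i in seq_along(keys)) {
    k <- keys[[i]]
    cfg[[k]] <- switch(.config_schema[[k]],
      character = vals[[i]],
      character_list = if (nzchar(vals[[i]])) {
        trimws(strsplit(vals[[i]], ",", fixed = TRUE)[[1L]])
      } else character(0),
      integer = as.integer(vals[[i]]),
      numeric = as.numeric(vals[[i]]))
  }
  validate_config(cfg)
}

#' Check an annotation set against a protein record
#'
#' Violations are returned as data, not raised: each element of the result
#' names the offending key and the constraint broken. An empty character
#' vector means every invariant holds — helix spans sorted, non-overlapping
#' and within the sequence; cleavage positions inside `[1, length - 1]`;
#' scores within their ranges.
#'
#' @param protein a `protein_record`.
#' @param ann named list of annotation entries for that protein.
#' @return character vector of violation descriptions (empty if valid).
#' @export
validate_annotations <- function(protein, ann) {
  v <- character(0)
  L <- protein$length
  for (hk in c("tmhmm_helices", "memsat3_helices")) {
    if (is.null(ann[[hk]])) next
    h <- .as_span_matrix(ann[[hk]])
    if (nrow(h) == 0L) next
    if (any(h[, 1L] > h[, 2L]))
      v <- c(v, sprintf("%s: span with start > stop", hk))
    if (any(h[, 1L] < 1L) || any(h[, 2L] > L))
      v <- c(v, sprintf("%s: span outside [1, %d]", hk, L))
    if (is.unsorted(h[, 1L], strictly = TRUE))
      v <- c(v, sprintf("%s: spans not sorted by start", hk))
    if (nrow(h) > 1L && any(h[-1L, 1L] <= h[-nrow(h), 2L]))
      v <- c(v, sprintf("%s: overlapping spans", hk))
  }
  for (ck in c("signalp_cleave_pos", "lipop_cleave_pos")) {
    p <- ann[[ck]]
    if (!is.null(p) && (p < 1L || p > L - 1L))
      v <- c(v, sprintf("%s: position %d outside [1, %d]", ck, p, L - 1L))
  }
  if (!is.null(ann$bomp_score) &&
      (ann$bomp_score < 0L || ann$bomp_score > 5L))
    v <- c(v, "bomp_score: outside 0..5")
  if (!is.null(ann$tmbhunt_prob) &&
      (ann$tmbhunt_prob < 0 || ann$tmbhunt_prob > 1))
    v <- c(v, "tmbhunt_prob: outside [0, 1]")
  for (sk in c("tmhmm_n_side", "memsat3_n_side")) {
    s <- ann[[sk]]
    if (!is.null(s) && !s %in% c("inside", "outside"))
      v <- c(v, sprintf("%s: invalid side '%s'", sk, s))
  }
  v
}

#' Category vocabularies of the two protocols
#'
#' @param protocol `"gram_pos"` or `"gram_neg"`.
#' @return character vector of the closed category vocabulary.
#' @export
protocol_categories <- function(protocol) {
  switch(match.arg(protocol, c("gram_pos", "gram_neg")),
    gram_pos = c("PSE-Membrane", "PSE-Cellwall", "PSE-Lipoprotein",
                 "MEMBRANE(non-PSE)", "SECRETED", "CYTOPLASM(non-PSE)"),
    gram_neg = c("OM(barrel)", "LIPOPROTEIN(OM)", "LIPOPROTEIN(IM)",
                 "IM", "IM(cyto)", "IM(peri)", "IM(cyto+peri)",
                 "PERIPLASMIC/SECRETED", "CYTOPLASMIC"))
}

#' Construct a localization call
#'
#' @param seq_id protein identifier.
#' @param category one of the protocol's closed vocabulary.
#' @param details ordered character vector of evidence strings,
#'   e.g. `"tmhmm(2)"`, `"signalp"`, `"hmm(LPxTG)"`.
#' @param protocol protocol whose vocabulary `category` must belong to.
#' @return list of class `localization_call`.
#' @export
localization_call <- function(seq_id, category, details = character(0),
                              protocol = c("gram_pos", "gram_neg")) {
  protocol <- match.arg(protocol)
  if (!category %in% protocol_categories(protocol))
    stop("category '", category, "' not in ", protocol, " vocabulary")
  structure(list(seq_id = seq_id, category = category,
                 details = as.character(details)),
            class = "localization_call")
}

#' @export
print.localization_call <- function(x, ...) {
  cat(sprintf("%s  %s  [%s]\n", x$seq_id, x$category,
              paste(x$details, collapse = ";")))
  invisible(x)
}
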