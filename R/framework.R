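#' @title Plugin orchestration
#' @description
#' The pipeline runs a fixed, per-protocol sequence of predictor plugins.
#' Each plugin owns one raw output file (`<plugin>.out`, or `.html` for
#' web-service result pages) in the results directory; a cached file is
#' reused as-is, a fixture directory can supply it, and a missing file
#' with no way to produce it is an error naming the plugin and the
#' expected filename. Re-running classification from saved predictor
#' output is therefore always possible, even when a predictor binary or
#' web service has disappeared.
#' @name framework
NULL

.plugin_registry <- function(cfg) {
  list(
    signalp = list(file = "signalp.out", parse = parse_signalp),
    lipop = list(file = "lipop.out", parse = parse_lipop),
    hmmsearch = list(file = "hmmsearch.out", parse = function(text)
      parse_hmmsearch(text, cfg$hmm_evalue_max, cfg$hmm_score_min)),
    tmhmm = list(file = "tmhmm.out", parse = parse_tmhmm),
    memsat3 = list(file = "memsat3.out", parse = function(text) {
      blocks <- split_memsat3_blocks(text)
      out <- list()
      for (b in blocks) out <- utils::modifyList(out, parse_memsat3(b))
      out
    }),
    tatfind = list(file = "tatfind.out", parse = parse_tatfind),
    tat_hmm = list(file = "tat_hmm.out", parse = function(text) {
      hits <- parse_hmmsearch(text, cfg$hmm_evalue_max, cfg$hmm_score_min)
      lapply(hits, function(x) list(is_tat_hmm = length(x$hmm_matches) > 0L))
    }),
    bomp = list(file = "bomp.html", parse = parse_bomp_html),
    tmbhunt = list(file = "tmbhunt.html", parse = parse_tmbhunt_html),
    tmbetadisc_rbf = list(file = "tmbetadisc_rbf.html",
                          parse = parse_tmbetadisc_html))
}

# fixed per-protocol plugin execution order (optional plugins included
# here run only when enabled in the config)
.protocol_plugins <- function(protocol) {
  switch(protocol,
    gram_pos = c("signalp", "lipop", "hmmsearch", "tmhmm", "memsat3"),
    gram_neg = c("signalp", "lipop", "tatfind", "tat_hmm", "tmhmm",
                 "memsat3", "bomp", "tmbhunt", "tmbetadisc_rbf"),
    stop("unknown protocol '", protocol, "'"))
}

# locate (or install from the fixture dir) the raw output of one plugin
.plugin_raw_file <- function(plugin, fname, results_dir, fixture_dir) {
  cached <- file.path(results_dir, fname)
  if (file.exists(cached)) return(cached)
  if (!is.null(fixture_dir)) {
    fix <- file.path(fixture_dir, fname)
    if (file.exists(fix)) {
      file.copy(fix, cached)
      return(cached)
    }
  }
  stop("plugin '", plugin, "' has no cached output and cannot be run; ",
       "expected cache file: ", cached)
}

#' Run a protocol end-to-end over a proteome
#'
#' Reads the FASTA file, then for each enabled plugin in protocol order
#' reuses its cached raw output in `results_dir` when present (copying it
#' from `fixture_dir` when supplied), parses it and merges the resulting
#' annotations into the per-protein evidence map. Finally every protein
#' is classified with the protocol's decision tree; a CSV report and a
#' plain-text category summary are written into `results_dir`.
#'
#' @param fasta_path proteome FASTA file.
#' @param cfg a `protocol_config`; `cfg$results_dir` holds the cache and
#'   the reports.
#' @param fixture_dir optional directory of stored raw predictor outputs,
#'   used to seed the cache (fixture mode).
#' @param out_csv CSV report path; default `<results_dir>/output.csv`.
#' @return named list of [localization_call()]s in input order, with the
#'   summary lines as attribute `"summary"` and the merged annotations as
#'   attribute `"annotations"`.
#' @export
run_protocol <- function(fasta_path, cfg, fixture_dir = NULL,
                         out_csv = NULL) {
  validate_config(cfg)
  proteins <- read_fasta(fasta_path)
  if (length(proteins) == 0L) stop("no sequences in ", fasta_path)
  if (!dir.exists(cfg$results_dir))
    dir.create(cfg$results_dir, recursive = TRUE)
  registry <- .plugin_registry(cfg)
  ann <- stats::setNames(rep(list(list()), length(proteins)),
                         names(proteins))
  plugins <- intersect(.protocol_plugins(cfg$protocol),
                       cfg$enabled_plugins)
  for (pg in plugins) {
    entry <- registry[[pg]]
    raw <- .plugin_raw_file(pg, entry$file, cfg$results_dir, fixture_dir)
    parsed <- tryCatch(entry$parse(readLines(raw, warn = FALSE)),
                       error = function(e)
                         stop("plugin '", pg, "' failed on ", raw, ": ",
                              conditionMessage(e), call. = FALSE))
    for (id in names(parsed)) {
      if (!id %in% names(ann)) {
        warning("plugin '", pg, "' reports unknown sequence '", id, "'")
        next
      }
      ann[[id]] <- utils::modifyList(ann[[id]], parsed[[id]])
    }
  }
  classify <- if (cfg$protocol == "gram_pos") classify_gram_pos
              else classify_gram_neg
  calls <- lapply(proteins, function(p) classify(p, ann[[p$seq_id]], cfg))
  if (is.null(out_csv)) out_csv <- file.path(cfg$results_dir, "output.csv")
  write_calls_csv(calls, proteins, out_csv)
  summary_lines <- format_summary(calls, cfg$protocol)
  writeLines(summary_lines, file.path(cfg$results_dir, "summary.txt"))
  structure(calls, summary = summary_lines, annotations = ann)
}
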