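#' @title Gram-positive classification protocol
#' @description
#' The Gram-positive decision tree assigns each protein one of six
#' categories: PSE-Cellwall (cell-wall anchoring motif), PSE-Membrane /
#' MEMBRANE(non-PSE) (transmembrane protein with / without a sufficiently
#' long extracytoplasmic loop), PSE-Lipoprotein, SECRETED, or
#' CYTOPLASM(non-PSE). Rule precedence is motif > membrane > lipoprotein >
#' secreted > cytoplasm.
#' @name protocol_gram_pos
NULL

# cleavage evidence used to chop the N-terminus before loop analysis;
# when both a Sec signal and a lipoprotein signal are predicted the larger
# cleavage position wins (both describe an absent N-terminal region).
.cleave_pos <- function(ann) {
  pos <- 0L
  if (isTRUE(ann$is_signalp) && !is.null(ann$signalp_cleave_pos))
    pos <- max(pos, ann$signalp_cleave_pos)
  if (isTRUE(ann$is_lipop) && !is.null(ann$lipop_cleave_pos))
    pos <- max(pos, ann$lipop_cleave_pos)
  as.integer(pos)
}

#' Topology models for one protein
#'
#' One model per enabled topology predictor (TMHMM, and MEMSAT3 when
#' enabled) that reports at least one helix, each after removing the
#' cleaved signal region with [chop_nterminal()]. A model whose helices
#' all fall inside the cleaved region is dropped. An empty list means
#' "no transmembrane segment".
#'
#' @param protein a [protein_record()].
#' @param ann merged annotation list for that protein.
#' @param cfg a `protocol_config`.
#' @return list of [topology_model()]s (possibly empty).
#' @export
get_topologies <- function(protein, ann, cfg) {
  cp <- .cleave_pos(ann)
  models <- list()
  preds <- list(
    tmhmm = c("tmhmm_helices", "tmhmm_n_side"),
    memsat3 = c("memsat3_helices", "memsat3_n_side"))
  for (nm in names(preds)) {
    if (!nm %in% cfg$enabled_plugins) next
    keys <- preds[[nm]]
    helices <- ann[[keys[[1L]]]]
    if (is.null(helices)) next
    helices <- .as_span_matrix(helices)
    if (nrow(helices) == 0L) next
    topo <- topology_model(helices, ann[[keys[[2L]]]], protein$length)
    if (cp > 0L && cp < topo$protein_length)
      topo <- chop_nterminal(topo, cp)
    if (nrow(topo$helices) > 0L) models[[nm]] <- topo
  }
  models
}

#' Names of the surface-motif profiles
#'
#' The Gram-positive protocol scans a directory of profile HMMs for
#' cell-wall attachment and surface-association motifs (LPxTG, GW
#' repeats, peptidoglycan-binding, choline-binding, LysM, cell-wall
#' binding type 2, S-layer homology, NLPC_P60). The directory's
#' `manifest.txt` maps each profile to the display name used in evidence
#' details; dropping a new profile into the directory adds it to the scan.
#'
#' @param cfg a `protocol_config` (uses `cfg$profiles_dir`).
#' @return character vector of profile display names.
#' @export
surface_motif_names <- function(cfg) {
  manifest <- file.path(cfg$profiles_dir, "manifest.txt")
  if (!file.exists(manifest)) return(character(0))
  lines <- readLines(manifest, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "[[:space:]]+"), `[[`, character(1), 1L)
}

# evidence strings in a fixed canonical order, independent of which rule
# fired; disabled-but-known plugins are recorded as not run.
.evidence_details <- function(ann, cfg, motif_names = character(0)) {
  d <- character(0)
  if (isTRUE(ann$is_signalp)) d <- c(d, "signalp")
  if (isTRUE(ann$is_lipop)) d <- c(d, "lipop")
  if (isTRUE(ann$is_tatfind)) d <- c(d, "tatfind")
  if (isTRUE(ann$is_tat_hmm)) d <- c(d, "tat_hmm")
  if (length(ann$hmm_matches)) {
    profs <- sort(unique(vapply(ann$hmm_matches, `[[`, character(1),
                                "profile")))
    d <- c(d, sprintf("hmm(%s)", profs))
  }
  th <- .as_span_matrix(ann$tmhmm_helices)
  if (nrow(th) > 0L) d <- c(d, sprintf("tmhmm(%d)", nrow(th)))
  mh <- .as_span_matrix(ann$memsat3_helices)
  if (nrow(mh) > 0L) d <- c(d, sprintf("memsat3(%d)", nrow(mh)))
  if (!is.null(ann$bomp_score) && ann$bomp_score > 0L)
    d <- c(d, sprintf("bomp(%d)", ann$bomp_score))
  if (!is.null(ann$tmbhunt_prob))
    d <- c(d, sprintf("tmbhunt(%s)", format(ann$tmbhunt_prob)))
  if (isTRUE(ann$is_tmbetadisc_rbf)) d <- c(d, "tmbetadisc")
  known <- .protocol_plugins(cfg$protocol)
  for (p in setdiff(known, cfg$enabled_plugins))
    d <- c(d, sprintf("%s(not-run)", p))
  d
}

#' Classify one protein under the Gram-positive protocol
#'
#' First matching rule wins: (1) an accepted profile-HMM match against a
#' surface motif gives PSE-Cellwall; (2) a transmembrane protein is
#' PSE-Membrane when any topology model has a long enough
#' extracytoplasmic loop, else MEMBRANE(non-PSE); (3) a lipoprotein
#' signal gives PSE-Lipoprotein; (4) a Sec signal gives SECRETED;
#' (5) otherwise CYTOPLASM(non-PSE). The details list records every
#' positive evidence key regardless of which rule fired.
#'
#' @param protein a [protein_record()].
#' @param ann merged annotation list for that protein.
#' @param cfg a `protocol_config` (gram_pos).
#' @return a [localization_call()].
#' @export
classify_gram_pos <- function(protein, ann, cfg) {
  motifs <- surface_motif_names(cfg)
  details <- .evidence_details(ann, cfg, motifs)
  hit_motif <- length(ann$hmm_matches) > 0L && {
    profs <- vapply(ann$hmm_matches, `[[`, character(1), "profile")
    if (length(motifs)) any(profs %in% motifs) else TRUE
  }
  models <- get_topologies(protein, ann, cfg)
  category <-
    if (hit_motif) {
      "PSE-Cellwall"
    } else if (length(models) > 0L) {
      exposed <- any(vapply(models, function(m)
        has_surface_exposed_loop(loops_from_topology(m), cfg), logical(1)))
      if (exposed) "PSE-Membrane" else "MEMBRANE(non-PSE)"
    } else if (isTRUE(ann$is_lipop)) {
      "PSE-Lipoprotein"
    } else if (isTRUE(ann$is_signalp)) {
      "SECRETED"
    } else {
      "CYTOPLASM(non-PSE)"
    }
  localization_call(protein$seq_id, category, details, "gram_pos")
}
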