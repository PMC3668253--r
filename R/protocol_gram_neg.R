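#' @title Gram-negative classification protocol
#' @description
#' The Gram-negative decision tree distinguishes outer-membrane
#' beta-barrels (consensus over BOMP, TMB-HUNT and TMBETADISC-RBF),
#' inner- and outer-membrane lipoproteins (Asp+2 sorting rule),
#' inner-membrane helical proteins tagged with long cytoplasmic and/or
#' periplasmic loops, periplasmic/secreted proteins (Sec or Tat signal)
#' and cytoplasmic proteins. Precedence is barrel > lipoprotein > inner
#' membrane > signal > cytoplasm: barrel evidence dominates because
#' topology predictors frequently mistake a barrel's signal anchor for a
#' transmembrane helix.
#' @name protocol_gram_neg
NULL

#' Beta-barrel consensus call
#'
#' High-scoring sequences are accepted outright: BOMP category at least
#' `bomp_clearly_min` (default 3) or TMB-HUNT probability at least
#' `tmbhunt_clearly_min` (default 0.95). Lower-scoring bands — BOMP in
#' `[bomp_maybe_min, bomp_clearly_min)`, TMB-HUNT in
#' `[tmbhunt_maybe_min, tmbhunt_clearly_min)`, or any TMBETADISC-RBF
#' positive — additionally require a predicted signal sequence. The bands
#' are OR-combined across predictors so each web service remains usable
#' on its own.
#'
#' @param ann merged annotation list for one protein.
#' @param cfg a `protocol_config` (gram_neg).
#' @param has_signal does the protein carry a predicted Sec or Tat signal?
#' @return logical scalar.
#' @export
is_barrel <- function(ann, cfg, has_signal) {
  bomp <- if (is.null(ann$bomp_score)) 0L else ann$bomp_score
  prob <- if (is.null(ann$tmbhunt_prob)) 0 else ann$tmbhunt_prob
  if (bomp >= cfg$bomp_clearly_min) return(TRUE)
  if (prob >= cfg$tmbhunt_clearly_min) return(TRUE)
  maybe <- (bomp >= cfg$bomp_maybe_min && bomp < cfg$bomp_clearly_min) ||
    (prob >= cfg$tmbhunt_maybe_min && prob < cfg$tmbhunt_clearly_min) ||
    isTRUE(ann$is_tmbetadisc_rbf)
  isTRUE(has_signal) && maybe
}

#' Asp+2 lipoprotein sorting
#'
#' The mature lipoprotein starts at the lipidated cysteine
#' (`lipop_cleave_pos + 1`). An aspartate at mature position 2 — the
#' outer-membrane avoidance signal — retains the lipoprotein at the
#' inner membrane; anything else is trafficked to the outer membrane.
#'
#' @param sequence full precursor amino-acid sequence.
#' @param lipop_cleave_pos last residue of the lipoprotein signal.
#' @return `"IM"` or `"OM"`.
#' @export
lipoprotein_destination <- function(sequence, lipop_cleave_pos) {
  pos2 <- lipop_cleave_pos + 2L
  if (pos2 > nchar(sequence))
    stop("mature lipoprotein shorter than 2 residues")
  if (substring(sequence, pos2, pos2) == "D") "IM" else "OM"
}

#' Classify one protein under the Gram-negative protocol
#'
#' First matching rule wins: (1) a beta-barrel consensus ([is_barrel()])
#' gives OM(barrel); (2) a lipoprotein signal gives LIPOPROTEIN(IM) or
#' LIPOPROTEIN(OM) by the Asp+2 rule; (3) a transmembrane protein is IM,
#' suffixed with the membrane sides carrying loops of at least
#' `internal_exposed_loop_min` residues — `IM(cyto)`, `IM(peri)` or
#' `IM(cyto+peri)`; (4) a Sec or Tat signal gives PERIPLASMIC/SECRETED;
#' (5) otherwise CYTOPLASMIC.
#'
#' @param protein a [protein_record()].
#' @param ann merged annotation list for that protein.
#' @param cfg a `protocol_config` (gram_neg).
#' @return a [localization_call()].
#' @export
classify_gram_neg <- function(protein, ann, cfg) {
  details <- .evidence_details(ann, cfg)
  has_signal <- isTRUE(ann$is_signalp) || isTRUE(ann$is_tatfind) ||
    isTRUE(ann$is_tat_hmm)
  models <- get_topologies(protein, ann, cfg)
  category <-
    if (is_barrel(ann, cfg, has_signal)) {
      "OM(barrel)"
    } else if (isTRUE(ann$is_lipop)) {
      dest <- lipoprotein_destination(protein$sequence,
                                      ann$lipop_cleave_pos)
      sprintf("LIPOPROTEIN(%s)", dest)
    } else if (length(models) > 0L) {
      sides <- unique(unlist(lapply(models, function(m)
        exposed_sides(loops_from_topology(m), cfg))))
      cyto <- "inside" %in% sides
      peri <- "outside" %in% sides
      if (cyto && peri) "IM(cyto+peri)"
      else if (cyto) "IM(cyto)"
      else if (peri) "IM(peri)"
      else "IM"
    } else if (has_signal) {
      "PERIPLASMIC/SECRETED"
    } else {
      "CYTOPLASMIC"
    }
  localization_call(protein$seq_id, category, details, "gram_neg")
}
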