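#' @title Loop derivation and surface-exposure rules
#' @description
#' The exposure algorithm: given the ordered transmembrane helices and the
#' side of the N-terminus, every inter-helix segment and both tails are
#' loops whose side alternates across the membrane. A protein is
#' potentially surface exposed when an extracytoplasmic loop is long
#' enough to protrude through the cell-wall layer — by default 50 residues
#' for terminal tails and 100 for internal loops under the Gram-positive
#' protocol, and 30 for both under the Gram-negative protocol.
#' @name topology
NULL

#' Derive loops from a topology model
#'
#' A model with H helices yields exactly H+1 loops: the N-terminal tail
#' `[1, start_1 - 1]`, the H-1 internal loops `[stop_k + 1, start_{k+1} - 1]`
#' and the C-terminal tail `[stop_H + 1, L]`. Zero-length loops are kept
#' (with an empty span) so sides keep alternating strictly from `n_side`.
#'
#' @param topo a [topology_model()] with at least one helix.
#' @return list of loops; each loop has `kind` (`n_tail`/`internal`/
#'   `c_tail`), `side`, `span` (`c(start, stop)` or `NULL` when empty) and
#'   `loop_len`.
#' @export
loops_from_topology <- function(topo) {
  stopifnot(inherits(topo, "topology_model"))
  h <- unname(topo$helices)
  H <- nrow(h)
  if (H == 0L)
    stop("topology model has no helices; branch on TM presence first")
  L <- topo$protein_length
  bounds <- rbind(
    c(1L, h[1L, 1L] - 1L),
    if (H > 1L) cbind(h[-H, 2L] + 1L, h[-1L, 1L] - 1L),
    c(h[H, 2L] + 1L, L))
  kinds <- c("n_tail", rep("internal", max(H - 1L, 0L)), "c_tail")
  side <- topo$n_side
  loops <- vector("list", H + 1L)
  for (i in seq_len(H + 1L)) {
    len <- max(bounds[i, 2L] - bounds[i, 1L] + 1L, 0L)
    loops[[i]] <- list(
      kind = kinds[[i]], side = side,
      span = if (len > 0L) c(bounds[i, 1L], bounds[i, 2L]) else NULL,
      loop_len = as.integer(len))
    side <- .other_side(side)
  }
  loops
}

#' Remove a cleaved N-terminal region from a topology model
#'
#' Residues `1..cleave_pos` are removed and the model renumbered, so that
#' a cleaved Sec or lipoprotein signal never counts as an exposed
#' N-terminal tail. Helices entirely within the removed region are dropped
#' (flipping `n_side` each time, so every surviving loop keeps its side);
#' a helix straddling the cut is truncated to start at residue 1.
#' `cleave_pos = 0` is the identity.
#'
#' @param topo a [topology_model()].
#' @param cleave_pos last removed residue, `0 <= cleave_pos < protein_length`.
#' @return a renumbered `topology_model` of length
#'   `protein_length - cleave_pos`; possibly with zero helices, in which
#'   case the caller should fall back to its no-TM branch.
#' @export
chop_nterminal <- function(topo, cleave_pos) {
  stopifnot(inherits(topo, "topology_model"))
  cleave_pos <- as.integer(cleave_pos)
  if (cleave_pos < 0L) stop("cleave_pos must be >= 0")
  if (cleave_pos >= topo$protein_length)
    stop("cleave_pos ", cleave_pos, " >= protein length ",
         topo$protein_length)
  if (cleave_pos == 0L) return(topo)
  h <- topo$helices
  n_side <- topo$n_side
  keep <- matrix(integer(0), ncol = 2L)
  for (i in seq_len(nrow(h))) {
    if (h[i, 2L] <= cleave_pos) {
      n_side <- .other_side(n_side)    # dropped helix flips the N side
    } else if (h[i, 1L] <= cleave_pos) {
      keep <- rbind(keep, c(1L, h[i, 2L] - cleave_pos))
    } else {
      keep <- rbind(keep, h[i, , drop = TRUE] - cleave_pos)
    }
  }
  topology_model(keep, n_side, topo$protein_length - cleave_pos)
}

.loop_threshold <- function(loop, cfg) {
  if (loop$kind == "internal") cfg$internal_exposed_loop_min
  else cfg$terminal_exposed_loop_min
}

#' Is any extracytoplasmic loop long enough to be surface exposed?
#'
#' True iff some loop on the outside satisfies its minimum length:
#' `terminal_exposed_loop_min` for tails, `internal_exposed_loop_min` for
#' internal loops. Comparisons are `>=`.
#'
#' @param loops output of [loops_from_topology()].
#' @param cfg a `protocol_config`.
#' @return logical scalar.
#' @export
has_surface_exposed_loop <- function(loops, cfg) {
  "outside" %in% exposed_sides(loops, cfg)
}

#' Membrane sides carrying a sufficiently long loop
#'
#' Used by the Gram-negative protocol to tag inner-membrane proteins with
#' long cytoplasmic (`inside`) and/or periplasmic (`outside`) domains.
#'
#' @inheritParams has_surface_exposed_loop
#' @return character vector, a subset of `c("inside", "outside")`.
#' @export
exposed_sides <- function(loops, cfg) {
  hit <- vapply(loops, function(lp) lp$loop_len >= .loop_threshold(lp, cfg),
                logical(1))
  sides <- unique(vapply(loops[hit], `[[`, character(1), "side"))
  intersect(c("inside", "outside"), sides)
}
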