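#' @title Synthetic proteome and fixture generation
#' @description
#' Generates a deterministic synthetic proteome together with the raw
#' output files of every predictor plugin, plus the ground truth the
#' fixtures encode. Sequence composition realizes the planted features —
#' hydrophobic 19-23-residue stretches at helix spans, a Sec signal
#' n/h/c-region layout, a lipobox ending in the lipidated cysteine with a
#' chosen mature position-2 residue — because the Asp+2 rule and the
#' N-terminal chop are the only places the classifiers read raw sequence.
#' The remaining background is uniform over the 20 amino acids.
#' @name synthetic_data
NULL

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.HYDRO <- c("A", "F", "I", "L", "M", "V")

.syn_archetypes <- c(
  "cytoplasmic", "secreted", "tat_secreted",
  "lipoprotein_im", "lipoprotein_om",
  "membrane_pse", "membrane_non_pse", "membrane_signal",
  "cellwall",
  "barrel_high", "barrel_low_signal", "barrel_rbf_signal",
  "barrel_low_nosignal")

.syn_codes <- c(
  cytoplasmic = "CYT", secreted = "SEC", tat_secreted = "TAT",
  lipoprotein_im = "LPI", lipoprotein_om = "LPO",
  membrane_pse = "TMP", membrane_non_pse = "TMN",
  membrane_signal = "TMS", cellwall = "CWM",
  barrel_high = "OBH", barrel_low_signal = "OBL",
  barrel_rbf_signal = "OBR", barrel_low_nosignal = "OBN")

.rand_residues <- function(n) sample(.AA20, n, replace = TRUE)

# Sec signal layout over residues 1..cs: Met, a charged n-region, a
# hydrophobic h-region, and an A-x-A c-region ending at the cleavage site.
.plant_signal <- function(chars, cs) {
  chars[1L] <- "M"
  chars[2:3] <- sample(c("K", "R"), 2L, replace = TRUE)
  chars[4:(cs - 3L)] <- sample(.HYDRO, cs - 6L, replace = TRUE)
  chars[(cs - 2L):cs] <- c("A", sample(.AA20, 1L), "A")
  chars
}

# loop lengths (H+1) + helix lengths (H) -> helix span matrix
.spans_from_loops <- function(loop_lens, helix_lens) {
  H <- length(helix_lens)
  starts <- integer(H)
  stops <- integer(H)
  pos <- 0L
  for (k in seq_len(H)) {
    pos <- pos + loop_lens[[k]]
    starts[[k]] <- pos + 1L
    pos <- pos + helix_lens[[k]]
    stops[[k]] <- pos
  }
  cbind(start = starts, stop = stops)
}

# loop descriptors (kind/side/len) implied by loop lengths and n_side
.loop_truth <- function(loop_lens, n_side) {
  H1 <- length(loop_lens)
  kinds <- c("n_tail", rep("internal", max(H1 - 2L, 0L)), "c_tail")
  side <- n_side
  out <- vector("list", H1)
  for (i in seq_len(H1)) {
    out[[i]] <- list(kind = kinds[[i]], side = side,
                     loop_len = as.integer(loop_lens[[i]]))
    side <- .other_side(side)
  }
  out
}

.syn_one <- function(archetype, id) {
  t <- list(archetype = archetype, seq_id = id,
            has_sec_signal = FALSE, signal_cleave = NULL,
            is_tat = FALSE, lipop_cleave = NULL, plus2 = NULL,
            helices = NULL, n_side = NULL, loops = NULL,
            hmm_profile = NULL, bomp = NULL, tmbhunt = NULL,
            rbf = FALSE)
  if (archetype %in% c("secreted", "tat_secreted", "membrane_signal",
                       "barrel_low_signal", "barrel_rbf_signal") &&
      archetype != "tat_secreted") {
    cs <- sample(18:28, 1L)
  } else cs <- NULL

  if (archetype %in% c("membrane_pse", "membrane_non_pse")) {
    H <- sample(1:3, 1L)
    helix_lens <- sample(19:23, H, replace = TRUE)
    loop_lens <- integer(H + 1L)
    n_side <- sample(c("inside", "outside"), 1L)
    sides <- rep(c(n_side, .other_side(n_side)), length.out = H + 1L)
    kinds <- c("n_tail", rep("internal", max(H - 1L, 0L)), "c_tail")
    for (i in seq_len(H + 1L)) {
      # cytoplasmic loops may exceed the Gram-negative tag threshold (30)
      # but never the Gram-positive exposure minima, which only look at
      # the extracytoplasmic side anyway
      loop_lens[[i]] <- if (sides[[i]] == "inside") {
        sample(2:60, 1L)
      } else if (kinds[[i]] == "internal") sample(2:95, 1L)
      else sample(2:45, 1L)
    }
    if (archetype == "membrane_pse") {
      # force one extracytoplasmic loop over the Gram-positive minimum
      out_idx <- which(sides == "outside")
      pick <- sample(out_idx, 1L)
      loop_lens[[pick]] <- if (kinds[[pick]] == "internal")
        sample(100:180, 1L) else sample(50:150, 1L)
    }
    spans <- .spans_from_loops(loop_lens, helix_lens)
    L <- sum(loop_lens) + sum(helix_lens)
    chars <- .rand_residues(L)
    for (k in seq_len(H))
      chars[spans[k, 1L]:spans[k, 2L]] <-
        sample(.HYDRO, helix_lens[[k]], replace = TRUE)
    t$helices <- spans
    t$n_side <- n_side
    t$loops <- .loop_truth(loop_lens, n_side)
  } else if (archetype == "membrane_signal") {
    gap <- sample(5:25, 1L)
    helix_len <- sample(19:23, 1L)
    c_tail <- sample(60:150, 1L)
    L <- cs + gap + helix_len + c_tail
    chars <- .rand_residues(L)
    chars <- .plant_signal(chars, cs)
    s1 <- cs + gap + 1L
    chars[s1:(s1 + helix_len - 1L)] <-
      sample(.HYDRO, helix_len, replace = TRUE)
    t$has_sec_signal <- TRUE
    t$signal_cleave <- cs
    t$helices <- cbind(start = s1, stop = s1 + helix_len - 1L)
    t$n_side <- "inside"
    # loops after removal of the cleaved signal region
    t$loops <- list(
      list(kind = "n_tail", side = "inside", loop_len = gap),
      list(kind = "c_tail", side = "outside", loop_len = c_tail))
  } else if (archetype %in% c("lipoprotein_im", "lipoprotein_om")) {
    cp <- sample(15:22, 1L)
    L <- cp + sample(80:200, 1L)
    chars <- .rand_residues(L)
    chars[1L] <- "M"
    chars[2:3] <- sample(c("K", "R"), 2L, replace = TRUE)
    chars[4:(cp - 3L)] <- sample(.HYDRO, cp - 6L, replace = TRUE)
    chars[(cp - 2L):cp] <- c("L", "A", "G")       # lipobox, Cys follows
    chars[cp + 1L] <- "C"
    t$plus2 <- if (archetype == "lipoprotein_im") "D"
               else sample(c("S", "A", "G", "N", "Q", "T"), 1L)
    chars[cp + 2L] <- t$plus2
    t$lipop_cleave <- cp
  } else {
    L <- sample(150:400, 1L)
    chars <- .rand_residues(L)
    if (!is.null(cs)) {
      chars <- .plant_signal(chars, cs)
      t$has_sec_signal <- TRUE
      t$signal_cleave <- cs
    }
    if (archetype == "tat_secreted") {
      chars[1:9] <- c("M", "S", "R", "R", "Q", "F", "L", "K", "A")
      t$is_tat <- TRUE
    }
    if (archetype == "cellwall")
      t$hmm_profile <- sample(c("LPxTG", "GW_repeat", "PG_binding_1",
                                "Choline_binding", "LysM", "CW_binding_2",
                                "SLH", "NLPC_P60"), 1L)
    if (archetype == "barrel_high") {
      t$bomp <- sample(3:5, 1L)
      t$tmbhunt <- round(stats::runif(1L, 0.95, 0.99), 2L)
    }
    if (archetype == "barrel_low_signal") {
      t$bomp <- sample(1:2, 1L)
      t$tmbhunt <- round(stats::runif(1L, 0.50, 0.94), 2L)
    }
    if (archetype == "barrel_rbf_signal") t$rbf <- TRUE
    if (archetype == "barrel_low_nosignal") t$bomp <- sample(1:2, 1L)
  }
  t$length <- length(chars)
  t$sequence <- paste(chars, collapse = "")
  t
}

# independent rule trace over planted features (never calls the
# classifiers or the loop arithmetic): the end-to-end oracle
.expected_category <- function(t, protocol, cfg) {
  loops_over <- function(side) {
    any(vapply(t$loops, function(lp) {
      thr <- if (lp$kind == "internal") cfg$internal_exposed_loop_min
             else cfg$terminal_exposed_loop_min
      lp$side == side && lp$loop_len >= thr
    }, logical(1)))
  }
  if (protocol == "gram_pos") {
    if (!is.null(t$hmm_profile)) return("PSE-Cellwall")
    if (!is.null(t$helices)) {
      return(if (loops_over("outside")) "PSE-Membrane"
             else "MEMBRANE(non-PSE)")
    }
    if (!is.null(t$lipop_cleave)) return("PSE-Lipoprotein")
    if (t$has_sec_signal) return("SECRETED")
    return("CYTOPLASM(non-PSE)")
  }
  has_signal <- t$has_sec_signal || t$is_tat
  bomp <- if (is.null(t$bomp)) 0L else t$bomp
  prob <- if (is.null(t$tmbhunt)) 0 else t$tmbhunt
  barrel <- bomp >= cfg$bomp_clearly_min ||
    prob >= cfg$tmbhunt_clearly_min ||
    (has_signal &&
       ((bomp >= cfg$bomp_maybe_min && bomp < cfg$bomp_clearly_min) ||
        (prob >= cfg$tmbhunt_maybe_min && prob < cfg$tmbhunt_clearly_min) ||
        t$rbf))
  if (barrel) return("OM(barrel)")
  if (!is.null(t$lipop_cleave))
    return(if (t$plus2 == "D") "LIPOPROTEIN(IM)" else "LIPOPROTEIN(OM)")
  if (!is.null(t$helices)) {
    cyto <- loops_over("inside")
    peri <- loops_over("outside")
    return(if (cyto && peri) "IM(cyto+peri)"
           else if (cyto) "IM(cyto)"
           else if (peri) "IM(peri)" else "IM")
  }
  if (has_signal) return("PERIPLASMIC/SECRETED")
  "CYTOPLASMIC"
}

.emit_signalp <- function(truths) {
  rows <- vapply(truths, function(t) {
    pos <- if (t$has_sec_signal) t$signal_cleave + 1L else 11L
    dec <- if (t$has_sec_signal) "Y" else "N"
    net <- if (t$has_sec_signal) "SignalP-noTM" else "SignalP-TM"
    sprintf("%-22s %5.3f %3d  %5.3f %3d  %5.3f %3d  %5.3f  %5.3f %s  %5.3f  %s",
            t$seq_id, 0.52, pos, if (t$has_sec_signal) 0.72 else 0.12, pos,
            0.81, max(pos - 8L, 1L), 0.61,
            if (t$has_sec_signal) 0.68 else 0.09, dec, 0.45, net)
  }, character(1))
  c("# SignalP-4.0   gram+ predictions",
    "# name                  Cmax  pos  Ymax  pos  Smax  pos  Smean   D     ?  Dmaxcut  Networks-used",
    rows)
}

.emit_lipop <- function(truths) {
  vapply(truths, function(t) {
    if (!is.null(t$lipop_cleave)) {
      sprintf("%s LipoP1.0:Best SpII 1 1 %.4f # cleavage=%d-%d Pos+2=%s",
              t$seq_id, 17.36, t$lipop_cleave, t$lipop_cleave + 1L, t$plus2)
    } else if (t$has_sec_signal) {
      sprintf("%s LipoP1.0:Best SpI 1 1 %.4f # cleavage=%d-%d",
              t$seq_id, 9.81, t$signal_cleave, t$signal_cleave + 1L)
    } else {
      sprintf("%s LipoP1.0:Best CYT 1 1 -0.2000", t$seq_id)
    }
  }, character(1))
}

.emit_tmhmm <- function(truths) {
  unlist(lapply(truths, function(t) {
    lines <- c(sprintf("# %s Length: %d", t$seq_id, t$length))
    if (is.null(t$helices)) {
      return(c(lines, sprintf("%s\tTMHMM2.0\tinside\t1\t%d",
                              t$seq_id, t$length)))
    }
    h <- t$helices
    side <- t$n_side
    pos <- 1L
    for (k in seq_len(nrow(h))) {
      if (h[k, 1L] > pos)
        lines <- c(lines, sprintf("%s\tTMHMM2.0\t%s\t%d\t%d",
                                  t$seq_id, side, pos, h[k, 1L] - 1L))
      lines <- c(lines, sprintf("%s\tTMHMM2.0\tTMhelix\t%d\t%d",
                                t$seq_id, h[k, 1L], h[k, 2L]))
      side <- .other_side(side)
      pos <- h[k, 2L] + 1L
    }
    if (pos <= t$length)
      lines <- c(lines, sprintf("%s\tTMHMM2.0\t%s\t%d\t%d",
                                t$seq_id, side, pos, t$length))
    lines
  }))
}

.emit_memsat3 <- function(truths) {
  unlist(lapply(truths, function(t) {
    lines <- c(sprintf("# SEQ %s", t$seq_id), "FINAL PREDICTION")
    if (!is.null(t$helices)) {
      h <- t$helices
      lines <- c(lines, sprintf("%d: (%d-%d)", seq_len(nrow(h)),
                                h[, 1L], h[, 2L]))
    }
    nt <- if (!is.null(t$n_side) && t$n_side == "outside") "out" else "in"
    c(lines, sprintf("N-terminal: %s", nt), "")
  }))
}

.emit_hmmsearch <- function(truths) {
  rows <- character(0)
  for (t in truths) {
    if (!is.null(t$hmm_profile)) {
      rows <- c(rows, sprintf(
        "%-22s -  %-16s PF00000  %.1e  %5.1f  0.1  %.1e  %5.1f  0.0",
        t$seq_id, t$hmm_profile, 1e-15, 62.4, 2e-15, 61.9))
    }
  }
  # a sub-threshold decoy hit: parsers must reject it
  decoy <- truths[[1L]]
  rows <- c(rows, sprintf(
    "%-22s -  %-16s PF00000  %.1e  %5.1f  0.0  %.1e  %5.1f  0.0",
    decoy$seq_id, "LPxTG", 0.5, 8.2, 0.6, 8.0))
  c("# --- full sequence ---  hmmsearch per-sequence hits",
    "# target name          acc  query name       acc      E-value  score  bias  dom-E  dom-score  dom-bias",
    rows)
}

.emit_tat_hmm <- function(truths) {
  rows <- character(0)
  for (t in truths) {
    if (t$is_tat)
      rows <- c(rows, sprintf(
        "%-22s -  %-16s PS51318  %.1e  %5.1f  0.0  %.1e  %5.1f  0.0",
        t$seq_id, "Tat_PS51318", 1e-12, 45.3, 2e-12, 44.8))
  }
  c("# hmmsearch per-sequence hits, twin-arginine signal profile",
    "# target name          acc  query name       acc      E-value  score  bias  dom-E  dom-score  dom-bias",
    rows)
}

.emit_tatfind <- function(truths) {
  c("TatFind 1.4 Results:",
    vapply(truths, function(t) {
      sprintf(">%s : %s%s", t$seq_id,
              if (t$is_tat) "TRUE" else "FALSE",
              if (t$is_tat) " - Tat signal predicted" else "")
    }, character(1)))
}

.html_page <- function(title, header_cells, rows) {
  c("<html><head><title>", title, "</title></head><body>",
    sprintf("<h1>%s</h1>", title),
    "<table border=\"1\">",
    paste0("<tr>", paste0("<th>", header_cells, "</th>", collapse = ""),
           "</tr>"),
    rows,
    "</table>", "</body></html>")
}

.emit_bomp <- function(truths) {
  rows <- character(0)
  n <- 0L
  for (t in truths) {
    if (!is.null(t$bomp)) {
      n <- n + 1L
      rows <- c(rows, sprintf(
        "<tr><td>%d</td><td>%s synthetic barrel candidate</td><td>%d</td></tr>",
        n, t$seq_id, t$bomp))
    }
  }
  .html_page("BOMP results", c("Number", "Sequence", "Category"), rows)
}

.emit_tmbhunt <- function(truths) {
  rows <- character(0)
  for (t in truths) {
    if (!is.null(t$tmbhunt))
      rows <- c(rows, sprintf(
        "<tr><td>%s</td><td>%.2f</td></tr>", t$seq_id, t$tmbhunt))
  }
  .html_page("TMB-HUNT results", c("Sequence", "Probability"), rows)
}

.emit_tmbetadisc <- function(truths) {
  rows <- vapply(truths, function(t) {
    verdict <- if (t$rbf) "Outer Membrane Protein"
               else "Non-Outer Membrane Protein"
    sprintf("<tr><td>%s</td><td>%s</td></tr>", t$seq_id, verdict)
  }, character(1))
  .html_page("TMBETADISC-RBF results", c("Sequence", "Prediction"), rows)
}

#' Default archetype mix of the synthetic proteome
#'
#' @return named integer vector of per-archetype counts.
#' @export
default_proteome_spec <- function() {
  c(cytoplasmic = 3L, secreted = 2L, tat_secreted = 1L,
    lipoprotein_im = 1L, lipoprotein_om = 1L,
    membrane_pse = 2L, membrane_non_pse = 2L, membrane_signal = 1L,
    cellwall = 1L,
    barrel_high = 1L, barrel_low_signal = 1L, barrel_rbf_signal = 1L,
    barrel_low_nosignal = 1L)
}

#' Generate a synthetic proteome with matching predictor fixtures
#'
#' Writes `proteome.fasta` plus one raw output file per plugin
#' (`signalp.out`, `lipop.out`, `tmhmm.out`, `memsat3.out`,
#' `hmmsearch.out`, `tatfind.out`, `tat_hmm.out`, `bomp.html`,
#' `tmbhunt.html`, `tmbetadisc_rbf.html`) into `dir`, such that parsing
#' the fixtures recovers the planted ground truth exactly and the
#' expected localization of every protein follows from the planted
#' features by the protocol rules. Deterministic for a given
#' `(spec, seed)` pair.
#'
#' @param spec named integer vector of archetype counts (see
#'   [default_proteome_spec()] for the archetype names).
#' @param seed integer random seed.
#' @param dir output directory (created if missing).
#' @return list with `dir`, `fasta` (path), `files` (named fixture
#'   paths), `proteins` (records) and `truth` — per-protein planted
#'   features including `expected$gram_pos` / `expected$gram_neg`.
#' @export
generate_synthetic_proteome <- function(spec = default_proteome_spec(),
                                        seed = 1L, dir = tempfile("synth")) {
  bad <- setdiff(names(spec), .syn_archetypes)
  if (length(bad)) stop("unknown archetype in spec: ", bad[[1L]])
  if (is.null(names(spec)) || any(!nzchar(names(spec))))
    stop("spec must be a named vector of archetype counts")
  if (sum(spec) < 1L) stop("spec requests no proteins")
  set.seed(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  archetypes <- rep(names(spec), times = spec)
  truths <- vector("list", length(archetypes))
  for (i in seq_along(archetypes)) {
    id <- sprintf("SYN%03d_%s", i, .syn_codes[[archetypes[[i]]]])
    truths[[i]] <- .syn_one(archetypes[[i]], id)
  }
  names(truths) <- vapply(truths, `[[`, character(1), "seq_id")
  cfg_gp <- default_config("gram_pos")
  cfg_gn <- default_config("gram_neg")
  for (id in names(truths)) {
    truths[[id]]$expected <- list(
      gram_pos = .expected_category(truths[[id]], "gram_pos", cfg_gp),
      gram_neg = .expected_category(truths[[id]], "gram_neg", cfg_gn))
  }
  proteins <- lapply(truths, function(t)
    protein_record(t$seq_id, t$sequence,
                   paste("synthetic", t$archetype, "protein")))
  fasta <- file.path(dir, "proteome.fasta")
  write_fasta(proteins, fasta)
  emitters <- list(
    signalp.out = .emit_signalp, lipop.out = .emit_lipop,
    tmhmm.out = .emit_tmhmm, memsat3.out = .emit_memsat3,
    hmmsearch.out = .emit_hmmsearch, tat_hmm.out = .emit_tat_hmm,
    tatfind.out = .emit_tatfind, bomp.html = .emit_bomp,
    tmbhunt.html = .emit_tmbhunt, tmbetadisc_rbf.html = .emit_tmbetadisc)
  files <- character(0)
  for (fname in names(emitters)) {
    path <- file.path(dir, fname)
    writeLines(emitters[[fname]](truths), path)
    files[[fname]] <- path
  }
  list(dir = dir, fasta = fasta, files = files,
       proteins = proteins, truth = truths)
}
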