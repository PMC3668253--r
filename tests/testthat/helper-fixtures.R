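# shared helpers: brute-force residue-labelling oracle, random topology
# generator, and small constructors used across the test files

# label every residue "H" (helix) or with its membrane side; the side of
# a non-helix residue is n_side flipped once per helix lying entirely
# before it (closed form, independent of the loop arithmetic under test)
label_residues <- function(helices, n_side, L) {
  other <- function(s) if (s == "inside") "outside" else "inside"
  in_helix <- rep(FALSE, L)
  n_before <- rep(0L, L)
  if (!is.null(helices) && nrow(helices) > 0L) {
    for (k in seq_len(nrow(helices)))
      in_helix[helices[k, 1L]:helices[k, 2L]] <- TRUE
    n_before <- rowSums(outer(seq_len(L), helices[, 2L], ">"))
  }
  labels <- ifelse(n_before %% 2L == 0L, n_side, other(n_side))
  labels[in_helix] <- "H"
  labels
}

# maximal non-helix runs of a label vector -> loops (non-empty only)
loops_from_labels <- function(labels) {
  L <- length(labels)
  runs <- rle(labels != "H")
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1L
  keep <- which(runs$values)
  lapply(keep, function(j) {
    s <- starts[[j]]; e <- stops[[j]]
    list(kind = if (s == 1L) "n_tail" else if (e == L) "c_tail"
                else "internal",
         side = labels[[s]], span = c(s, e), loop_len = e - s + 1L)
  })
}

# random valid topology: H helices inside length L, loops may be empty
random_topology <- function(L, max_helices = 10L) {
  H <- sample(seq_len(max_helices), 1L)
  repeat {
    widths <- sample(1:30, H, replace = TRUE)
    if (sum(widths) < L) break
  }
  slack <- L - sum(widths)
  gaps <- as.integer(stats::rmultinom(1L, slack, rep(1, H + 1L)))
  starts <- integer(H)
  pos <- 0L
  for (k in seq_len(H)) {
    pos <- pos + gaps[[k]]
    starts[[k]] <- pos + 1L
    pos <- pos + widths[[k]]
  }
  topology_model(cbind(starts, starts + widths - 1L),
                 sample(c("inside", "outside"), 1L), L)
}

# annotation list for a protein with one TMHMM topology
tm_ann <- function(helices, n_side = "inside") {
  list(tmhmm_helices = helices, tmhmm_n_side = n_side)
}

make_protein <- function(len, id = "p1", seq = NULL) {
  protein_record(id, if (is.null(seq)) strrep("A", len) else seq,
                 "test protein")
}

# random archetype mix with at least one protein
random_proteome_spec <- function() {
  repeat {
    counts <- sample(0:2, length(default_proteome_spec()), replace = TRUE)
    names(counts) <- names(default_proteome_spec())
    if (sum(counts) >= 1L) return(counts[counts > 0L])
  }
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
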