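---
title: "Classifying bacterial surfaceomes from predictor evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying bacterial surfaceomes from predictor evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacsurf)
```

## The procedure

`bacsurf` does no sequence prediction of its own. Its contribution is
the *integration* step: parsing the raw output of established
predictors of signal peptides, lipoprotein signals, transmembrane
topology, cell-wall motifs and outer-membrane β-barrels into one
evidence map per protein, and classifying every protein of a proteome
with a protocol-specific decision tree. The assumptions are therefore
those of the upstream predictors, plus one structural assumption made
explicit below: a helical membrane protein's exposure is decided
entirely by the lengths and sides of its inter-helix loops and tails.

### Loop arithmetic

A topology model is the ordered list of helix spans plus the membrane
side of residue 1. A model with $H$ helices has exactly $H+1$ loops:
the N-tail $[1, s_1-1]$, internal loops $[e_k+1, s_{k+1}-1]$ and the
C-tail $[e_H+1, L]$, with sides alternating from the N-side. Loops of
length zero are kept so the alternation stays strict; a loop is
*strictly inter-helix* — helix-flanking residues are never counted
into a loop. The invariant $\sum \text{loop lengths} + \sum
\text{helix lengths} = L$ holds for every model and is tested against
a brute-force residue-labelling oracle.

Cleaved N-terminal regions (Sec or lipoprotein signals) are removed
before loop analysis, so a signal peptide can never masquerade as an
exposed N-tail. When both SignalP and LipoP are positive the larger
cleavage position is used, since both describe an N-terminal region
absent from the mature protein. A helix that straddles the cut is
truncated to start at residue 1 rather than dropped — a partially
predicted helix downstream of the cleavage site still anchors the
protein — while a helix entirely within the cut is dropped, flipping
the recorded N-side so every surviving loop keeps its side. A model
left with no helices sends the protein down the no-TM branch.

### Exposure thresholds

```{r}
default_config("gram_pos")[c("terminal_exposed_loop_min",
                             "internal_exposed_loop_min")]
default_config("gram_neg")[c("terminal_exposed_loop_min",
                             "internal_exposed_loop_min")]
```

Under the Gram-positive protocol an extracytoplasmic tail of ≥ 50
residues or internal loop of ≥ 100 residues marks a protein
potentially surface exposed; the values derive from membrane-shaving
experiments and depend on cell-wall thickness, so they are plain
config entries. The comparison is `>=`: the threshold is a *minimum
length*, matching the `_min` naming, so a 50-residue tail is exposed.
The alternative strict reading is one config change away.

Under the Gram-negative protocol both thresholds default to 30
residues, a conservative mark for tagging inner-membrane proteins with
long cytoplasmic (`+cyto`) or periplasmic (`+peri`) domains. Only an
internal-loop threshold is documented for this protocol upstream; we
apply 30 to tails as well, because a periplasmic C-terminal domain is
no less accessible in a spheroplast-shaving experiment than an
internal periplasmic loop of the same size. Both values are
configurable.

When TMHMM and MEMSAT3 are both enabled and disagree, exposure is
OR-combined across their models (any model with an exposed loop makes
the protein PSE, and the union of exposed sides feeds the IM suffix).
This deliberately maximizes sensitivity — the screening use case would
rather re-examine a candidate than miss one. Both predictors' helix
counts are always recorded in the evidence details, so disagreement is
visible in the report.

### Rule precedence

Gram-positive: surface motif > membrane > lipoprotein > secreted >
cytoplasm. A lipoprotein that also has predicted helices therefore
follows the membrane branch — the helices, not the lipid anchor,
determine what protrudes.

Gram-negative: barrel > lipoprotein > inner membrane > signal >
cytoplasm. Barrel evidence dominates because topology predictors
frequently call a barrel's signal anchor as a helix; a lipoprotein
with spurious helix calls stays a lipoprotein, with both evidence
strings recorded.

The β-barrel "maybe" bands — BOMP in $[1, 3)$, TMB-HUNT in
$[0.5, 0.95)$, any TMBETADISC-RBF positive, each requiring a predicted
Sec or Tat signal — are OR-combined across predictors. The upstream
description of the low-score band is ambiguous between AND and OR
semantics; OR is chosen because the web services are independently
optional, and an AND rule would make each unusable alone. The
high-confidence rule (BOMP ≥ 3 *or* TMB-HUNT ≥ 0.95, no signal
required) is read the same way.

### Tunable parameters

| key | default | meaning |
|---|---|---|
| `terminal_exposed_loop_min` | 50 (gram_pos) / 30 (gram_neg) | minimum exposed tail, residues |
| `internal_exposed_loop_min` | 100 (gram_pos) / 30 (gram_neg) | minimum exposed internal loop, residues |
| `hmm_evalue_max`, `hmm_score_min` | 0.1, 10 | profile-HMM hit acceptance; package defaults, as no canonical cutoffs accompany the motif set |
| `bomp_clearly_min`, `bomp_maybe_min` | 3, 1 | BOMP category bands |
| `tmbhunt_clearly_min`, `tmbhunt_maybe_min` | 0.95, 0.5 | TMB-HUNT probability bands |
| `enabled_plugins` | per protocol | MEMSAT3 off by default (it needs a PSI-BLAST run); TMBETA-NET not implemented |

Configurations serialize to a flat `key=value` file (comments with
`#`), chosen over executable configuration because a declarative file
is language-agnostic, safely shareable and round-trips losslessly —
the round trip is part of the test contract. Unknown keys are rejected
by name rather than ignored, so typos cannot silently revert a
threshold to its default.

### The profiles manifest

The Gram-positive motif scan reads whatever profile HMMs sit in
`profiles_dir`; `manifest.txt` maps each profile to the display name
used in evidence details (`hmm(LPxTG)`). The shipped manifest lists
the classic cell-wall motif set (LPxTG, GW repeats, PG-binding type 1,
choline-binding, LysM, cell-wall binding type 2, SLH, NLPC/P60). The
source listing assigns PF04122 to both cell-wall binding type 2 and
the S-layer homology domain — almost certainly a typographical
duplication; the manifest keeps both names and flags the shared
accession rather than guessing the intended one.

## The fixture model

Every plugin's testable half is a pure parser from the tool's raw
output text (or saved HTML result page) to annotation entries. The
exact dialect each parser accepts is pinned by generated fixture files,
which *are* the format contract: SignalP 4.0 short format, LipoP 1.0
short format, TMHMM 2.0 long format, MEMSAT3 output with the query id
on a `# SEQ` line, HMMER 3.x tabular hits, TatFind verdicts, and one
results-table layout per web service. HTML parsing tolerates attribute
and whitespace changes (it walks the DOM for a table whose header names
the score column) but fails loudly with "unrecognized page layout" on
structural change — screen-scraped interfaces break, and a loud error
beats silently empty annotations.

The synthetic-proteome generator plants archetypes — cytoplasmic,
Sec- and Tat-secreted, IM/OM lipoproteins, single- and multi-pass
membrane proteins with controlled loop lengths, cell-wall-motif
proteins, and β-barrels in each scoring band — and emits a FASTA file
plus matching raw outputs for every plugin. Sequence composition
realizes the planted features where the pipeline actually reads
sequence: hydrophobic 19–23-residue stretches at helix spans, a
Met/charged/hydrophobic/A-x-A signal layout, a lipobox ending in Cys
with the chosen +2 residue. Elsewhere the background is uniform over
the 20 amino acids: composition realism is *not* required, because the
classifiers only inspect raw sequence for the Asp+2 rule and the chop
arithmetic. Loop lengths are drawn to respect each archetype's
category (e.g. a non-PSE membrane protein's extracytoplasmic tails
stay below 50 and its internal loops below 100, while cytoplasmic
loops may exceed the Gram-negative 30-residue tag threshold).

The expected category of each synthetic protein is computed by an
independent rule trace over the planted feature values — never through
the loop arithmetic or classifiers under test — and the end-to-end
check demands exact agreement for every protein.

What passing these tests shows, and what it does not: the parsers
recover exactly what the pinned dialects encode, and the decision
trees implement the documented rules exactly. It does not show that
the upstream predictors are accurate on real sequences, that real tool
output never deviates from the pinned dialects (format drift across
tool versions is the known failure mode of wrapped pipelines), or that
the thresholds are right for organisms with unusual cell-wall
thickness.

## Numerical and degenerate-input choices

* All span arithmetic is 1-based inclusive; cleavage positions store
  the *last* residue of the removed peptide, so "mature protein starts
  at `pos + 1`" holds uniformly for SignalP and LipoP.
* Zero-length loops are representable (empty span, length 0) and all
  threshold comparisons are `>=`, so behaviour at the boundary is
  defined, tested, and monotone: growing an exposed loop can never
  un-expose a protein.
* Absent evidence is distinct from negative evidence: a plugin that
  was disabled contributes no keys and is recorded as
  `<plugin>(not-run)` in the details; a plugin that ran and found
  nothing stores explicit negatives.
* Duplicate sequence ids, empty sequences, text before the first `>`,
  `cleave_pos ≥ L` and malformed predictor rows are hard errors naming
  the offender; unknown letters in sequences are softened to `X` with
  a warning, since genome-annotation FASTA commonly contains them.
* Classification is deterministic: details strings are emitted in one
  canonical order, and re-running from a warm cache reproduces the CSV
  byte-for-byte.

## Problem sizes

The test suite checks the loop arithmetic against the brute-force
oracle on 1,000 random topologies (lengths up to 5,000 residues, up to
50 helices), parser ground-truth recovery over 100 generator seeds
(18-protein default proteome), and end-to-end agreement on 100 random
archetype mixes under both protocols; `scripts/acceptance.R` repeats
these measurements from scratch at the same sizes and additionally
recovers the thresholds (50/100/30), the barrel cutoffs (3, 0.95) and
the Asp+2 position behaviourally by sweeping.

## Limitations

* Predictors are wrapped, never re-implemented: without their saved
  raw outputs (or the fixture generator) the pipeline stops with an
  error naming the missing plugin and the expected cache file. Live
  execution of local binaries and web-form submission are deliberately
  out of scope here; re-running classification from a results folder
  is the supported recovery path when a service disappears.
* Secreted proteins without classical signals (Type 3 secretion,
  flagellar and pilus components) are not detected and will be called
  cytoplasmic.
* TMBETA-NET strand-position annotation is not implemented (prone to
  false positives on multidomain barrels and disabled by default
  upstream).
* Whether helix-flanking residues should count toward loop length is
  not decidable from the available descriptions; loops here are
  strictly inter-helix, which is the conservative (shorter-loop)
  reading.
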