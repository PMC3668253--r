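# bacsurf

Annotation of bacterial proteomes for subcellular localization and
potential surface exposure.

## The problem

Cell-surface protease "shaving" experiments digest intact bacteria and
identify, by mass spectrometry, the peptides that protrude outside the
cell. Interpreting such experiments — and screening pathogen proteomes
for vaccine candidates — requires knowing, for every protein in a
proteome, where it sits (cytoplasm, membrane, cell wall, periplasm,
outside) and whether enough of its polypeptide is exposed on the surface
to be accessible to a protease. No single predictor answers this;
the answer comes from combining evidence from several of them:

* **Sec signal peptides** (SignalP) and **Tat signals** (TatFind, plus a
  twin-arginine profile HMM),
* **lipoprotein signals** (LipoP) with their cleavage sites,
* **transmembrane helix topology** (TMHMM, optionally MEMSAT3),
* **cell-wall attachment motifs** (profile HMMs: LPxTG, GW repeats,
  peptidoglycan-binding, choline-binding, LysM, cell-wall binding type 2,
  S-layer homology, NLPC/P60),
* **outer-membrane β-barrel predictors** (BOMP, TMB-HUNT,
  TMBETADISC-RBF).

`bacsurf` parses the raw output of these tools, merges the evidence into
one map per protein, and classifies each protein with one of two
protocols.

## The classification logic

**Loop exposure.** For a protein with transmembrane helices
`(s_1,e_1) … (s_H,e_H)` and N-terminus on side `σ`, the H+1 loops (two
tails and H−1 inter-helix segments) alternate sides starting from `σ`.
A cleaved signal region is first removed (`chop_nterminal`), so a signal
peptide never counts as an exposed tail. A protein is *potentially
surface exposed* (PSE) when an extracytoplasmic loop reaches the
thresholds

    terminal tails   ≥ 50 aa    (Gram-positive default)
    internal loops   ≥ 100 aa   (Gram-positive default)

values calibrated against membrane-shaving data and configurable per run.

**Gram-positive protocol** (categories `PSE-Cellwall`, `PSE-Membrane`,
`PSE-Lipoprotein`, `MEMBRANE(non-PSE)`, `SECRETED`,
`CYTOPLASM(non-PSE)`): surface motif > membrane (PSE iff any topology
model has an exposed loop) > lipoprotein > secreted > cytoplasm.

**Gram-negative protocol** (categories `OM(barrel)`, `LIPOPROTEIN(IM)`,
`LIPOPROTEIN(OM)`, `IM`, `IM(cyto)`, `IM(peri)`, `IM(cyto+peri)`,
`PERIPLASMIC/SECRETED`, `CYTOPLASMIC`):

* β-barrel consensus: BOMP ≥ 3 or TMB-HUNT ≥ 0.95 alone; BOMP ∈ [1,3),
  TMB-HUNT ∈ [0.5,0.95) or an RBF positive only together with a
  predicted signal sequence;
* lipoproteins sorted by the **Asp+2 rule**: Asp at mature position 2
  (the residue after the lipidated Cys) retains the protein at the inner
  membrane, otherwise it goes to the outer membrane;
* inner-membrane proteins tagged `+cyto` / `+peri` for loops of ≥ 30
  residues on the cytoplasmic / periplasmic side.

## Worked example

Every predictor plugin reads a raw output file from the results
directory, so a run needs either the external tools' saved outputs or
the bundled fixture generator, which creates a synthetic proteome
together with matching predictor outputs and known ground truth:

```r
library(bacsurf)
syn <- generate_synthetic_proteome(seed = 101, dir = "demo")
cfg <- default_config("gram_pos")
cfg$results_dir <- "demo/results"
calls <- run_protocol(syn$fasta, cfg, fixture_dir = syn$dir)
writeLines(attr(calls, "summary"))
```

```
CYTOPLASM(non-PSE)      6
MEMBRANE(non-PSE)       2
PSE(total)              6
SECRETED                4
Total                  18
```

The summary rolls the three PSE categories into `PSE(total)`; `Total`
always equals the number of input proteins. Individual calls carry the
evidence behind them:

```r
print(calls[["SYN009_TMP"]])
#> SYN009_TMP  PSE-Membrane  [tmhmm(1);memsat3(not-run)]
```

— a single predicted helix whose extracytoplasmic tail passes the
50-residue threshold; MEMSAT3 is recorded as not run because it is
disabled by default. A CSV report (`seqid,category,details,description`)
is written alongside:

```
seqid,category,details,description
SYN001_CYT,CYTOPLASM(non-PSE),memsat3(not-run),synthetic cytoplasmic protein
SYN004_SEC,SECRETED,signalp;memsat3(not-run),synthetic secreted protein
```

The same FASTA classified with `default_config("gram_neg")` yields the
Gram-negative vocabulary (barrels, lipoprotein sorting, IM loop tags).

A thin command-line wrapper is included:

```sh
Rscript inst/cli/bacsurf.R proteome.fasta --protocol gram_neg \
    --results-dir results --fixture-dir saved_outputs
Rscript inst/cli/bacsurf.R --test        # bundled self-check
```

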