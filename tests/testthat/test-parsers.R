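# Inline fixture snippets pin the output dialect each parser targets.

test_that("SignalP short format: decision column and cleavage position", {
  text <- c(
    "# SignalP-4.0   gram+ predictions",
    "# name  Cmax  pos  Ymax  pos  Smax  pos  Smean   D     ?  Dmaxcut  Networks-used",
    "posA  0.52  23  0.72  23  0.81  15  0.61  0.68 Y  0.45  SignalP-noTM",
    "negB  0.11  11  0.12  11  0.20   4  0.15  0.09 N  0.45  SignalP-TM")
  m <- parse_signalp(text)
  expect_true(m$posA$is_signalp)
  expect_equal(m$posA$signalp_cleave_pos, 22L)  # mature starts at 23
  expect_false(m$negB$is_signalp)
  expect_null(m$negB$signalp_cleave_pos)
  expect_identical(parse_signalp(character(0)), list())
  expect_error(parse_signalp("posA 0.52 badrow"), "line 1")
})

test_that("LipoP short format: SpII class and cleavage pair", {
  text <- c(
    "lipo1 LipoP1.0:Best SpII 1 1 17.3600 # cleavage=19-20 Pos+2=D",
    "sec1 LipoP1.0:Best SpI 1 1 9.8100 # cleavage=22-23",
    "cyt1 LipoP1.0:Best CYT 1 1 -0.2000")
  m <- parse_lipop(text)
  expect_true(m$lipo1$is_lipop)
  expect_equal(m$lipo1$lipop_cleave_pos, 19L)
  expect_false(m$sec1$is_lipop)
  expect_false(m$cyt1$is_lipop)
  expect_identical(parse_lipop(character(0)), list())
  expect_error(parse_lipop("lipo1 LipoP1.0:Best SpII 1 1 17.36"),
               "cleavage")
})

test_that("TMHMM long format: helices, N side, and segment sanity", {
  text <- c(
    "# one Length: 200",
    "one\tTMHMM2.0\tinside\t1\t20",
    "one\tTMHMM2.0\tTMhelix\t21\t43",
    "one\tTMHMM2.0\toutside\t44\t200",
    "two\tTMHMM2.0\toutside\t1\t10",
    "two\tTMHMM2.0\tTMhelix\t11\t30",
    "two\tTMHMM2.0\tinside\t31\t50",
    "two\tTMHMM2.0\tTMhelix\t51\t70",
    "two\tTMHMM2.0\toutside\t71\t90",
    "none\tTMHMM2.0\tinside\t1\t150")
  m <- parse_tmhmm(text)
  expect_equal(unname(m$one$tmhmm_helices[, "start"]), 21L)
  expect_equal(unname(m$one$tmhmm_helices[, "stop"]), 43L)
  expect_equal(m$one$tmhmm_n_side, "inside")
  expect_equal(nrow(m$two$tmhmm_helices), 2L)
  expect_equal(m$two$tmhmm_n_side, "outside")
  expect_equal(nrow(m$none$tmhmm_helices), 0L)

  bad <- c("x\tTMHMM2.0\tinside\t1\t30",
           "x\tTMHMM2.0\tTMhelix\t25\t45")   # overlaps previous segment
  expect_error(parse_tmhmm(bad), "overlapping|contiguous")
  bad2 <- c("x\tTMHMM2.0\tinside\t1\t30",
            "x\tTMHMM2.0\tinside\t31\t60")   # same side twice, no helix
  expect_error(parse_tmhmm(bad2), "non-alternating")
})

test_that("MEMSAT3 output: helices and orientation for one sequence", {
  text <- c("# SEQ prot1", "FINAL PREDICTION",
            "1: (21-43)", "2: (80-102)", "3: (130-152)",
            "N-terminal: in")
  m <- parse_memsat3(text)
  expect_equal(nrow(m$prot1$memsat3_helices), 3L)
  expect_equal(m$prot1$memsat3_n_side, "inside")

  none <- parse_memsat3(c("# SEQ p2", "FINAL PREDICTION",
                          "N-terminal: in"))
  expect_equal(nrow(none$p2$memsat3_helices), 0L)

  nout <- parse_memsat3(c("# SEQ p3", "FINAL PREDICTION",
                          "1: (5-27)", "N-terminal: out"))
  expect_equal(nout$p3$memsat3_n_side, "outside")

  expect_error(parse_memsat3(c("# SEQ p4", "N-terminal: in")),
               "FINAL PREDICTION")
})

test_that("hmmsearch hits honour the E-value and score thresholds", {
  text <- c(
    "# target name  acc  query name  acc  E-value  score  bias",
    "hitA  -  LPxTG  PF00746  1e-20  80.0  0.1",
    "weakB -  LPxTG  PF00746  0.5     8.0  0.0",
    "hitA  -  LysM   PF01476  1e-05  25.0  0.0")
  m <- parse_hmmsearch(text, evalue_max = 0.1, score_min = 10)
  expect_length(m$hitA$hmm_matches, 2L)
  expect_equal(m$hitA$hmm_matches[[1L]]$profile, "LPxTG")
  expect_equal(m$hitA$hmm_matches[[1L]]$e_value, 1e-20)
  expect_null(m$weakB)
  expect_identical(parse_hmmsearch(character(0)), list())
  expect_error(parse_hmmsearch("hitA - LPxTG"), "line 1")
})

test_that("TatFind verdict lines", {
  text <- c("TatFind 1.4 Results:",
            ">tat1 : TRUE - Tat signal predicted",
            ">no1 : FALSE")
  m <- parse_tatfind(text)
  expect_true(m$tat1$is_tatfind)
  expect_false(m$no1$is_tatfind)
  expect_identical(parse_tatfind(character(0)), list())
  expect_error(parse_tatfind(">weird verdict line"), "malformed")
})

test_that("BOMP result pages yield integer categories", {
  page <- c("<html><body><table>",
            "<tr><th>Number</th><th>Sequence</th><th>Category</th></tr>",
            "<tr><td>1</td><td>barrelA some description</td><td>4</td></tr>",
            "<tr><td>2</td><td>barrelB</td><td>1</td></tr>",
            "<tr><td>3</td><td>barrelC</td><td>5</td></tr>",
            "</table></body></html>")
  m <- parse_bomp_html(page)
  expect_equal(m$barrelA$bomp_score, 4L)
  expect_equal(m$barrelB$bomp_score, 1L)
  expect_equal(m$barrelC$bomp_score, 5L)

  empty <- c("<html><body><table>",
             "<tr><th>Number</th><th>Sequence</th><th>Category</th></tr>",
             "</table></body></html>")
  expect_identical(parse_bomp_html(empty), list())
  expect_error(parse_bomp_html("<html><body><p>maintenance</p></body></html>"),
               "unrecognized page layout")
})

test_that("TMB-HUNT and TMBETADISC-RBF pages parse probabilities/verdicts", {
  hunt <- c("<html><body><table>",
            "<tr><th>Sequence</th><th>Probability</th></tr>",
            "<tr><td>a</td><td>0.97</td></tr>",
            "<tr><td>b</td><td>0.10</td></tr>",
            "</table></body></html>")
  m <- parse_tmbhunt_html(hunt)
  expect_equal(m$a$tmbhunt_prob, 0.97)
  expect_equal(m$b$tmbhunt_prob, 0.10)

  rbf <- c("<html><body><table>",
           "<tr><th>Sequence</th><th>Prediction</th></tr>",
           "<tr><td>pos</td><td>Outer Membrane Protein</td></tr>",
           "<tr><td>neg</td><td>Non-Outer Membrane Protein</td></tr>",
           "</table></body></html>")
  m2 <- parse_tmbetadisc_html(rbf)
  expect_true(m2$pos$is_tmbetadisc_rbf)
  expect_false(m2$neg$is_tmbetadisc_rbf)
  expect_error(parse_tmbhunt_html("<html><body></body></html>"),
               "unrecognized page layout")
})

test_that("parsers recover generator ground truth (spot seeds)", {
  for (seed in c(2, 23, 91)) {
    syn <- generate_synthetic_proteome(seed = seed)
    sp <- parse_signalp(readLines(syn$files[["signalp.out"]]))
    lp <- parse_lipop(readLines(syn$files[["lipop.out"]]))
    tm <- parse_tmhmm(readLines(syn$files[["tmhmm.out"]]))
    for (id in names(syn$truth)) {
      t <- syn$truth[[id]]
      expect_equal(sp[[id]]$is_signalp, t$has_sec_signal)
      if (t$has_sec_signal)
        expect_equal(sp[[id]]$signalp_cleave_pos, t$signal_cleave)
      expect_equal(lp[[id]]$is_lipop, !is.null(t$lipop_cleave))
      if (!is.null(t$lipop_cleave))
        expect_equal(lp[[id]]$lipop_cleave_pos, t$lipop_cleave)
      if (is.null(t$helices)) {
        expect_equal(nrow(tm[[id]]$tmhmm_helices), 0L)
      } else {
        expect_equal(unname(tm[[id]]$tmhmm_helices),
                     unname(t$helices))
        expect_equal(tm[[id]]$tmhmm_n_side, t$n_side)
      }
    }
    unlink(syn$dir, recursive = TRUE)
  }
})

test_that("merging parser outputs with disjoint keys is order-independent", {
  syn <- generate_synthetic_proteome(seed = 5)
  a <- parse_signalp(readLines(syn$files[["signalp.out"]]))
  b <- parse_tmhmm(readLines(syn$files[["tmhmm.out"]]))
  merge_maps <- function(x, y) {
    for (id in names(y))
      x[[id]] <- utils::modifyList(
        if (is.null(x[[id]])) list() else x[[id]], y[[id]])
    x
  }
  ab <- merge_maps(a, b)
  ba <- merge_maps(b, a)
  for (id in names(ab))
    expect_equal(ab[[id]][order(names(ab[[id]]))],
                 ba[[id]][order(names(ba[[id]]))])
  unlink(syn$dir, recursive = TRUE)
})
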