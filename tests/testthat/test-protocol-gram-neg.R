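cfg_gn <- default_config("gram_neg")

test_that("barrel consensus bands and the signal requirement", {
  ib <- function(ann, sig) is_barrel(ann, cfg_gn, sig)
  expect_true(ib(list(bomp_score = 3L), FALSE))       # high band alone
  expect_false(ib(list(bomp_score = 2L), FALSE))      # low band needs signal
  expect_true(ib(list(bomp_score = 2L), TRUE))
  expect_true(ib(list(tmbhunt_prob = 0.95), FALSE))
  expect_false(ib(list(tmbhunt_prob = 0.94), FALSE))
  expect_true(ib(list(tmbhunt_prob = 0.5), TRUE))
  expect_false(ib(list(tmbhunt_prob = 0.49), TRUE))
  expect_false(ib(list(is_tmbetadisc_rbf = TRUE), FALSE))
  expect_true(ib(list(is_tmbetadisc_rbf = TRUE), TRUE))
  expect_false(ib(list(), TRUE))
})

test_that("barrel call is monotone in each predictor score", {
  for (sig in c(FALSE, TRUE)) {
    bomp_res <- vapply(0:5, function(s)
      is_barrel(list(bomp_score = s), cfg_gn, sig), logical(1))
    expect_true(all(diff(bomp_res) >= 0))
    prob_res <- vapply(seq(0, 1, by = 0.01), function(pr)
      is_barrel(list(tmbhunt_prob = pr), cfg_gn, sig), logical(1))
    expect_true(all(diff(prob_res) >= 0))
  }
})

test_that("Asp at mature position 2, and only position 2, retains at the IM", {
  # precursor: 19-residue signal, then C at 20; mature position k is 19+k
  mk_seq <- function(asp_at) {
    chars <- strsplit(strrep("S", 60), "")[[1L]]
    chars[20L] <- "C"
    if (!is.na(asp_at)) chars[19L + asp_at] <- "D"
    paste(chars, collapse = "")
  }
  expect_equal(lipoprotein_destination(mk_seq(2L), 19L), "IM")
  expect_equal(lipoprotein_destination(mk_seq(NA), 19L), "OM")
  expect_equal(lipoprotein_destination(mk_seq(3L), 19L), "OM")
  for (pos in c(1L, 3L, 4L, 5L, 10L))
    expect_equal(lipoprotein_destination(mk_seq(pos), 19L), "OM")
  expect_error(lipoprotein_destination("MKLC", 3L), "shorter than 2")
})

test_that("decision tree assigns the documented categories", {
  p <- make_protein(200)
  cl <- function(ann, prot = p) classify_gram_neg(prot, ann, cfg_gn)$category

  expect_equal(cl(list()), "CYTOPLASMIC")
  expect_equal(cl(list(is_signalp = TRUE, signalp_cleave_pos = 22L)),
               "PERIPLASMIC/SECRETED")
  expect_equal(cl(list(is_tatfind = TRUE)), "PERIPLASMIC/SECRETED")
  expect_equal(cl(list(is_tat_hmm = TRUE)), "PERIPLASMIC/SECRETED")
  expect_equal(cl(list(bomp_score = 4L)), "OM(barrel)")
  # low barrel evidence plus a Tat signal is still a barrel
  expect_equal(cl(list(bomp_score = 2L, is_tatfind = TRUE)), "OM(barrel)")

  seq_im <- paste0(strrep("S", 19), "CD", strrep("S", 60))
  lip <- protein_record("lip", seq_im, "")
  expect_equal(cl(list(is_lipop = TRUE, lipop_cleave_pos = 19L), lip),
               "LIPOPROTEIN(IM)")
  seq_om <- paste0(strrep("S", 19), "CS", strrep("S", 60))
  lip2 <- protein_record("lip2", seq_om, "")
  expect_equal(cl(list(is_lipop = TRUE, lipop_cleave_pos = 19L), lip2),
               "LIPOPROTEIN(OM)")
})

test_that("inner-membrane suffixes reflect the exposed sides", {
  cl <- function(L, helices, n_side = "inside") {
    classify_gram_neg(make_protein(L), tm_ann(helices, n_side),
                      cfg_gn)$category
  }
  # two helices, inside internal loop of 40, outside loops short
  expect_equal(cl(100, rbind(c(11, 30), c(71, 90)), "outside"), "IM(cyto)")
  # all loops under 30
  expect_equal(cl(60, rbind(c(11, 30), c(36, 55)), "inside"), "IM")
  # long outside C-tail only
  expect_equal(cl(150, rbind(c(5, 25)), "inside"), "IM(peri)")
  # long tails on both sides
  expect_equal(cl(200, rbind(c(60, 80)), "inside"), "IM(cyto+peri)")
})

test_that("suffix soundness holds over random topologies", {
  set.seed(77)
  for (i in 1:100) {
    L <- sample(80:1000, 1L)
    topo <- random_topology(L, max_helices = 6L)
    ann <- tm_ann(topo$helices, topo$n_side)
    p <- make_protein(L)
    cat <- classify_gram_neg(p, ann, cfg_gn)$category
    loops <- loops_from_topology(topo)
    lens <- vapply(loops, `[[`, integer(1), "loop_len")
    sides <- vapply(loops, `[[`, character(1), "side")
    peri <- any(lens >= 30L & sides == "outside")
    cyto <- any(lens >= 30L & sides == "inside")
    expect_equal(grepl("peri", cat), peri)
    expect_equal(grepl("cyto", cat), cyto)
    expect_true(startsWith(cat, "IM"))
  }
})

test_that("lipoprotein destination depends only on the mature +2 residue", {
  set.seed(88)
  for (i in 1:25) {
    cp <- sample(12:30, 1L)
    L <- cp + sample(50:150, 1L)
    chars <- sample(c("A", "E", "F", "G", "K", "L", "S", "T"), L,
                    replace = TRUE)
    chars[cp + 1L] <- "C"
    plus2 <- sample(c("D", "S", "A", "N"), 1L)
    chars[cp + 2L] <- plus2
    p <- protein_record(paste0("lp", i), paste(chars, collapse = ""), "")
    cat <- classify_gram_neg(p, list(is_lipop = TRUE,
                                     lipop_cleave_pos = cp), cfg_gn)$category
    expect_equal(cat, if (plus2 == "D") "LIPOPROTEIN(IM)"
                      else "LIPOPROTEIN(OM)")
  }
})

test_that("lipoprotein evidence wins over helices, with both in details", {
  seq_im <- paste0(strrep("S", 19), "CD", strrep("S", 100))
  p <- protein_record("lp", seq_im, "")
  ann <- c(tm_ann(rbind(c(40, 62))),
           list(is_lipop = TRUE, lipop_cleave_pos = 19L))
  call <- classify_gram_neg(p, ann, cfg_gn)
  expect_equal(call$category, "LIPOPROTEIN(IM)")
  expect_true(all(c("lipop", "tmhmm(1)") %in% call$details))
})

test_that("category partition and totals hold on a fixture proteome", {
  syn <- generate_synthetic_proteome(seed = 29)
  cfg <- default_config("gram_neg")
  cfg$results_dir <- tempfile()
  calls <- run_protocol(syn$fasta, cfg, fixture_dir = syn$dir)
  cats <- vapply(calls, `[[`, character(1), "category")
  expect_true(all(cats %in% protocol_categories("gram_neg")))
  lines <- format_summary(calls, "gram_neg")
  counts <- as.integer(sub(".*\\s", "", lines))
  expect_equal(sum(counts[-length(counts)]), counts[[length(counts)]])
  expect_equal(counts[[length(counts)]], length(syn$proteins))
  unlink(c(syn$dir, cfg$results_dir), recursive = TRUE)
})
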