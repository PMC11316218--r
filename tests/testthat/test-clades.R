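test_that("monophyly matches node tip sets exactly", {
  tr <- ape::read.tree(text = "((a,b),c);")
  expect_true(is_monophyletic(tr, c("a", "b")))
  expect_false(is_monophyletic(tr, c("a", "c")))
  expect_true(is_monophyletic(tr, "a"))
  expect_true(is_monophyletic(tr, c("a", "b", "c")))
  expect_error(is_monophyletic(tr, c("a", "zzz")), "not in tree")
})

test_that("queries are assigned to the smallest reference-pure clade", {
  tr <- ape::read.tree(text = "((q,ascl1),ors1);")
  refs <- c(ascl1 = "ASCL", ors1 = "ORS")
  expect_equal(assign_query_to_clade(tr, "q", refs), "ASCL")
  # query sister to the root with references split below
  tr2 <- ape::read.tree(text = "(q,(ascl1,ors1));")
  expect_equal(assign_query_to_clade(tr2, "q", refs), "unplaced")
  # query inside a clade of three same-class references
  tr3 <- ape::read.tree(text = "(((q,ors1),(ors2,ors3)),ascl1);")
  refs3 <- c(ors1 = "ORS", ors2 = "ORS", ors3 = "ORS", ascl1 = "ASCL")
  expect_equal(assign_query_to_clade(tr3, "q", refs3), "ORS")
  expect_error(assign_query_to_clade(tr, "zzz", refs), "not a leaf")
})

test_that("clade assignment is invariant to child rotation", {
  tr <- ape::read.tree(text = "(((q,ors1),(ors2,ascl2)),ascl1);")
  refs <- c(ors1 = "ORS", ors2 = "ORS", ascl1 = "ASCL", ascl2 = "ASCL")
  rotated <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(assign_query_to_clade(tr, "q", refs),
               assign_query_to_clade(rotated, "q", refs))
})

test_that("maximal clade counting matches hand enumeration", {
  tr <- ape::read.tree(text = "((a1,a2),(b,(a3,c)));")
  is_a <- setNames(grepl("^a", tr$tip.label), tr$tip.label)
  expect_equal(count_maximal_clades(tr, is_a), 2L)
  expect_equal(count_maximal_clades(tr, setNames(rep(TRUE, 5),
                                                 tr$tip.label)), 1L)
  expect_equal(count_maximal_clades(tr, setNames(rep(FALSE, 5),
                                                 tr$tip.label)), 0L)
  expect_error(count_maximal_clades(tr, c(a1 = TRUE)), "no metadata")
})

test_that("maximal clade counting equals brute force on random trees", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    sat <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE), tr$tip.label)
    expect_equal(count_maximal_clades(tr, sat),
                 brute_maximal_clades(tr, sat))
  }
})

test_that("concordance report flags planted discordance", {
  # queries placed with their own class references
  tr <- ape::read.tree(
    text = "(((qa,ascl1),(qo1,(qo2,ors1))),out);")
  refs <- c(ascl1 = "ASCL", ors1 = "ORS")
  mk <- function(id, label) {
    data.frame(id = id, label = label, best_reference = "", score = 0,
               triad_ok = TRUE, triad = "", motif_positions = "372",
               diagnostics = "", note = "", stringsAsFactors = FALSE)
  }
  good <- rbind(mk("qa", "ASCL"), mk("qo1", "ORS"), mk("qo2", "ORS"))
  rep1 <- concordance_report(good, tr, refs)
  expect_equal(rep1$concordance, 100)
  expect_true(all(rep1$assignments$concordant))
  expect_true(rep1$monophyly[["ASCL"]])
  # a query with ASCL residues sitting in the ORS clade
  bad <- rbind(mk("qa", "ASCL"), mk("qo1", "ASCL"), mk("qo2", "ORS"))
  rep2 <- concordance_report(bad, tr, refs)
  expect_false(rep2$assignments$concordant[rep2$assignments$id == "qo1"])
  expect_equal(rep2$assignments$clade_label[rep2$assignments$id == "qo1"],
               "ORS")
  # empty query set: empty report, no error
  rep3 <- concordance_report(good[0, ], tr, refs)
  expect_equal(nrow(rep3$assignments), 0)
})

test_that("clade reports serialize to JSON and TSV", {
  tr <- ape::read.tree(text = "((qa,ascl1),ors1);")
  refs <- c(ascl1 = "ASCL", ors1 = "ORS")
  tab <- data.frame(id = "qa", label = "ASCL", stringsAsFactors = FALSE)
  rep <- concordance_report(tab, tr, refs)
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_clade_report(rep, jf, tf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$concordance, 100)
  back <- read.delim(tf)
  expect_equal(back$id, "qa")
})
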