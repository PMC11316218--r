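test_that("NJ reproduces the closed-form three-taxon solution", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- nj_tree(D)
  # closed form: la = (Dab + Dac - Dbc)/2 = 0.5, lb = 1.5, lc = 2.5
  len <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                  tree$tip.label)
  expect_equal(len, c(a = 0.5, b = 1.5, c = 2.5))
})

test_that("NJ recovers additive matrices exactly (path lengths and topology)", {
  set.seed(13)
  for (n in 4:6) {
    true <- ape::rtree(n)
    true$edge.length <- true$edge.length + 0.1
    D <- ape::cophenetic.phylo(true)
    ids <- rownames(D)
    est <- nj_tree(D)
    # leaf-to-leaf path lengths reproduce the matrix exactly
    expect_equal(ape::cophenetic.phylo(est)[ids, ids], D, tolerance = 1e-10)
    # topology identical to the generating tree
    expect_equal(phangorn::RF.dist(ape::unroot(true), est), 0)
    # and to the exhaustive least-squares optimum
    expect_equal(phangorn::RF.dist(exhaustive_ls_topology(D), est), 0)
  }
})

test_that("NJ validates its input and is deterministic on ties", {
  D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  t1 <- nj_tree(D)
  t2 <- nj_tree(D)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  bad <- D
  bad[1, 2] <- NaN
  expect_error(nj_tree(bad), "NA/NaN")
  asym <- D
  asym[1, 2] <- 5
  expect_error(nj_tree(asym), "symmetric")
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("bootstrap gives full support to uncontradicted clades and is reproducible", {
  set.seed(77)
  # a/b identical, far from c/d: every resampled column supports {a,b}
  base <- random_protein(120)
  far1 <- random_protein(120)
  far2 <- paste0(substr(far1, 1, 100), random_protein(20))
  msa <- new_msa(c(a = base, b = base, c = far1, d = far2))
  tr <- bootstrap_support(msa, 50, seed = 5)
  keys <- pks3class:::tree_bipartitions(tr)
  ab_node <- names(keys)[keys == paste(sort(c("c", "d")), collapse = "\r") |
                           keys == paste(sort(c("a", "b")), collapse = "\r")]
  ntip <- 4
  supports <- tr$node.label[as.integer(ab_node) - ntip]
  expect_true(all(supports == "100"))
  # same seed -> byte-identical newick; different seed may differ
  tr2 <- bootstrap_support(msa, 50, seed = 5)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  expect_error(bootstrap_support(msa, 0), "at least 1")
})

test_that("bootstrap supports stay within [0, 100] on random alignments", {
  set.seed(19)
  # correlated rows so distances stay finite
  base <- random_protein(60)
  rows <- setNames(vapply(1:6, function(i) {
    s <- base
    for (p in sample(60, 12)) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(aa_alphabet(), cur), 1)
    }
    s
  }, character(1)), paste0("t", 1:6))
  tr <- bootstrap_support(new_msa(rows), 25, seed = 3)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("outgroup rooting splits the subtending branch and keeps path lengths", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- nj_tree(D)
  rooted <- root_with_outgroup(tree, "a")
  expect_true(ape::is.rooted(rooted))
  kids <- rooted$edge[rooted$edge[, 1] == length(rooted$tip.label) + 1L, 2]
  a_tip <- match("a", rooted$tip.label)
  expect_true(a_tip %in% kids)
  pd_before <- ape::cophenetic.phylo(tree)
  pd_after <- ape::cophenetic.phylo(rooted)
  ids <- rownames(pd_before)
  expect_equal(pd_after[ids, ids], pd_before, tolerance = 1e-10)
  expect_error(root_with_outgroup(tree, "zzz"), "not a leaf")
})

test_that("rooting a larger tree preserves bipartition supports", {
  set.seed(101)
  base <- random_protein(150)
  rows <- setNames(vapply(1:6, function(i) {
    s <- base
    for (p in sample(150, 10 * i)) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(aa_alphabet(), cur), 1)
    }
    s
  }, character(1)), paste0("t", 1:6))
  tr <- bootstrap_support(new_msa(rows), 20, seed = 2)
  rooted <- root_with_outgroup(tr, "t6")
  expect_true(ape::is.rooted(rooted))
  expect_setequal(setdiff(rooted$node.label, c("", "Root")),
                  setdiff(tr$node.label, ""))
})

test_that("Newick round-trip preserves topology, lengths and supports", {
  set.seed(55)
  tree <- ape::rtree(8)
  tree$node.label <- c("", as.character(sample(50:100, tree$Nnode - 1)))
  tree$tip.label[1] <- "Spimu1|13141"   # punctuated id needs quoting
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tree, f)
  back <- read_tree_newick(f)
  expect_equal(phangorn::RF.dist(tree, back), 0)
  expect_setequal(back$tip.label, tree$tip.label)
  o <- match(ape::write.tree(tree), ape::write.tree(back))
  expect_equal(sort(back$edge.length), sort(tree$edge.length),
               tolerance = 1e-9)
  expect_setequal(back$node.label, tree$node.label)
})

test_that("NNI refinement restores the generating topology and never worsens fit", {
  set.seed(61)
  true <- ape::rtree(4)
  true$edge.length <- true$edge.length + 0.2
  D <- ape::cophenetic.phylo(true)
  # already-optimal tree is returned unchanged (criterion 0)
  opt <- nni_refine(ape::unroot(true), D)
  expect_equal(phangorn::RF.dist(opt, ape::unroot(true)), 0)
  expect_lt(attr(opt, "lsq"), 1e-10)
  # deliberately swapped topology is repaired
  labs <- true$tip.label
  wrong <- NULL
  for (a in list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))) {
    cand <- ape::read.tree(text = sprintf("((%s,%s),%s,%s);",
                                          labs[a[1]], labs[a[2]],
                                          labs[a[3]], labs[a[4]]))
    if (phangorn::RF.dist(cand, ape::unroot(true)) > 0) {
      wrong <- cand
      break
    }
  }
  wrong$edge.length <- rep(0.5, nrow(wrong$edge))
  fixed <- nni_refine(wrong, D)
  expect_equal(phangorn::RF.dist(fixed, ape::unroot(true)), 0)
  expect_lt(attr(fixed, "lsq"), 1e-10)
})
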