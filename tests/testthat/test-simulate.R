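test_that("reference scaffolds are self-consistent, classifiable and seeded", {
  spec <- synthetic_family_spec(seed = 5)
  profs <- make_reference_scaffolds(spec)
  for (p in profs) expect_silent(validate_reference_profile(p))
  expect_equal(classify_sequence(profs$ASCL$residues, profs)$label, "ASCL")
  expect_equal(classify_sequence(attr(profs, "not_pks"), profs)$label,
               "not_PKSIII")
  profs2 <- make_reference_scaffolds(spec)
  expect_identical(vapply(profs, `[[`, character(1), "residues"),
                   vapply(profs2, `[[`, character(1), "residues"))
  expect_error(make_reference_scaffolds(
    synthetic_family_spec(scaffold_length = 100)), "too short")
})

test_that("a zero-length tree leaves all leaves identical to the scaffold", {
  spec <- synthetic_family_spec(seed = 9, indel_rate = 0.01)
  profs <- make_reference_scaffolds(spec)
  tree <- sim_tree(4, 0.5, seed = 2)
  tree$edge.length <- tree$edge.length * 0
  fam <- evolve_family(profs$ORS, tree, spec, seed = 3)
  expect_true(all(fam$records$residues == profs$ORS$residues))
})

test_that("preserved diagnostics keep every leaf classifiable as its class", {
  spec <- synthetic_family_spec(seed = 21, tree_height = 0.5,
                                preserve_diagnostics = TRUE)
  profs <- make_reference_scaffolds(spec)
  for (cl in c("ASCL", "ORS")) {
    fam <- evolve_family(profs[[cl]], sim_tree(5, 0.5, seed = 31), spec,
                         seed = 37)
    labels <- vapply(seq_len(nrow(fam$records)), function(i)
      classify_sequence(fam$records[i, ], profs)$label, character(1))
    expect_true(all(labels == cl))
    # planted coordinates point at the required residues after remapping
    for (i in seq_len(nrow(fam$records))) {
      coords <- fam$planted[[i]]
      lay <- pks3class:::synthetic_layout()
      triad_now <- coords[as.character(lay$triad$position)]
      expect_equal(
        unname(substring(fam$records$residues[i], triad_now, triad_now)),
        lay$triad$residue)
    }
  }
})

test_that("realized pairwise distance tracks the generating path length", {
  spec <- synthetic_family_spec(seed = 1, indel_rate = 0,
                                preserve_diagnostics = FALSE)
  profs <- make_reference_scaffolds(spec)
  # two leaves at path distance 2 * 0.25 = 0.5
  tree <- ape::read.tree(text = "(a:0.25,b:0.25);")
  dists <- vapply(1:40, function(r) {
    fam <- evolve_family(profs$other_PKSIII, tree, spec, seed = 100 + r)
    as.numeric(jtt_distance(fam$records$residues[1], fam$records$residues[2]))
  }, numeric(1))
  # Monte-Carlo mean within ~3 standard errors of the generating value
  expect_equal(mean(dists), 0.5, tolerance = 3 * stats::sd(dists) /
                 sqrt(length(dists)) / 0.5 + 0.02)
})

test_that("indels remap planted coordinates and respect the buffer", {
  spec <- synthetic_family_spec(seed = 77, tree_height = 0.8,
                                indel_rate = 0.01, indel_mean_length = 4)
  profs <- make_reference_scaffolds(spec)
  fam <- evolve_family(profs$ASCL, sim_tree(6, 0.8, seed = 7), spec, seed = 11)
  lengths <- nchar(fam$records$residues)
  expect_gt(length(unique(lengths)), 1)  # indels actually happened
  lay <- pks3class:::synthetic_layout()
  for (i in seq_len(nrow(fam$records))) {
    coords <- fam$planted[[i]]
    m <- coords[as.character(lay$motif_start)]
    expect_equal(substring(fam$records$residues[i], m, m + 4), "GFGPG")
  }
})

test_that("datasets are written deterministically and survive a round trip", {
  spec <- synthetic_family_spec(
    n_per_class = c(ASCL = 2, ORS = 2, other_PKSIII = 1, not_PKSIII = 1),
    seed = 19)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gen1 <- generate_dataset(spec, d1)
  gen2 <- generate_dataset(spec, d2)
  for (f in c("sequences.fasta", "taxa.tsv", "references.fasta",
              "reference_annotations.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  recs <- read_fasta(gen1$paths$sequences)
  expect_equal(nrow(recs), 7)  # 6 + outgroup
  taxa <- read_taxon_table(gen1$paths$taxa)
  expect_setequal(taxa$id, recs$id)
  profs <- load_reference_profiles(gen1$paths$references, gen1$paths$annotations)
  expect_named(profs, c("ASCL_ref", "ORS_ref", "PKS3_ref"))
})

test_that("an all-zero spec yields empty outputs without crashing", {
  spec <- synthetic_family_spec(n_per_class = c(ASCL = 0, ORS = 0,
                                                other_PKSIII = 0,
                                                not_PKSIII = 0),
                                outgroup = FALSE, seed = 4)
  d <- withr::local_tempdir()
  gen <- generate_dataset(spec, d)
  expect_equal(nrow(gen$records), 0)
  expect_true(file.exists(gen$paths$sequences))
})

test_that("classifier accuracy is perfect at moderate height with preservation", {
  spec <- synthetic_family_spec(
    n_per_class = c(ASCL = 4, ORS = 4, other_PKSIII = 4, not_PKSIII = 2),
    tree_height = 0.5, seed = 23)
  d <- withr::local_tempdir()
  gen <- generate_dataset(spec, d)
  profs <- load_reference_profiles(gen$paths$references, gen$paths$annotations)
  recs <- read_fasta(gen$paths$sequences)
  tab <- classification_table(classify_sequences(recs, profs))
  expect_equal(tab$label[match(gen$truth$id, tab$id)], gen$truth$class)
})

test_that("NJ recovers the generating topology at low divergence", {
  spec <- synthetic_family_spec(seed = 1, tree_height = 0.5, indel_rate = 0,
                                preserve_diagnostics = TRUE)
  profs <- make_reference_scaffolds(spec)
  hits <- vapply(1:20, function(r) {
    tree <- sim_tree(8, 0.5, seed = 400 + r)
    fam <- evolve_family(profs$other_PKSIII, tree, spec, seed = 500 + r)
    msa <- new_msa(setNames(fam$records$residues, fam$records$id))
    est <- nj_tree(build_distance_matrix(msa))
    phangorn::RF.dist(ape::unroot(tree), est) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
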