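# hand-checkable mini reference used for the numbering-transfer tests
mini_profile <- function() {
  reference_profile(
    "mini", "ASCL", "MKCWHANDYWGFGPG",
    triad = data.frame(position = c(3L, 5L, 7L), residue = c("C", "H", "N")),
    motif_position = 11L,
    diagnostics = data.frame(position = c(8L, 9L), allowed = c("D", "YW"),
                             class = "ASCL"))
}

test_that("alignment to an identical reference maps every position to itself", {
  prof <- mini_profile()
  aln <- align_to_reference(prof$residues, prof)
  expect_false(grepl("-", aln$ref_gapped))
  expect_false(grepl("-", aln$query_gapped))
  for (p in c(1, 3, 8, 15)) expect_equal(map_position(aln, p), p)
})

test_that("an insertion in the query shifts downstream reference numbering", {
  prof <- mini_profile()
  # insert one residue before reference position 8
  query <- paste0(substr(prof$residues, 1, 7), "A",
                  substr(prof$residues, 8, nchar(prof$residues)))
  aln <- align_to_reference(query, prof)
  expect_equal(map_position(aln, 7), 7)
  expect_equal(map_position(aln, 8), 9)
  expect_equal(map_position(aln, 15), 16)
  # hand-worked analogue: in the alignment A-BC / AXBC the reference B
  # (position 2) faces query position 3
  aln2 <- pks3class:::new_pairwise_alignment("r", "q", "A-BC", "AXBC", 0)
  expect_equal(map_position(aln2, 2), 3)
  expect_equal(aln2$ref_to_query, c(1L, 3L, 4L))
})

test_that("map_position reports gaps and rejects out-of-range positions", {
  prof <- mini_profile()
  # delete reference positions 4-6 from the query
  query <- paste0(substr(prof$residues, 1, 3),
                  substr(prof$residues, 7, nchar(prof$residues)))
  aln <- align_to_reference(query, prof)
  expect_true(is.na(map_position(aln, 5)))
  expect_error(map_position(aln, 0), "out of range")
  expect_error(map_position(aln, 99), "out of range")
  expect_error(align_to_reference("", prof), "empty")
})

test_that("signature motif scanner finds (G/A)FGPG occurrences", {
  expect_equal(find_signature_motif("MKGFGPGQ"), 3L)
  expect_equal(find_signature_motif("AFGPG"), 1L)
  expect_equal(find_signature_motif("SFGPG"), integer(0))
  # overlap: GFGPGFGPG has hits at 1 and 5
  expect_equal(find_signature_motif("GFGPGFGPG"), c(1L, 5L))
})

test_that("motif scanner agrees with a brute-force window scan", {
  set.seed(99)
  for (i in 1:300) {
    s <- random_protein(sample(5:80, 1), alphabet = c("G", "A", "F", "P", "S"))
    expect_identical(find_signature_motif(s), brute_motif_scan(s))
  }
})

test_that("triad checking reports residues, mismatches and gaps", {
  prof <- mini_profile()
  aln <- align_to_reference(prof$residues, prof)
  tri <- check_triad(prof$residues, prof, aln)
  expect_true(tri$ok)
  expect_equal(tri$evidence$observed, c("C", "H", "N"))

  mutated <- prof$residues
  substr(mutated, 3, 3) <- "S"
  tri2 <- check_triad(mutated, prof, align_to_reference(mutated, prof))
  expect_false(tri2$ok)
  expect_equal(tri2$evidence$observed[1], "S")

  # deletion spanning the triad-H position
  gapped <- paste0(substr(prof$residues, 1, 3),
                   substr(prof$residues, 7, nchar(prof$residues)))
  tri3 <- check_triad(gapped, prof, align_to_reference(gapped, prof))
  expect_false(tri3$ok)
  expect_equal(tri3$evidence$observed[2], "-")
})

test_that("reference scaffolds self-classify and labels respect diagnostics", {
  profs <- test_profiles()
  expect_equal(classify_sequence(profs$ASCL$residues, profs)$label, "ASCL")
  expect_equal(classify_sequence(profs$ORS$residues, profs)$label, "ORS")
  expect_equal(classify_sequence(profs$other_PKSIII$residues, profs)$label,
               "other_PKSIII")
  expect_equal(classify_sequence(attr(profs, "not_pks"), profs)$label,
               "not_PKSIII")
  expect_error(classify_sequence(profs$ASCL$residues, list()), "no reference")
  expect_error(classify_sequence(profs$ASCL$residues, profs["ASCL"]),
               "at least one ASCL and one ORS")
})

test_that("single diagnostic mutations flip labels; neutral ones do not", {
  profs <- test_profiles()
  ascl <- profs$ASCL$residues
  diag_pos <- profs$ASCL$diagnostics$position
  for (p in diag_pos) {
    mutated <- ascl
    substr(mutated, p, p) <- "W"   # W is in no diagnostic allowed set
    expect_equal(classify_sequence(mutated, profs)$label, "other_PKSIII")
  }
  # X never satisfies a requirement
  xmut <- ascl
  substr(xmut, diag_pos[1], diag_pos[1]) <- "X"
  expect_equal(classify_sequence(xmut, profs)$label, "other_PKSIII")
  # mutating unannotated positions leaves the label unchanged
  lay <- pks3class:::layout_positions()
  set.seed(4)
  free <- setdiff(seq_len(nchar(ascl)), c(lay, lay + 1, lay - 1))
  for (p in sample(free, 10)) {
    mutated <- ascl
    substr(mutated, p, p) <- "M"
    expect_equal(classify_sequence(mutated, profs)$label, "ASCL")
  }
})

test_that("a sequence satisfying both diagnostic sets is flagged ambiguous", {
  profs <- test_profiles()
  lay <- pks3class:::synthetic_layout()
  both <- profs$ASCL$residues
  for (i in seq_len(nrow(lay$ors)))
    substr(both, lay$ors$position[i], lay$ors$position[i]) <-
      lay$ors$plant[i]
  expect_equal(classify_sequence(both, profs)$label, "ambiguous")
})

test_that("unalignable sequences fall below the alignment floor", {
  profs <- test_profiles()
  junk <- paste(rep("K", 400), collapse = "")
  res <- classify_sequence(junk, profs, align_floor = 0)
  expect_equal(res$label, "not_PKSIII")
})

test_that("PKS domains are extracted from synthetic fusion proteins", {
  profs <- test_profiles()
  set.seed(8)
  ref <- profs$ASCL$residues
  fusion <- data.frame(id = "fus1", description = "",
                       residues = paste0(random_protein(200), ref,
                                         random_protein(180)),
                       is_fusion = TRUE, stringsAsFactors = FALSE)
  dom <- extract_pks_domain(fusion, profs$ASCL)
  expect_match(dom$id, "_pksdomain$")
  expect_true(grepl(ref, dom$residues, fixed = TRUE))
  expect_lte(attr(dom, "domain_start"), 201)
  # domain at the N-terminus: margin clips at position 1
  nterm <- paste0(ref, random_protein(150))
  dom2 <- extract_pks_domain(nterm, profs$ASCL, margin = 10)
  expect_identical(attr(dom2, "domain_start"), 1L)
  # unrelated sequence: no domain
  expect_error(extract_pks_domain(paste(rep("K", 500), collapse = ""),
                                  profs$ASCL), "no PKS domain")
  # the extracted domain classifies like the parent class
  expect_equal(classify_sequence(dom, profs)$label, "ASCL")
})
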