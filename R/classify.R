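# Candidate validation (catalytic triad + signature motif) and ASCL/ORS
# classification via diagnostic residues mapped through pairwise alignment
# onto reference numbering.

#' Default alignment scoring
#'
#' BLOSUM62 with affine gap penalties (open 11, extend 1), the standard
#' protein defaults; a length-k gap costs `open + k * extend`.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`) or a 20 x 20 numeric matrix in [aa_alphabet()] order.
#' @param gap_open,gap_extend Nonnegative gap penalties.
#' @return A scoring configuration list.
#' @export
default_scoring <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend)
}

# resolve the scoring matrix to a numeric matrix over the full Biostrings
# alphabet (for pairwiseAlignment) and the 20-letter model order (for the
# profile aligner)
scoring_matrix <- function(scoring) {
  m <- scoring$matrix
  if (is.character(m)) {
    key <- paste0("submat_", m)
    if (is.null(.pks3_cache[[key]])) {
      env <- new.env()
      utils::data(list = m, package = "Biostrings", envir = env)
      .pks3_cache[[key]] <- env[[m]]
    }
    m <- .pks3_cache[[key]]
  }
  m
}

scoring_matrix20 <- function(scoring) {
  m <- scoring_matrix(scoring)
  aa <- aa_alphabet()
  if (!all(aa %in% rownames(m)))
    stop("substitution matrix must cover the 20 amino acid letters")
  unname(m[aa, aa])
}

#' Globally align a query to a reference profile
#'
#' Needleman-Wunsch global alignment (affine gaps) used to transfer
#' reference residue numbering onto the query.
#'
#' @param query A single-row sequence data.frame (or residue string).
#' @param profile A [reference_profile()].
#' @param scoring Scoring configuration from [default_scoring()].
#' @return Object of class `pairwise_alignment` with the two gapped rows, the
#'   score, and the reference-to-query position map.
#' @export
align_to_reference <- function(query, profile, scoring = default_scoring()) {
  qid <- if (is.data.frame(query)) query$id[1] else "query"
  qres <- if (is.data.frame(query)) query$residues[1] else query
  if (is.null(qres) || is.na(qres) || nchar(qres) == 0)
    stop("query sequence is empty")
  if (nchar(profile$residues) == 0) stop("reference sequence is empty")
  aln <- Biostrings::pairwiseAlignment(
    pattern = qres, subject = profile$residues,
    substitutionMatrix = scoring_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "global")
  qgap <- as.character(Biostrings::alignedPattern(aln))
  rgap <- as.character(Biostrings::alignedSubject(aln))
  new_pairwise_alignment(profile$name, qid, rgap, qgap,
                         Biostrings::score(aln))
}

# construct from gapped rows; derives the strictly increasing position map
new_pairwise_alignment <- function(ref_id, query_id, ref_gapped, query_gapped,
                                   score) {
  if (nchar(ref_gapped) != nchar(query_gapped))
    stop("gapped rows must have equal length")
  rch <- strsplit(ref_gapped, "", fixed = TRUE)[[1]]
  qch <- strsplit(query_gapped, "", fixed = TRUE)[[1]]
  rpos <- cumsum(rch != "-")
  qpos <- cumsum(qch != "-")
  # for each reference position, the query position aligned to it (NA = gap)
  map <- rep(NA_integer_, max(rpos, 0))
  take <- rch != "-" & qch != "-"
  map[rpos[take]] <- qpos[take]
  structure(list(ref_id = ref_id, query_id = query_id,
                 ref_gapped = ref_gapped, query_gapped = query_gapped,
                 score = score, ref_to_query = map),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s, score %.1f, width %d\n",
              x$query_id, x$ref_id, x$score, nchar(x$ref_gapped)))
  invisible(x)
}

#' Map a reference position onto the query
#'
#' Transfers 1-based reference numbering through a pairwise alignment.
#'
#' @param alignment A `pairwise_alignment` from [align_to_reference()].
#' @param ref_pos 1-based reference position.
#' @return The 1-based query position, or `NA` when the reference column
#'   faces a gap in the query.
#' @export
map_position <- function(alignment, ref_pos) {
  n <- length(alignment$ref_to_query)
  if (!is.numeric(ref_pos) || length(ref_pos) != 1 || ref_pos < 1 || ref_pos > n)
    stop(sprintf("reference position %s out of range [1, %d]",
                 format(ref_pos), n))
  alignment$ref_to_query[[as.integer(ref_pos)]]
}

#' Find the (G/A)FGPG signature motif
#'
#' Scans for every (possibly overlapping) occurrence of the type III PKS
#' signature: a 5-mer whose first residue is G or A followed by F, G, P, G.
#'
#' @param seq Residue string.
#' @param pattern Allowed-set list from a profile's motif annotation, or a
#'   pattern string such as `"[GA]FGPG"`.
#' @return Integer vector of 1-based start positions (possibly empty).
#' @export
find_signature_motif <- function(seq, pattern = "[GA]FGPG") {
  sets <- if (is.character(pattern)) parse_motif_pattern(pattern) else pattern
  k <- length(sets)
  n <- nchar(seq)
  if (n < k) return(integer())
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ok <- rep(TRUE, n - k + 1)
  for (j in seq_len(k))
    ok <- ok & ch[seq_len(n - k + 1) + j - 1] %in% sets[[j]]
  which(ok)
}

#' Check the Cys-His-Asn catalytic triad
#'
#' Maps the profile's three annotated triad positions onto the query and
#' verifies the required residues. A position facing a gap counts as
#' unsatisfied; X never satisfies a requirement.
#'
#' @param query Sequence data.frame row or residue string.
#' @param profile A [reference_profile()].
#' @param alignment The query-profile alignment from [align_to_reference()].
#' @return List with `ok` (all three satisfied) and `evidence`, a data.frame
#'   of reference position, required residue, mapped query position and
#'   observed residue.
#' @export
check_triad <- function(query, profile, alignment) {
  qres <- if (is.data.frame(query)) query$residues[1] else query
  ev <- profile$triad
  ev$query_position <- vapply(ev$position, function(p)
    map_position(alignment, p), integer(1))
  ev$observed <- ifelse(is.na(ev$query_position), "-",
                        substring(qres, ev$query_position, ev$query_position))
  ev$satisfied <- !is.na(ev$query_position) & ev$observed == ev$residue
  list(ok = all(ev$satisfied), evidence = ev)
}

# evaluate one class's diagnostic positions through that class's profile
check_diagnostics <- function(qres, profile, alignment) {
  d <- profile$diagnostics
  if (nrow(d) == 0)
    return(cbind(d, query_position = integer(), observed = character(),
                 satisfied = logical()))
  d$query_position <- vapply(d$position, function(p)
    map_position(alignment, p), integer(1))
  d$observed <- ifelse(is.na(d$query_position), "-",
                       substring(qres, d$query_position, d$query_position))
  d$satisfied <- mapply(function(obs, allowed)
    obs %in% strsplit(allowed, "")[[1]], d$observed, d$allowed)
  d
}

#' Classify one sequence against a set of reference profiles
#'
#' Validates type III PKS candidacy (triad + signature motif on the
#' best-scoring profile alignment) and assigns the subfamily label from the
#' class-specific diagnostic residues, each class evaluated through its own
#' reference's numbering.
#'
#' Labels: `not_PKSIII` when the triad fails or the motif is absent (or no
#' profile alignment reaches `align_floor`); `ASCL`/`ORS` when that class's
#' full diagnostic set is satisfied; `ambiguous` when both are; otherwise
#' `other_PKSIII`.
#'
#' @param query Single-row sequence data.frame (or residue string).
#' @param profiles Named list of [reference_profile()]s containing at least
#'   one ASCL- and one ORS-tagged profile.
#' @param scoring Scoring configuration.
#' @param align_floor Minimum acceptable global alignment score; below it the
#'   sequence is `not_PKSIII` with a "no usable alignment" note.
#' @return Object of class `classification_result`.
#' @export
classify_sequence <- function(query, profiles, scoring = default_scoring(),
                              align_floor = 0) {
  if (length(profiles) == 0) stop("no reference profiles supplied")
  classes <- vapply(profiles, `[[`, character(1), "class")
  if (!"ASCL" %in% classes || !"ORS" %in% classes)
    stop("profiles must include at least one ASCL and one ORS reference")
  qid <- if (is.data.frame(query)) query$id[1] else "query"
  qres <- if (is.data.frame(query)) query$residues[1] else query

  alns <- lapply(profiles, function(p) align_to_reference(query, p, scoring))
  scores <- vapply(alns, `[[`, numeric(1), "score")
  best <- which.max(scores)
  note <- NA_character_

  if (scores[best] < align_floor) {
    return(new_classification_result(
      qid, names(profiles)[best], triad = NULL, motif_hits = integer(),
      diagnostics = NULL, label = "not_PKSIII", score = scores[best],
      note = "no usable alignment"))
  }
  triad <- check_triad(qres, profiles[[best]], alns[[best]])
  motif_hits <- find_signature_motif(qres, profiles[[best]]$motif$sets)

  diag_ev <- do.call(rbind, lapply(which(!duplicated(classes) &
                                         classes %in% c("ASCL", "ORS")),
    function(i) {
      # evaluate each class's positions through its own reference alignment
      idx <- which(classes == classes[i])[1]
      check_diagnostics(qres, profiles[[idx]], alns[[idx]])
    }))

  if (!triad$ok || length(motif_hits) == 0) {
    label <- "not_PKSIII"
  } else {
    sat <- vapply(c("ASCL", "ORS"), function(cl) {
      rows <- diag_ev[diag_ev$class == cl, ]
      nrow(rows) > 0 && all(rows$satisfied)
    }, logical(1))
    label <- if (sat[["ASCL"]] && sat[["ORS"]]) "ambiguous"
      else if (sat[["ASCL"]]) "ASCL"
      else if (sat[["ORS"]]) "ORS"
      else "other_PKSIII"
  }
  new_classification_result(qid, names(profiles)[best], triad, motif_hits,
                            diag_ev, label, scores[best], note)
}

new_classification_result <- function(query_id, best_reference, triad,
                                      motif_hits, diagnostics, label, score,
                                      note = NA_character_) {
  structure(list(query_id = query_id, best_reference = best_reference,
                 triad_ok = if (is.null(triad)) FALSE else triad$ok,
                 triad = if (is.null(triad)) NULL else triad$evidence,
                 motif_hits = motif_hits, diagnostics = diagnostics,
                 label = label, score = score, note = note),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s -> %s (best ref %s, score %.1f)\n",
              x$query_id, x$label, x$best_reference, x$score))
  invisible(x)
}

#' Classify every sequence in a set
#'
#' @param records Sequence data.frame from [read_fasta()].
#' @param profiles Named list of reference profiles.
#' @inheritParams classify_sequence
#' @return List of `classification_result`, one per record, in input order.
#' @export
classify_sequences <- function(records, profiles, scoring = default_scoring(),
                               align_floor = 0) {
  lapply(seq_len(nrow(records)), function(i)
    classify_sequence(records[i, ], profiles, scoring, align_floor))
}

#' Tabulate classification results
#'
#' @param results List of `classification_result` objects.
#' @return Data.frame with one row per query: id, label, best reference,
#'   alignment score, triad and motif evidence, per-class diagnostic
#'   evidence (compact `class@refpos>qpos:obs(ok)` strings).
#' @export
classification_table <- function(results) {
  fmt_triad <- function(r) {
    if (is.null(r$triad)) return("")
    paste(sprintf("%s%d>%s:%s%s", r$triad$residue, r$triad$position,
                  ifelse(is.na(r$triad$query_position), "gap",
                         r$triad$query_position),
                  r$triad$observed, ifelse(r$triad$satisfied, "(ok)", "(x)")),
          collapse = ";")
  }
  fmt_diag <- function(r) {
    d <- r$diagnostics
    if (is.null(d) || nrow(d) == 0) return("")
    paste(sprintf("%s@%d>%s:%s%s", d$class, d$position,
                  ifelse(is.na(d$query_position), "gap", d$query_position),
                  d$observed, ifelse(d$satisfied, "(ok)", "(x)")),
          collapse = ";")
  }
  data.frame(
    id = vapply(results, `[[`, character(1), "query_id"),
    label = vapply(results, `[[`, character(1), "label"),
    best_reference = vapply(results, `[[`, character(1), "best_reference"),
    score = vapply(results, `[[`, numeric(1), "score"),
    triad_ok = vapply(results, `[[`, logical(1), "triad_ok"),
    triad = vapply(results, fmt_triad, character(1)),
    motif_positions = vapply(results, function(r)
      paste(r$motif_hits, collapse = ","), character(1)),
    diagnostics = vapply(results, fmt_diag, character(1)),
    note = vapply(results, function(r)
      if (is.na(r$note)) "" else r$note, character(1)),
    stringsAsFactors = FALSE)
}

#' Extract the type III PKS domain from a fusion protein
#'
#' Locally aligns the reference to the (longer) query and returns the query
#' segment covered by the best local alignment, padded by a margin and
#' clipped to the sequence bounds. Intended for fusion proteins in which a
#' PKS domain is embedded among unrelated domains.
#'
#' @param fusion Single-row sequence data.frame (or residue string).
#' @param profile A [reference_profile()].
#' @param margin Residues of padding on each side of the matched segment.
#' @param floor Minimum local alignment score below which no domain is
#'   deemed present.
#' @param scoring Scoring configuration.
#' @return A one-row sequence data.frame whose id carries a `_pksdomain`
#'   suffix, with attributes `domain_start`/`domain_end` (1-based, on the
#'   input sequence).
#' @export
extract_pks_domain <- function(fusion, profile, margin = 10, floor = 100,
                               scoring = default_scoring()) {
  qid <- if (is.data.frame(fusion)) fusion$id[1] else "query"
  qres <- if (is.data.frame(fusion)) fusion$residues[1] else fusion
  if (nchar(qres) == 0) stop("query sequence is empty")
  aln <- Biostrings::pairwiseAlignment(
    pattern = profile$residues, subject = qres,
    substitutionMatrix = scoring_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "local")
  if (Biostrings::score(aln) < floor)
    stop(sprintf("no PKS domain found in '%s' (local score %.1f below floor %.1f)",
                 qid, Biostrings::score(aln), floor))
  s <- max(1L, Biostrings::start(Biostrings::subject(aln)) - as.integer(margin))
  e <- min(nchar(qres), Biostrings::end(Biostrings::subject(aln)) +
             as.integer(margin))
  out <- data.frame(id = paste0(qid, "_pksdomain"), description = "",
                    residues = substr(qres, s, e), is_fusion = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "domain_start") <- s
  attr(out, "domain_end") <- e
  out
}
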