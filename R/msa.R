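# Multiple sequence alignment: a self-contained progressive aligner (k-mer
# guide tree + profile-profile alignment) and validated import of externally
# computed alignments. The in-house aligner is a deliberate simplification
# of iterative refiners such as MUSCLE; for maximum fidelity an external MSA
# can be supplied via import_alignment().

#' Construct a multiple alignment object
#'
#' @param rows Named character vector of gapped residue strings (equal
#'   lengths, unique names).
#' @return Object of class `pks_msa` (a named character vector).
#' @export
new_msa <- function(rows) {
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named by sequence id")
  if (anyDuplicated(names(rows)))
    stop(sprintf("duplicate id(s) in alignment: %s",
                 paste(unique(names(rows)[duplicated(names(rows))]),
                       collapse = ", ")))
  w <- nchar(rows)
  if (length(unique(w)) > 1)
    stop("ragged alignment: row lengths differ")
  structure(rows, class = "pks_msa")
}

as_msa <- function(x) {
  if (inherits(x, "pks_msa")) x else new_msa(x)
}

#' @export
print.pks_msa <- function(x, ...) {
  cat(sprintf("<pks_msa> %d sequences, width %d\n", length(x),
              if (length(x)) nchar(x[[1]]) else 0))
  invisible(x)
}

#' Remove gaps from alignment rows
#'
#' @param x A `pks_msa` or character vector of gapped strings.
#' @return Character vector of ungapped sequences (names preserved).
#' @export
degap <- function(x) {
  out <- gsub("-", "", unclass(x), fixed = TRUE)
  names(out) <- names(x)
  out
}

#' k-mer distance between two protein sequences
#'
#' One minus the number of distinct shared k-mers divided by the smaller
#' distinct k-mer count; a cheap guide-tree distance in [0, 1].
#'
#' @param a,b Residue strings (or single-row sequence data.frames).
#' @param k Word length.
#' @return Numeric distance in `[0, 1]`, symmetric.
#' @export
kmer_distance <- function(a, b, k = 3) {
  sa <- if (is.data.frame(a)) a$residues[1] else a
  sb <- if (is.data.frame(b)) b$residues[1] else b
  if (nchar(sa) < k || nchar(sb) < k)
    stop(sprintf("sequences must be at least k = %d residues long", k))
  ka <- unique(substring(sa, seq_len(nchar(sa) - k + 1),
                         seq_len(nchar(sa) - k + 1) + k - 1))
  kb <- unique(substring(sb, seq_len(nchar(sb) - k + 1),
                         seq_len(nchar(sb) - k + 1) + k - 1))
  1 - length(intersect(ka, kb)) / min(length(ka), length(kb))
}

# 20 x width residue-frequency profile of a set of gapped rows
profile_freqs <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  w <- ncol(mat)
  out <- matrix(0, 20, w)
  aa <- aa_alphabet()
  n <- nrow(mat)
  for (j in seq_len(w)) {
    tab <- tabulate(match(mat[, j], aa), nbins = 20)
    out[, j] <- tab / n
  }
  out
}

# merge two sub-alignments along a profile-profile alignment path
merge_profiles <- function(rows_a, rows_b, path_a, path_b) {
  expand <- function(rows, path) {
    ch <- strsplit(rows, "", fixed = TRUE)
    vapply(ch, function(v) {
      paste(ifelse(path == 0, "-", v[pmax(path, 1)]), collapse = "")
    }, character(1))
  }
  c(expand(rows_a, path_a), expand(rows_b, path_b))
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by neighbor-joining on pairwise [kmer_distance()]s
#' (midpoint-rooted), then aligns profiles up the tree with affine-gap
#' profile-profile alignment under the configured scoring. Deterministic.
#'
#' @param records Sequence data.frame from [read_fasta()] (or a named
#'   character vector of residue strings); at least two sequences.
#' @param scoring Scoring configuration from [default_scoring()].
#' @param k Guide-tree word length.
#' @return A `pks_msa`, rows in input order, with attribute `score` (the
#'   final profile-profile alignment score).
#' @export
progressive_align <- function(records, scoring = default_scoring(), k = 3) {
  if (is.data.frame(records)) {
    seqs <- setNames(records$residues, records$id)
  } else seqs <- records
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences to align")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids")
  S <- scoring_matrix20(scoring)

  align_pair <- function(rows_a, rows_b) {
    res <- profile_align_cpp(profile_freqs(rows_a), profile_freqs(rows_b), S,
                             scoring$gap_open, scoring$gap_extend)
    list(rows = merge_profiles(rows_a, rows_b, res$path_a, res$path_b),
         score = res$score)
  }

  if (n == 2) {
    res <- align_pair(seqs[1], seqs[2])
    out <- new_msa(res$rows[names(seqs)])
    attr(out, "score") <- res$score
    return(out)
  }

  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      D[i, j] <- D[j, i] <- kmer_distance(seqs[[i]], seqs[[j]], k)
  guide <- phangorn::midpoint(ape::nj(stats::as.dist(D)))

  score_last <- NA_real_
  align_node <- function(node) {
    tips <- names(seqs)
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    if (length(kids) == 0)
      return(seqs[guide$tip.label[node]])
    prof <- align_node(kids[1])
    for (kid in kids[-1]) {
      res <- align_pair(prof, align_node(kid))
      prof <- res$rows
      score_last <<- res$score
    }
    prof
  }
  root <- length(guide$tip.label) + 1L
  rows <- align_node(root)
  out <- new_msa(rows[names(seqs)])
  attr(out, "score") <- score_last
  out
}

#' Import an externally computed alignment
#'
#' Reads an aligned-FASTA file (gap character `-`), validating equal row
#' lengths, unique ids and the amino acid alphabet.
#'
#' @param path Path to an aligned FASTA file.
#' @return A `pks_msa`.
#' @export
import_alignment <- function(path) {
  if (!file.exists(path)) stop(sprintf("alignment file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop(sprintf("empty alignment file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate id(s) in alignment: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  rows <- toupper(as.character(set))
  names(rows) <- ids
  for (i in seq_along(rows)) {
    bad <- regexpr(sprintf("[^-%s]", paste(.aa_valid(), collapse = "")),
                   rows[[i]])
    if (bad > 0)
      stop(sprintf("illegal character '%s' in aligned row '%s' at column %d",
                   substr(rows[[i]], bad, bad), ids[i], bad))
  }
  new_msa(rows)
}

#' Write an alignment as aligned FASTA
#'
#' @param msa A `pks_msa`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_alignment <- function(msa, path) {
  msa <- as_msa(msa)
  write_fasta(data.frame(id = names(msa), residues = unclass(unname(msa)),
                         stringsAsFactors = FALSE), path)
  invisible(path)
}
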