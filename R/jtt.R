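# JTT amino acid substitution model: the published Jones-Taylor-Thornton
# (1992) exchangeability counts (lower triangle, PAML residue order
# ARNDCQEGHILKMFPSTWYV) and equilibrium frequencies.

#' Amino acid alphabet in model order
#'
#' The twenty standard amino acid one-letter codes in the residue order used
#' by the JTT rate matrix (A R N D C Q E G H I L K M F P S T W Y V).
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

.jtt_lower_triangle <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
  126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
  8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46,
  31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26,
  597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
  16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40,
  245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47,
  103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62,
  285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)

.jtt_freqs <- c(
  0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
  0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
  0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005)

#' JTT equilibrium amino acid frequencies
#'
#' @return Named numeric vector of length 20 (names in [aa_alphabet()] order),
#'   normalized to sum to one.
#' @export
jtt_frequencies <- function() {
  f <- .jtt_freqs / sum(.jtt_freqs)
  names(f) <- aa_alphabet()
  f
}

# Instantaneous rate matrix Q, scaled so the expected substitution rate at
# equilibrium is one (branch lengths in substitutions/site).
jtt_rate_matrix <- function() {
  if (!is.null(.pks3_cache$Q)) return(.pks3_cache$Q)
  S <- matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  S[lower.tri(S)] <- .jtt_lower_triangle
  S <- S + t(S)
  pi <- jtt_frequencies()
  Q <- S * rep(pi, each = 20)   # Q_ij = s_ij * pi_j for i != j
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(pi * diag(Q))
  .pks3_cache$Q <- Q
  Q
}

# Eigendecomposition of the symmetrized Q for fast P(t); cached.
jtt_eigen <- function() {
  if (!is.null(.pks3_cache$eig)) return(.pks3_cache$eig)
  Q <- jtt_rate_matrix()
  pi <- jtt_frequencies()
  d <- sqrt(pi)
  A <- diag(d) %*% Q %*% diag(1 / d)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  eig <- list(U = diag(1 / d) %*% e$vectors,
              lambda = e$values,
              W = t(e$vectors) %*% diag(d),
              pi = unname(pi))
  .pks3_cache$eig <- eig
  eig
}

#' JTT transition probability matrix
#'
#' Probability `P[a, b]` of observing residue `b` at a site that started as
#' residue `a` after `t` expected substitutions/site under the JTT model.
#'
#' @param t Nonnegative divergence in substitutions/site.
#' @return 20 x 20 row-stochastic matrix in [aa_alphabet()] order.
#' @export
jtt_prob_matrix <- function(t) {
  stopifnot(is.numeric(t), length(t) == 1, t >= 0)
  e <- jtt_eigen()
  P <- e$U %*% diag(exp(e$lambda * t)) %*% e$W
  dimnames(P) <- list(aa_alphabet(), aa_alphabet())
  P
}

# Encode residue strings to 0-based model indices; gaps, X and anything
# outside the 20-letter alphabet become -1 (ignored in distances).
encode_residues <- function(x) {
  idx <- match(strsplit(x, "", fixed = TRUE)[[1]], aa_alphabet())
  idx[is.na(idx)] <- 0L
  idx - 1L
}

#' Maximum likelihood JTT distance between two aligned sequences
#'
#' Estimates the evolutionary distance (expected substitutions/site) between
#' two rows of an alignment by maximizing the JTT likelihood of the aligned
#' residue pairs over divergence time. Columns in which either row carries a
#' gap or an unknown residue (X) are dropped (pairwise deletion).
#'
#' @param row_a,row_b Gapped residue strings of equal length.
#' @param cap Saturation cap in substitutions/site; estimates at the cap are
#'   flagged saturated (attribute `saturated`).
#' @return Numeric distance with logical attribute `saturated`.
#' @export
jtt_distance <- function(row_a, row_b, cap = 10) {
  stopifnot(is.character(row_a), is.character(row_b),
            length(row_a) == 1, length(row_b) == 1)
  if (nchar(row_a) != nchar(row_b))
    stop("aligned rows must have equal length")
  a <- encode_residues(row_a)
  b <- encode_residues(row_b)
  keep <- a >= 0 & b >= 0
  if (!any(keep))
    stop("no shared gap-free columns between the two rows")
  N <- matrix(0, 20, 20)
  tab <- table(factor(a[keep], levels = 0:19), factor(b[keep], levels = 0:19))
  N[] <- as.numeric(tab)
  e <- jtt_eigen()
  res <- jtt_pair_mle_cpp(N, e$U, e$lambda, e$W, e$pi, cap)
  structure(res$distance, saturated = res$saturated)
}

#' JTT distance matrix from a multiple alignment
#'
#' Applies [jtt_distance()] to every pair of rows of a multiple alignment
#' (pairwise deletion of gapped columns).
#'
#' @param msa A [new_msa()] alignment (or named character vector of equal
#'   length gapped strings).
#' @param cap Saturation cap passed to [jtt_distance()].
#' @return Symmetric numeric matrix with zero diagonal, taxon ids as
#'   dimnames, and a logical `saturated` attribute matrix.
#' @export
build_distance_matrix <- function(msa, cap = 10) {
  msa <- as_msa(msa)
  ids <- names(msa)
  if (length(ids) < 3)
    stop("need at least 3 taxa to build a distance matrix")
  enc <- do.call(rbind, lapply(unname(msa), encode_residues))
  e <- jtt_eigen()
  res <- jtt_dist_matrix_cpp(enc, e$U, e$lambda, e$W, e$pi, cap)
  D <- res$distance
  if (anyNA(D)) {
    bad <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)[1, ]
    stop(sprintf("no shared gap-free columns between '%s' and '%s'",
                 ids[bad[1]], ids[bad[2]]))
  }
  dimnames(D) <- list(ids, ids)
  sat <- res$saturated
  dimnames(sat) <- dimnames(D)
  structure(D, saturated = sat)
}
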