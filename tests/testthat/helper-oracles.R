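# Independent oracle implementations used to verify the package's
# algorithms, deliberately written as brute force / enumeration.

# brute-force motif scan: test every window against the allowed sets
brute_motif_scan <- function(seq, pattern = "[GA]FGPG") {
  first <- c("G", "A")
  tail <- c("F", "G", "P", "G")
  n <- nchar(seq)
  hits <- integer()
  for (i in seq_len(max(n - 4, 0))) {
    w <- strsplit(substr(seq, i, i + 4), "")[[1]]
    if (w[1] %in% first && all(w[2:5] == tail)) hits <- c(hits, i)
  }
  hits
}

# exhaustive global alignment score by recursive enumeration of edit paths
# with affine gaps (length-k gap costs open + k*extend); only feasible for
# very short strings
exhaustive_align_score <- function(a, b, submat, gap_open, gap_extend) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(ac) && j > length(bc)) return(0)
    best <- -Inf
    if (i <= length(ac) && j <= length(bc))
      best <- max(best, submat[ac[i], bc[j]] + rec(i + 1, j + 1, "m"))
    if (i <= length(ac)) {
      pen <- gap_extend + if (state == "ga") 0 else gap_open
      best <- max(best, -pen + rec(i + 1, j, "ga"))
    }
    if (j <= length(bc)) {
      pen <- gap_extend + if (state == "gb") 0 else gap_open
      best <- max(best, -pen + rec(i, j + 1, "gb"))
    }
    best
  }
  rec(1, 1, "m")
}

# likelihood grid search for the JTT pairwise distance; transition
# probabilities via series matrix exponential (Matrix::expm-free, plain
# scaling and squaring), independent of the package's eigendecomposition
oracle_expm <- function(Q, t) {
  A <- Q * t
  s <- max(0, ceiling(log2(max(1, max(abs(A))) * 4)))
  A <- A / 2^s
  P <- diag(20)
  term <- diag(20)
  for (k in 1:12) {
    term <- term %*% A / k
    P <- P + term
  }
  for (k in seq_len(s)) P <- P %*% P
  P
}

jtt_grid_oracle <- function(row_a, row_b, lo = 1e-4, hi = 2, step = 1e-4) {
  Q <- pks3class:::jtt_rate_matrix()
  pi <- jtt_frequencies()
  aa <- aa_alphabet()
  a <- strsplit(row_a, "")[[1]]
  b <- strsplit(row_b, "")[[1]]
  keep <- a %in% aa & b %in% aa
  a <- a[keep]; b <- b[keep]
  ll <- function(t) {
    P <- oracle_expm(Q, t)
    dimnames(P) <- list(aa, aa)
    sum(log(pi[a] * P[cbind(a, b)]))
  }
  # coarse grid then fine grid around the maximum
  coarse <- seq(lo, hi, by = 100 * step)
  t0 <- coarse[which.max(vapply(coarse, ll, numeric(1)))]
  fine <- seq(max(lo, t0 - 120 * step), t0 + 120 * step, by = step)
  fine[which.max(vapply(fine, ll, numeric(1)))]
}

# brute-force maximal clade count: test every node's full tip set
brute_maximal_clades <- function(tree, satisfies) {
  tips <- tree$tip.label
  nn <- length(tips) + tree$Nnode
  tipsets <- lapply(seq_len(nn), function(node) {
    if (node <= length(tips)) return(tips[node])
    tips[phangorn::Descendants(tree, node, "tips")[[1]]]
  })
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  ok <- vapply(tipsets, function(s) all(satisfies[s]), logical(1))
  sum(vapply(seq_len(nn), function(node)
    ok[node] && (is.na(parent[node]) || !ok[parent[node]]), logical(1)))
}

# least-squares tree fit over all topologies (<= 6 taxa)
exhaustive_ls_topology <- function(D) {
  ids <- rownames(D)
  best <- NULL
  best_val <- Inf
  tops <- phangorn::allTrees(length(ids), rooted = FALSE, tip.label = ids)
  for (k in seq_along(tops)) {
    # index via [[ so multiPhylo re-attaches its compressed tip labels
    fit <- phangorn::nnls.tree(D, tops[[k]], method = "unrooted")
    pd <- ape::cophenetic.phylo(fit)[ids, ids]
    val <- sum((pd - D)[upper.tri(D)]^2)
    if (val < best_val) {
      best_val <- val
      best <- fit
    }
  }
  best
}

random_protein <- function(n, alphabet = aa_alphabet()) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small standard profile set used across tests
test_profiles <- function(seed = 42) {
  make_reference_scaffolds(synthetic_family_spec(seed = seed))
}
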