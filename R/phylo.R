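# Tree building: neighbor-joining on JTT distances, nonparametric bootstrap
# support, outgroup rooting, optional least-squares NNI refinement, Newick
# output. Trees are ape "phylo" objects; internal node labels carry integer
# bootstrap percentages.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape) with input validation and negative
#' branch lengths clamped to zero (total clamped length reported in the
#' `clamped` attribute).
#'
#' @param D Symmetric numeric distance matrix with taxon ids as dimnames.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (anyNA(D) || any(!is.finite(D)))
    stop("distance matrix contains NA/NaN/Inf entries")
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix is not symmetric")
  if (nrow(D) < 3) stop("need at least 3 taxa")
  if (is.null(rownames(D)))
    stop("distance matrix must carry taxon ids as dimnames")
  tree <- ape::nj(stats::as.dist(D))
  clamped <- -sum(tree$edge.length[tree$edge.length < 0])
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

# canonical bipartition keys of the internal edges of an unrooted tree:
# each key is the sorted tip set on the side not containing the first taxon
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, type = "tips")
  root <- ntip + 1L
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(ntip))
  keys <- vapply(internal, function(node) {
    tips <- tree$tip.label[desc[[node]]]
    if (tree$tip.label[1] %in% tips)
      tips <- setdiff(tree$tip.label, tips)
    paste(sort(tips), collapse = "\r")
  }, character(1))
  names(keys) <- as.character(internal)
  # drop trivial splits (all-but-one taxon)
  keys[vapply(strsplit(keys, "\r"), function(s)
    length(s) >= 2 && length(s) <= ntip - 2, logical(1))]
}

# derived per-replicate seed below 2^31
replicate_seed <- function(seed, r) {
  (as.numeric(seed) * 48271 + r * 16807) %% 2147483647
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Builds the point-estimate NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilding JTT
#' distances and the NJ tree per replicate. Support for each internal edge
#' of the point tree is the percentage of replicate trees containing the
#' same bipartition, stored as integer node labels.
#'
#' @param msa A `pks_msa`.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; replicate r draws from a stream derived from
#'   (seed, r), so results are reproducible.
#' @param cap Saturation cap for [jtt_distance()].
#' @return The point-estimate unrooted `phylo` with `node.label` supports
#'   (empty label at the root).
#' @export
bootstrap_support <- function(msa, n_reps, seed = 1, cap = 10) {
  msa <- as_msa(msa)
  if (n_reps < 1) stop("n_reps must be at least 1")
  point <- nj_tree(build_distance_matrix(msa, cap = cap))
  keys <- tree_bipartitions(point)
  counts <- setNames(rep(0, length(keys)), keys)
  width <- nchar(msa[[1]])
  rows <- unclass(msa)
  for (r in seq_len(n_reps)) {
    set.seed(replicate_seed(seed, r))
    cols <- sample.int(width, width, replace = TRUE)
    rep_rows <- vapply(rows, function(s)
      paste(strsplit(s, "", fixed = TRUE)[[1]][cols], collapse = ""),
      character(1))
    rep_tree <- try(nj_tree(build_distance_matrix(new_msa(rep_rows),
                                                  cap = cap)), silent = TRUE)
    if (inherits(rep_tree, "try-error")) next
    rep_keys <- tree_bipartitions(rep_tree)
    hit <- keys %in% rep_keys
    counts[hit] <- counts[hit] + 1
  }
  support <- round(100 * counts / n_reps)
  ntip <- length(point$tip.label)
  nnode <- point$Nnode
  labels <- rep("", nnode)
  idx <- as.integer(names(keys)) - ntip
  labels[idx] <- as.character(as.integer(support))
  point$node.label <- labels
  point
}

#' Root a tree on a designated outgroup
#'
#' Places the root at the midpoint of the branch subtending the outgroup
#' leaf; bootstrap supports move with their edges.
#'
#' @param tree A `phylo` (typically with node-label supports).
#' @param outgroup_id Tip label of the outgroup.
#' @return Rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_id) {
  if (!outgroup_id %in% tree$tip.label)
    stop(sprintf("outgroup '%s' is not a leaf of the tree", outgroup_id))
  has_labels <- !is.null(tree$node.label)
  rooted <- ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE,
                      edgelabel = has_labels)
  if (!is.null(rooted$edge.length)) {
    root <- length(rooted$tip.label) + 1L
    kids <- which(rooted$edge[, 1] == root)
    if (length(kids) == 2) {
      total <- sum(rooted$edge.length[kids])
      rooted$edge.length[kids] <- total / 2
    }
  }
  rooted
}

# weighted least-squares fit of a topology to a distance matrix:
# branch lengths by nonnegative least squares, criterion = sum of squared
# residuals between path lengths and D
lsq_criterion <- function(tree, D) {
  fit <- phangorn::nnls.tree(D, tree, method = "unrooted")
  pd <- ape::cophenetic.phylo(fit)
  ids <- rownames(D)
  resid <- pd[ids, ids] - D
  list(tree = fit, value = sum(resid[upper.tri(resid)]^2))
}

#' Nearest-neighbor-interchange refinement under least squares
#'
#' Hill-climbs over NNI rearrangements of an unrooted tree, accepting a move
#' only when it lowers the least-squares misfit between the tree's path
#' lengths (nonnegative branch lengths refit per topology) and the distance
#' matrix. The criterion never increases.
#'
#' @param tree Unrooted `phylo` with >= 4 leaves.
#' @param D Distance matrix over the tree's tips.
#' @return Refined unrooted `phylo` with attribute `lsq` (final criterion).
#' @export
nni_refine <- function(tree, D) {
  D <- as.matrix(D)
  if (length(tree$tip.label) < 4) {
    cur <- lsq_criterion(tree, D)
    out <- cur$tree
    attr(out, "lsq") <- cur$value
    return(out)
  }
  cur <- lsq_criterion(tree, D)
  repeat {
    nbrs <- phangorn::nni(cur$tree)
    improved <- FALSE
    for (k in seq_along(nbrs)) {
      cand <- lsq_criterion(nbrs[[k]], D)
      if (cand$value < cur$value - 1e-12) {
        cur <- cand
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  out <- cur$tree
  attr(out, "lsq") <- cur$value
  out
}

#' Write a tree in Newick format
#'
#' Branch lengths are substitutions/site; bootstrap supports are internal
#' node labels; labels containing punctuation are quoted by ape.
#'
#' @param tree A `phylo`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return A `phylo`.
#' @export
read_tree_newick <- function(path) {
  if (!file.exists(path)) stop(sprintf("tree file not found: %s", path))
  ape::read.tree(path)
}

#' Write a distance matrix as a square tab-separated table
#'
#' PHYLIP-style: first line the taxon count, then one row per taxon with its
#' id and distances.
#'
#' @param D Distance matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  D <- as.matrix(D)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(c(rownames(D)[i], formatC(D[i, ], format = "g",
                                               digits = 10)),
                     collapse = "\t"), con)
  invisible(path)
}
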