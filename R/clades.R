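# Interpretation of the rooted tree: monophyly, clade assignment of queries
# relative to labeled references, maximal-clade counting, and concordance
# between residue-based labels and tree placement.

# tip labels under each node (index = node number)
node_tip_sets <- function(tree) {
  desc <- phangorn::Descendants(tree, type = "tips")
  lapply(desc, function(i) tree$tip.label[i])
}

#' Test a tip set for monophyly
#'
#' True iff some node of the rooted tree has exactly `tip_set` as its
#' descendant leaves (singletons are monophyletic by convention).
#'
#' @param tree Rooted `phylo`.
#' @param tip_set Character vector of tip labels.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, tip_set) {
  missing <- setdiff(tip_set, tree$tip.label)
  if (length(missing))
    stop(sprintf("tip(s) not in tree: %s", paste(missing, collapse = ", ")))
  if (length(tip_set) == 1) return(TRUE)
  want <- sort(unique(tip_set))
  sets <- node_tip_sets(tree)
  any(vapply(sets, function(s)
    length(s) == length(want) && all(sort(s) == want), logical(1)))
}

#' Assign a query tip to a reference-labeled clade
#'
#' Walks from the query toward the root; the first ancestor containing at
#' least one labeled reference decides: if all references it contains share
#' one class, the query gets that class, otherwise it is `"unplaced"`.
#' Queries themselves never vote, so placement mirrors dropping an unknown
#' into a labeled tree.
#'
#' @param tree Rooted `phylo`.
#' @param query_id Tip label of the query.
#' @param reference_labels Named character vector, reference tip id -> class.
#' @return Class label or `"unplaced"`.
#' @export
assign_query_to_clade <- function(tree, query_id, reference_labels) {
  if (!query_id %in% tree$tip.label)
    stop(sprintf("query '%s' is not a leaf of the tree", query_id))
  refs <- reference_labels[names(reference_labels) %in% tree$tip.label]
  refs <- refs[names(refs) != query_id]
  if (length(refs) == 0) return("unplaced")
  sets <- node_tip_sets(tree)
  tip <- match(query_id, tree$tip.label)
  node <- tree$edge[tree$edge[, 2] == tip, 1]
  repeat {
    present <- refs[names(refs) %in% sets[[node]]]
    if (length(present) > 0) {
      cls <- unique(present)
      return(if (length(cls) == 1) cls else "unplaced")
    }
    up <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(up) == 0) return("unplaced")
    node <- up
  }
}

#' Count maximal clades satisfying a predicate
#'
#' A node is counted when every leaf below it satisfies the predicate and no
#' counted node is an ancestor of another (i.e. its parent has at least one
#' non-satisfying leaf). Singleton leaves count as clades.
#'
#' @param tree Rooted `phylo`.
#' @param satisfies Either a named logical vector over all tip labels, or a
#'   function applied to each tip label.
#' @return Integer count.
#' @export
count_maximal_clades <- function(tree, satisfies) {
  tips <- tree$tip.label
  if (is.function(satisfies))
    satisfies <- setNames(vapply(tips, satisfies, logical(1)), tips)
  missing <- setdiff(tips, names(satisfies))
  if (length(missing))
    stop(sprintf("no metadata for leaf '%s'", missing[1]))
  if (anyNA(satisfies[tips]))
    stop(sprintf("no metadata for leaf '%s'",
                 tips[which(is.na(satisfies[tips]))[1]]))
  sat <- unname(satisfies[tips])
  ntip <- length(tips)
  nnode <- tree$Nnode
  all_ok <- c(sat, rep(NA, nnode))
  # postorder: children before parents
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; child <- edges[k, 2]
    if (is.na(all_ok[par])) all_ok[par] <- TRUE
    all_ok[par] <- all_ok[par] && all_ok[child]
  }
  parent <- rep(NA_integer_, ntip + nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  count <- 0L
  for (node in seq_len(ntip + nnode)) {
    if (isTRUE(all_ok[node]) &&
        (is.na(parent[node]) || !isTRUE(all_ok[parent[node]])))
      count <- count + 1L
  }
  count
}

#' Concordance between residue classification and tree placement
#'
#' For every classified query that is a leaf of the tree, compares its
#' residue-based label with its clade assignment relative to the labeled
#' references. A query is concordant when the two labels agree, or when its
#' residue label has no reference class in the tree and it is unplaced.
#'
#' @param classifications List of `classification_result` (or a
#'   [classification_table()] data.frame).
#' @param tree Rooted `phylo` whose leaves include the classified ids.
#' @param reference_labels Named character vector, reference tip id -> class.
#' @return Object of class `clade_report`: per-query assignment table,
#'   per-class summary counts, monophyly verdicts for each reference class
#'   and for each full label set, and per-class maximal clade counts.
#' @export
concordance_report <- function(classifications, tree, reference_labels) {
  tab <- if (is.data.frame(classifications)) classifications
         else classification_table(classifications)
  tab <- tab[, c("id", "label")]
  missing <- setdiff(tab$id, tree$tip.label)
  if (length(missing))
    stop(sprintf("classified id(s) missing from tree: %s",
                 paste(missing, collapse = ", ")))
  ref_classes <- unique(unname(reference_labels))
  assignments <- data.frame(id = character(), residue_label = character(),
                            clade_label = character(), concordant = logical(),
                            stringsAsFactors = FALSE)
  if (nrow(tab)) {
    clade <- vapply(tab$id, function(q)
      assign_query_to_clade(tree, q, reference_labels), character(1))
    concordant <- clade == tab$label |
      (!tab$label %in% ref_classes & clade == "unplaced")
    assignments <- data.frame(id = tab$id, residue_label = tab$label,
                              clade_label = unname(clade),
                              concordant = unname(concordant),
                              stringsAsFactors = FALSE)
  }
  # labels over all leaves: references by their class, queries by residue label
  leaf_label <- setNames(rep(NA_character_, length(tree$tip.label)),
                         tree$tip.label)
  leaf_label[names(reference_labels)[names(reference_labels) %in%
                                       tree$tip.label]] <-
    reference_labels[names(reference_labels) %in% tree$tip.label]
  leaf_label[assignments$id] <- assignments$residue_label
  monophyly <- vapply(ref_classes, function(cl) {
    ids <- names(reference_labels)[reference_labels == cl]
    ids <- intersect(ids, tree$tip.label)
    length(ids) > 0 && is_monophyletic(tree, ids)
  }, logical(1))
  classes_present <- sort(unique(stats::na.omit(leaf_label)))
  maximal <- vapply(classes_present, function(cl)
    count_maximal_clades(tree, !is.na(leaf_label) & leaf_label == cl),
    integer(1))
  summary <- do.call(rbind, lapply(classes_present, function(cl) {
    data.frame(class = cl,
               n_residue = sum(assignments$residue_label == cl),
               n_clade = sum(assignments$clade_label == cl),
               n_concordant = sum(assignments$concordant &
                                    assignments$residue_label == cl),
               maximal_clades = maximal[[cl]],
               stringsAsFactors = FALSE)
  }))
  structure(list(assignments = assignments, summary = summary,
                 monophyly = monophyly,
                 concordance = if (nrow(assignments))
                   mean(assignments$concordant) * 100 else NA_real_),
            class = "clade_report")
}

#' @export
print.clade_report <- function(x, ...) {
  cat(sprintf("<clade_report> %d queries, %.1f%% concordant\n",
              nrow(x$assignments), x$concordance))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Write a clade report as JSON and a tab-separated summary
#'
#' @param report A `clade_report`.
#' @param json_path,tsv_path Output paths (either may be NULL to skip).
#' @return Invisibly, the written paths.
#' @export
write_clade_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(assignments = report$assignments, summary = report$summary,
           monophyly = as.list(report$monophyly),
           concordance = report$concordance),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(tsv_path))
    write.table(report$assignments, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(json_path, tsv_path))
}
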