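# Seeded generator for labeled type III PKS-like protein families: scaffolds
# with a planted Cys-His-Asn triad, (G/A)FGPG signature and class-specific
# diagnostic residues, diverged along random trees under the JTT model with
# optional indels, with truth labels and remapped annotation coordinates.

# canonical coordinate layout of the synthetic scaffolds; triad positions
# follow the classic chalcone synthase numbering (C164/H303/N336), the
# signature sits near the C-terminus, diagnostic coordinates mirror the
# PpASCL (G225, A/V240) and PpORS (Q218, V/A277, A286) conventions
synthetic_layout <- function() {
  list(
    triad = data.frame(position = c(164L, 303L, 336L),
                       residue = c("C", "H", "N"), stringsAsFactors = FALSE),
    motif_start = 372L,
    motif_pattern = "[GA]FGPG",
    ascl = data.frame(position = c(225L, 240L), allowed = c("G", "AV"),
                      plant = c("G", "A"), anti = c("D", "T"),
                      stringsAsFactors = FALSE),
    ors = data.frame(position = c(218L, 277L, 286L),
                     allowed = c("Q", "VA", "A"), plant = c("Q", "V", "A"),
                     anti = c("L", "T", "S"), stringsAsFactors = FALSE))
}

layout_positions <- function(layout = synthetic_layout()) {
  sort(unique(c(layout$triad$position,
                layout$motif_start + 0:4,
                layout$ascl$position, layout$ors$position)))
}

#' Specify a synthetic protein family set
#'
#' Bundles the generator parameters: per-class sequence counts, scaffold
#' length, tree height (root-to-tip, expected substitutions/site), indel
#' process, fusion decoration and seed. All randomness derives from the
#' seed.
#'
#' @param n_per_class Named integer vector over the classes ASCL, ORS,
#'   other_PKSIII, not_PKSIII.
#' @param scaffold_length Ungapped scaffold length (default 400 aa, typical
#'   of type III PKSs).
#' @param tree_height Within-family root-to-tip height in expected
#'   substitutions/site.
#' @param stem_length Divergence between a class scaffold and its family
#'   root (backbone separation of the clades).
#' @param indel_rate Indel events per site per substitution/site of branch
#'   length.
#' @param indel_mean_length Mean indel tract length (geometric).
#' @param indel_buffer Indels are kept at least this many residues away from
#'   planted positions when diagnostics are preserved.
#' @param fusion_fraction Fraction of sequences decorated with unrelated
#'   flanking domains (marked `is_fusion`).
#' @param flank_mean Mean flank length for fusion decoration.
#' @param ref_divergence Divergence (substitutions/site) between the shared
#'   background and each class reference scaffold, so the ASCL, ORS and
#'   generic references are distinct homologs rather than near-duplicates
#'   (no indels, keeping annotation coordinates canonical).
#' @param preserve_diagnostics Hold every annotated layout position
#'   invariant during evolution, so truth labels stay valid.
#' @param outgroup Include a single highly diverged outgroup sequence
#'   (its own scaffold evolved `outgroup_divergence` from the base), as a
#'   distantly related rooting taxon.
#' @param outgroup_divergence Branch length to the outgroup scaffold.
#' @param taxa Optional data.frame (`id`, `species`, `lineage_group`,
#'   `expected_class`, `family`) fixing the composition; when NULL it is
#'   built from `n_per_class`.
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `synthetic_family_spec`.
#' @export
synthetic_family_spec <- function(
    n_per_class = c(ASCL = 3, ORS = 3, other_PKSIII = 3, not_PKSIII = 1),
    scaffold_length = 400, tree_height = 0.3, stem_length = 0.25,
    indel_rate = 0.002, indel_mean_length = 3, indel_buffer = 5,
    ref_divergence = 0.5, fusion_fraction = 0, flank_mean = 120,
    preserve_diagnostics = TRUE, outgroup = TRUE, outgroup_divergence = 1.2,
    taxa = NULL, seed = 1) {
  stopifnot(scaffold_length > 0, tree_height > 0, stem_length >= 0,
            indel_rate >= 0, indel_mean_length >= 1,
            fusion_fraction >= 0, fusion_fraction <= 1,
            outgroup_divergence > 0)
  classes <- c("ASCL", "ORS", "other_PKSIII", "not_PKSIII")
  n <- setNames(rep(0L, 4), classes)
  n[names(n_per_class)] <- as.integer(n_per_class)
  stopifnot(ref_divergence >= 0)
  structure(list(n_per_class = n, scaffold_length = as.integer(scaffold_length),
                 tree_height = tree_height, stem_length = stem_length,
                 indel_rate = indel_rate,
                 indel_mean_length = indel_mean_length,
                 indel_buffer = as.integer(indel_buffer),
                 ref_divergence = ref_divergence,
                 fusion_fraction = fusion_fraction, flank_mean = flank_mean,
                 preserve_diagnostics = preserve_diagnostics,
                 outgroup = outgroup,
                 outgroup_divergence = outgroup_divergence,
                 taxa = taxa, seed = as.integer(seed)),
            class = "synthetic_family_spec")
}

# background residues drawn from the JTT equilibrium so evolution is stationary
random_background <- function(n) {
  sample(aa_alphabet(), n, replace = TRUE, prob = jtt_frequencies())
}

plant <- function(chars, positions, residues) {
  chars[positions] <- residues
  chars
}

#' Build the class reference scaffolds
#'
#' Generates one annotated reference profile per PKS class (ASCL, ORS and a
#' generic other_PKSIII) on a shared random background: catalytic triad and
#' signature motif planted at the layout positions, the class's own
#' diagnostic residues planted, and the other classes' diagnostic positions
#' held at disallowed residues. All profiles pass self-consistency.
#'
#' @param spec A [synthetic_family_spec()].
#' @param seed Seed (defaults to the spec's).
#' @return Named list of [reference_profile()]s (`ASCL`, `ORS`,
#'   `other_PKSIII`) with attribute `base` (the undecorated background) and
#'   `not_pks` (a triad-free, motif-free scaffold sequence).
#' @export
make_reference_scaffolds <- function(spec, seed = spec$seed) {
  lay <- synthetic_layout()
  L <- spec$scaffold_length
  if (L < max(layout_positions(lay)))
    stop(sprintf("scaffold length %d too short for the annotation layout (need >= %d)",
                 L, max(layout_positions(lay))))
  set.seed(seed)
  base <- random_background(L)
  base <- plant(base, lay$triad$position, lay$triad$residue)
  base <- plant(base, lay$motif_start + 0:4,
                c("G", "F", "G", "P", "G"))
  # each class reference is a diverged homolog of the shared background
  # (substitutions only, so the canonical annotation coordinates hold)
  nosub <- spec
  nosub$indel_rate <- 0
  diverge <- function(k) {
    if (spec$ref_divergence <= 0) return(base)
    set.seed(replicate_seed(seed, 100 + k))
    evolve_branch(base, spec$ref_divergence, layout_positions(lay), nosub,
                  TRUE)$chars
  }
  mk <- function(k, name, class_tag, ascl_res, ors_res, diagnostics) {
    chars <- plant(diverge(k), lay$ascl$position, ascl_res)
    chars <- plant(chars, lay$ors$position, ors_res)
    reference_profile(name, class_tag, paste(chars, collapse = ""),
                      triad = lay$triad, motif_pattern = lay$motif_pattern,
                      motif_position = lay$motif_start,
                      diagnostics = diagnostics)
  }
  profiles <- list(
    ASCL = mk(1, "ASCL_ref", "ASCL", lay$ascl$plant, lay$ors$anti,
              data.frame(position = lay$ascl$position,
                         allowed = lay$ascl$allowed, class = "ASCL",
                         stringsAsFactors = FALSE)),
    ORS = mk(2, "ORS_ref", "ORS", lay$ascl$anti, lay$ors$plant,
             data.frame(position = lay$ors$position,
                        allowed = lay$ors$allowed, class = "ORS",
                        stringsAsFactors = FALSE)),
    other_PKSIII = mk(3, "PKS3_ref", "other_PKSIII", lay$ascl$anti,
                      lay$ors$anti,
                      data.frame(position = integer(), allowed = character(),
                                 class = character(), stringsAsFactors = FALSE)))
  # triad-free scaffold: break the triad and every chance signature hit
  np <- plant(diverge(4), lay$ascl$position, lay$ascl$anti)
  np <- plant(np, lay$ors$position, lay$ors$anti)
  np <- plant(np, lay$triad$position, c("S", "R", "D"))
  np_str <- paste(np, collapse = "")
  repeat {
    hits <- find_signature_motif(np_str, lay$motif_pattern)
    if (length(hits) == 0) break
    substr(np_str, hits[1], hits[1]) <- "S"
  }
  attr(profiles, "base") <- paste(base, collapse = "")
  attr(profiles, "not_pks") <- np_str
  profiles
}

#' Random family tree
#'
#' Random topology with branch lengths drawn uniformly, shifted away from
#' zero so every internal edge carries an identifiable number of expected
#' substitutions, then rescaled so the maximum root-to-tip depth equals
#' `height` (substitutions/site).
#'
#' @param n Number of leaves (>= 2).
#' @param height Target root-to-tip height.
#' @param seed Integer seed.
#' @param min_brlen Lower bound added to the raw uniform branch lengths
#'   before rescaling.
#' @return Rooted `phylo`.
#' @export
sim_tree <- function(n, height, seed = 1, min_brlen = 0.1) {
  stopifnot(n >= 2, height > 0)
  set.seed(seed)
  tree <- ape::rtree(n)
  tree$edge.length <- tree$edge.length + min_brlen
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * height / depth
  tree
}

# evolve one sequence along a branch: JTT substitutions (masked positions
# held fixed), then indels that never touch the protected windows
evolve_branch <- function(chars, t, protected, spec, preserve) {
  L <- length(chars)
  if (t > 0) {
    P <- jtt_prob_matrix(t)
    enc <- match(chars, aa_alphabet())
    free <- if (preserve) setdiff(seq_len(L), protected) else seq_len(L)
    for (a in unique(enc[free])) {
      idx <- free[enc[free] == a]
      chars[idx] <- sample(aa_alphabet(), length(idx), replace = TRUE,
                           prob = P[a, ])
    }
  }
  n_events <- if (spec$indel_rate > 0)
    stats::rpois(1, spec$indel_rate * L * t) else 0L
  shift_map <- seq_len(L)  # old position -> new position (NA = deleted)
  if (n_events > 0) {
    for (ev in seq_len(n_events)) {
      len <- stats::rgeom(1, 1 / spec$indel_mean_length) + 1L
      cur_len <- length(chars)
      if (stats::runif(1) < 0.5) {  # insertion after position p (0..len)
        p <- sample.int(cur_len + 1L, 1) - 1L
        if (preserve) {
          prot_now <- stats::na.omit(shift_map[protected])
          if (any(abs(prot_now - p) <= spec$indel_buffer)) next
        }
        chars <- append(chars, random_background(len), after = p)
        shift_map <- ifelse(!is.na(shift_map) & shift_map > p,
                            shift_map + len, shift_map)
      } else {                      # deletion of [p, p+len-1]
        if (cur_len <= len + 10) next
        p <- sample.int(cur_len - len, 1)
        span <- p:(p + len - 1L)
        if (preserve) {
          prot_now <- stats::na.omit(shift_map[protected])
          if (any(prot_now >= p - spec$indel_buffer &
                  prot_now <= p + len - 1L + spec$indel_buffer)) next
        }
        chars <- chars[-span]
        shift_map <- ifelse(!is.na(shift_map) & shift_map %in% span, NA,
                            ifelse(!is.na(shift_map) & shift_map > max(span),
                                   shift_map - len, shift_map))
      }
    }
  }
  list(chars = chars, shift = shift_map)
}

#' Evolve a protein family along a tree
#'
#' Evolves the profile's (or scaffold's) sequence along the given rooted
#' tree under the JTT model with optional indels. When
#' `spec$preserve_diagnostics` is true, every annotated layout position is
#' held invariant and indels keep their distance, so each leaf retains its
#' class-defining residues; planted coordinates are remapped through every
#' accepted indel.
#'
#' @param profile A [reference_profile()] (or a residue string).
#' @param tree Rooted `phylo` whose tip labels become sequence ids.
#' @param spec A [synthetic_family_spec()].
#' @param seed Integer seed.
#' @param class_label Truth class recorded for the leaves (defaults to the
#'   profile's class).
#' @param planted Integer vector of the annotated positions to protect on
#'   the root sequence (defaults to the layout positions); callers that have
#'   already evolved the scaffold must pass the remapped coordinates.
#' @return List with `records` (sequence data.frame), `truth` (data.frame
#'   id/class), `planted` (per-leaf named integer vectors of remapped layout
#'   coordinates) and `tree`.
#' @export
evolve_family <- function(profile, tree, spec, seed = spec$seed,
                          class_label = NULL, planted = NULL) {
  root_seq <- if (inherits(profile, "reference_profile"))
    profile$residues else profile
  if (is.null(class_label))
    class_label <- if (inherits(profile, "reference_profile"))
      profile$class else "other_PKSIII"
  set.seed(seed)
  lay_pos <- if (is.null(planted)) layout_positions() else planted
  lay_pos <- lay_pos[lay_pos <= nchar(root_seq)]
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- list(chars = strsplit(root_seq, "", fixed = TRUE)[[1]],
                         coords = setNames(lay_pos, lay_pos))
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  preserve <- spec$preserve_diagnostics
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; child <- edges[k, 2]
    st <- states[[par]]
    protected <- unname(st$coords[!is.na(st$coords)])
    res <- evolve_branch(st$chars, lens[k], protected, spec, preserve)
    new_coords <- st$coords
    ok <- !is.na(new_coords)
    new_coords[ok] <- res$shift[new_coords[ok]]
    states[[child]] <- list(chars = res$chars, coords = new_coords)
  }
  ids <- tree$tip.label
  records <- data.frame(
    id = ids, description = "",
    residues = vapply(seq_len(ntip), function(i)
      paste(states[[i]]$chars, collapse = ""), character(1)),
    is_fusion = FALSE, stringsAsFactors = FALSE)
  list(records = records,
       truth = data.frame(id = ids, class = class_label,
                          stringsAsFactors = FALSE),
       planted = lapply(seq_len(ntip), function(i) states[[i]]$coords),
       tree = tree)
}

# default composition from per-class counts
default_taxa <- function(spec) {
  lineages <- c(ASCL = "bryophyte", ORS = "bryophyte",
                other_PKSIII = "other_embryophyte", not_PKSIII = "other_alga")
  rows <- lapply(names(spec$n_per_class), function(cl) {
    n <- spec$n_per_class[[cl]]
    if (n == 0) return(NULL)
    data.frame(id = sprintf("%s_%02d", cl, seq_len(n)),
               species = sprintf("Synthsp %s", tolower(cl)),
               lineage_group = lineages[[cl]],
               expected_class = if (cl == "not_PKSIII") NA_character_ else cl,
               family = cl, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a full synthetic dataset on disk
#'
#' Writes every input the pipeline consumes: a protein FASTA, a taxon table,
#' the reference profiles (FASTA + annotation TSV) and a truth JSON with the
#' generating trees and per-leaf class labels. Deterministic under the
#' spec's seed.
#'
#' @param spec A [synthetic_family_spec()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list with the output `paths`, the `records`,
#'   `taxa`, `profiles` and `truth` objects.
#' @export
generate_dataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  taxa <- if (is.null(spec$taxa)) default_taxa(spec) else spec$taxa
  profiles <- make_reference_scaffolds(spec)
  class_of_family <- list()
  all_records <- list()
  all_truth <- list()
  trees <- list()
  if (!is.null(taxa)) {
    fam_names <- unique(taxa$family)
    for (fi in seq_along(fam_names)) {
      fam <- fam_names[fi]
      rows <- taxa[taxa$family == fam, ]
      cls <- unique(rows$expected_class)
      cls <- if (all(is.na(cls))) "not_PKSIII" else cls[!is.na(cls)][1]
      n <- nrow(rows)
      fam_seed <- replicate_seed(spec$seed, 1000 + fi)
      scaffold <- switch(cls,
        ASCL = profiles$ASCL$residues,
        ORS = profiles$ORS$residues,
        other_PKSIII = profiles$other_PKSIII$residues,
        not_PKSIII = attr(profiles, "not_pks"))
      coords <- layout_positions()
      if (fam == "outgroup") {
        # distantly related rooting taxon: a generic PKS pushed far out
        set.seed(replicate_seed(spec$seed, 500 + fi))
        og <- evolve_branch(
          strsplit(profiles$other_PKSIII$residues, "", fixed = TRUE)[[1]],
          spec$outgroup_divergence, coords, spec, TRUE)
        scaffold <- paste(og$chars, collapse = "")
        coords <- coords[!is.na(og$shift[coords])]
        coords <- og$shift[coords]
      }
      # diverge the family root from the class scaffold along a stem
      if (spec$stem_length > 0) {
        set.seed(fam_seed)
        stem <- evolve_branch(strsplit(scaffold, "", fixed = TRUE)[[1]],
                              spec$stem_length, coords, spec,
                              spec$preserve_diagnostics)
        scaffold <- paste(stem$chars, collapse = "")
        coords <- coords[!is.na(stem$shift[coords])]
        coords <- stem$shift[coords]
      }
      if (n == 1) {
        tree <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                               edge.length = spec$tree_height,
                               tip.label = rows$id, Nnode = 1L),
                          class = "phylo")
      } else {
        tree <- sim_tree(n, spec$tree_height,
                         seed = replicate_seed(spec$seed, 2000 + fi))
        tree$tip.label <- rows$id[as.integer(sub("^t", "", tree$tip.label))]
      }
      fam_res <- evolve_family(scaffold, tree, spec,
                               seed = replicate_seed(spec$seed, 3000 + fi),
                               class_label = cls, planted = coords)
      all_records[[fam]] <- fam_res$records
      fam_res$truth$family <- fam
      all_truth[[fam]] <- fam_res$truth
      trees[[fam]] <- ape::write.tree(tree)
    }
  }
  if (spec$outgroup && !"outgroup" %in% taxa$family) {
    set.seed(replicate_seed(spec$seed, 9999))
    og <- evolve_branch(
      strsplit(profiles$other_PKSIII$residues, "", fixed = TRUE)[[1]],
      spec$outgroup_divergence, layout_positions(), spec, TRUE)
    rec <- data.frame(id = "Outgroup_PKS", description = "",
                      residues = paste(og$chars, collapse = ""),
                      is_fusion = FALSE, stringsAsFactors = FALSE)
    all_records[["outgroup"]] <- rec
    all_truth[["outgroup"]] <- data.frame(id = "Outgroup_PKS",
                                          class = "other_PKSIII",
                                          family = "outgroup",
                                          stringsAsFactors = FALSE)
    taxa <- rbind(taxa,
                  data.frame(id = "Outgroup_PKS", species = "Synthsp outgroup",
                             lineage_group = "cyanobacterium",
                             expected_class = "other_PKSIII",
                             family = "outgroup", stringsAsFactors = FALSE))
  }
  records <- do.call(rbind, unname(all_records))
  truth <- do.call(rbind, unname(all_truth))
  # fusion decoration
  if (!is.null(records) && spec$fusion_fraction > 0 && nrow(records) > 0) {
    set.seed(replicate_seed(spec$seed, 7777))
    n_fuse <- floor(spec$fusion_fraction *
                      sum(records$id != "Outgroup_PKS"))
    cand <- which(records$id != "Outgroup_PKS")
    fuse <- sort(sample(cand, n_fuse))
    for (i in fuse) {
      nlen <- stats::rpois(1, spec$flank_mean)
      clen <- stats::rpois(1, spec$flank_mean)
      records$residues[i] <- paste0(
        paste(random_background(nlen), collapse = ""), records$residues[i],
        paste(random_background(clen), collapse = ""))
      records$is_fusion[i] <- TRUE
    }
    truth$is_fusion <- records$is_fusion[match(truth$id, records$id)]
  } else if (!is.null(truth)) {
    truth$is_fusion <- FALSE
  }
  paths <- list(
    sequences = file.path(dir, "sequences.fasta"),
    taxa = file.path(dir, "taxa.tsv"),
    references = file.path(dir, "references.fasta"),
    annotations = file.path(dir, "reference_annotations.tsv"),
    truth = file.path(dir, "truth.json"))
  if (is.null(records)) {
    records <- data.frame(id = character(), description = character(),
                          residues = character(), is_fusion = logical(),
                          stringsAsFactors = FALSE)
    truth <- data.frame(id = character(), class = character(),
                        family = character(), is_fusion = logical(),
                        stringsAsFactors = FALSE)
  }
  write_fasta(records, paths$sequences)
  out_taxa <- if (is.null(taxa))
    data.frame(id = character(), species = character(),
               lineage_group = character(), expected_class = character(),
               stringsAsFactors = FALSE)
  else taxa[, c("id", "species", "lineage_group", "expected_class")]
  write.table(out_taxa, paths$taxa, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_reference_profiles(profiles[c("ASCL", "ORS", "other_PKSIII")],
                           paths$references, paths$annotations)
  jsonlite::write_json(
    list(classes = truth, trees = trees, seed = spec$seed),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(paths = paths, records = records, taxa = taxa,
                 profiles = profiles, truth = truth))
}
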