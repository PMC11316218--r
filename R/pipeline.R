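# End-to-end orchestration: classify -> align -> distances -> NJ + bootstrap
# -> root -> clade report, with a run log and machine-readable manifest.

#' Assemble a pipeline configuration
#'
#' @param sequences Path to the query FASTA.
#' @param references_fasta,references_annotation Paths to the reference
#'   profile FASTA and annotation table.
#' @param msa Optional path to an externally computed aligned FASTA; when
#'   given, the in-house progressive aligner is skipped.
#' @param taxon_table Optional taxon metadata TSV.
#' @param outgroup Optional outgroup sequence id for rooting.
#' @param out_dir Output directory.
#' @param bootstrap Bootstrap replicate count (0 disables support values).
#' @param seed Integer seed for the bootstrap resampler.
#' @param scoring Alignment scoring configuration.
#' @param align_floor Classification alignment floor (see
#'   [classify_sequence()]).
#' @param skip_msa,skip_tree Stage toggles; `skip_tree` stops after
#'   classification, `skip_msa` implies `skip_tree` unless `msa` is given.
#' @param nni Apply least-squares NNI refinement to the NJ tree.
#' @param fusion_length_factor Sequences longer than this multiple of the
#'   longest reference are treated as fusions and domain-extracted before
#'   alignment stages.
#' @param domain_margin,domain_floor Passed to [extract_pks_domain()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sequences, references_fasta, references_annotation,
                            out_dir, msa = NULL, taxon_table = NULL,
                            outgroup = NULL, bootstrap = 1000, seed = 1,
                            scoring = default_scoring(), align_floor = 0,
                            skip_msa = FALSE, skip_tree = FALSE, nni = FALSE,
                            fusion_length_factor = 1.7, domain_margin = 10,
                            domain_floor = 100) {
  for (p in c(sequences, references_fasta, references_annotation, msa,
              taxon_table)) {
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("input not found: %s", p))
  }
  if (bootstrap < 0) stop("bootstrap count must be >= 0")
  structure(list(sequences = sequences, references_fasta = references_fasta,
                 references_annotation = references_annotation,
                 msa = msa, taxon_table = taxon_table, outgroup = outgroup,
                 out_dir = out_dir, bootstrap = bootstrap, seed = seed,
                 scoring = scoring, align_floor = align_floor,
                 skip_msa = skip_msa, skip_tree = skip_tree, nni = nni,
                 fusion_length_factor = fusion_length_factor,
                 domain_margin = domain_margin, domain_floor = domain_floor),
            class = "pipeline_config")
}

#' Run the full classification and phylogeny pipeline
#'
#' Stages: load inputs; validate/classify every sequence (fusions are
#' domain-extracted first); write the classification table; census against
#' the taxon table; align (imported or progressive, references included);
#' JTT distances; NJ tree with bootstrap supports, outgroup rooting and
#' optional NNI refinement; clade/concordance report. Every stage logs to
#' `run.log`; a `manifest.json` captures parameters, seed and timings. A
#' stage failure leaves earlier outputs in place and raises an error naming
#' the stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of output paths and key in-memory
#'   results (`classifications`, `census`, `tree`, `clade_report`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    writeLines(line, log_con)
  }
  timings <- list()
  stage <- function(name, expr) {
    logmsg("stage %s: start", name)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      logmsg("stage %s: FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    logmsg("stage %s: done (%.2fs)", name, timings[[name]])
    res
  }
  out <- list(log = log_path)

  inputs <- stage("load", {
    records <- read_fasta(config$sequences)
    profiles <- load_reference_profiles(config$references_fasta,
                                        config$references_annotation)
    taxa <- if (!is.null(config$taxon_table))
      read_taxon_table(config$taxon_table) else NULL
    list(records = records, profiles = profiles, taxa = taxa)
  })
  logmsg("loaded %d sequences, %d reference profiles",
         nrow(inputs$records), length(inputs$profiles))

  classified <- stage("classify", {
    ref_len <- max(nchar(vapply(inputs$profiles, `[[`, character(1),
                                "residues")))
    recs <- inputs$records
    analysis <- recs
    for (i in seq_len(nrow(recs))) {
      if (recs$is_fusion[i] ||
          nchar(recs$residues[i]) > config$fusion_length_factor * ref_len) {
        dom <- try(extract_pks_domain(recs[i, ], inputs$profiles[[1]],
                                      margin = config$domain_margin,
                                      floor = config$domain_floor,
                                      scoring = config$scoring), silent = TRUE)
        if (!inherits(dom, "try-error")) {
          analysis$residues[i] <- dom$residues
          logmsg("extracted PKS domain from '%s' (%d..%d)", recs$id[i],
                 attr(dom, "domain_start"), attr(dom, "domain_end"))
        }
      }
    }
    results <- classify_sequences(analysis, inputs$profiles, config$scoring,
                                  config$align_floor)
    list(results = results, table = classification_table(results),
         analysis = analysis)
  })
  out$classifications <- file.path(config$out_dir, "classifications.tsv")
  write.table(classified$table, out$classifications, sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(classified$table,
                       file.path(config$out_dir, "classifications.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  census <- NULL
  if (!is.null(inputs$taxa)) {
    census <- stage("census", summarize_census(classified$table, inputs$taxa))
    out$census_tsv <- file.path(config$out_dir, "census.tsv")
    write.table(census$by_lineage, out$census_tsv, sep = "\t", quote = FALSE,
                row.names = TRUE, col.names = NA)
  }

  tree <- NULL
  report <- NULL
  do_tree <- !config$skip_tree &&
    (!config$skip_msa || !is.null(config$msa)) &&
    nrow(classified$analysis) + length(inputs$profiles) >= 3
  if (do_tree) {
    msa <- stage("msa", {
      if (!is.null(config$msa)) import_alignment(config$msa)
      else {
        refs <- data.frame(
          id = vapply(inputs$profiles, `[[`, character(1), "name"),
          description = "", residues = vapply(inputs$profiles, `[[`,
                                              character(1), "residues"),
          is_fusion = FALSE, stringsAsFactors = FALSE)
        both <- rbind(classified$analysis[, names(refs)], refs)
        both$id <- make.unique(both$id)
        progressive_align(both, config$scoring)
      }
    })
    out$alignment <- file.path(config$out_dir, "alignment.fasta")
    write_alignment(msa, out$alignment)

    D <- stage("distances", build_distance_matrix(msa))
    out$distances <- file.path(config$out_dir, "distances.tsv")
    write_distance_matrix(D, out$distances)

    tree <- stage("tree", {
      tr <- if (config$bootstrap > 0)
        bootstrap_support(msa, config$bootstrap, seed = config$seed)
      else nj_tree(D)
      if (config$nni) tr <- nni_refine(tr, D)
      if (!is.null(config$outgroup)) tr <- root_with_outgroup(tr,
                                                              config$outgroup)
      tr
    })
    out$tree_nwk <- file.path(config$out_dir, "tree.nwk")
    write_tree_newick(tree, out$tree_nwk)

    report <- stage("clades", {
      ref_labels <- setNames(
        vapply(inputs$profiles, `[[`, character(1), "class"),
        vapply(inputs$profiles, `[[`, character(1), "name"))
      rooted <- if (is.null(config$outgroup))
        root_with_outgroup(tree, tree$tip.label[1]) else tree
      tab <- classified$table
      tab$id <- classified$analysis$id  # ids as they appear in the MSA
      concordance_report(tab[tab$id %in% rooted$tip.label, ], rooted,
                         ref_labels)
    })
    out$clade_report_json <- file.path(config$out_dir, "clade_report.json")
    write_clade_report(report, out$clade_report_json,
                       file.path(config$out_dir, "clade_summary.tsv"))
  }

  manifest <- list(
    package = as.character(utils::packageVersion("pks3class")),
    seed = config$seed, bootstrap = config$bootstrap,
    outgroup = config$outgroup,
    inputs = list(sequences = config$sequences,
                  references = config$references_fasta,
                  annotation = config$references_annotation,
                  msa = config$msa, taxon_table = config$taxon_table),
    n_sequences = nrow(inputs$records),
    timings = timings)
  out$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, out$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  logmsg("pipeline complete")
  invisible(c(out, list(classification_table = classified$table,
                        census = census, tree = tree,
                        clade_report = report)))
}

#' Cross-tabulate classification labels by lineage
#'
#' @param classification Classification table from [classification_table()]
#'   (or a list of results).
#' @param taxa Taxon table from [read_taxon_table()].
#' @return List with `by_lineage` (lineage x label contingency as a
#'   data.frame) and `by_species` (long data.frame species/label/n). Ids
#'   absent from the taxon table are counted under lineage `unknown` with a
#'   warning.
#' @export
summarize_census <- function(classification, taxa) {
  tab <- if (is.data.frame(classification)) classification
         else classification_table(classification)
  if (nrow(tab) == 0)
    return(list(by_lineage = as.data.frame(matrix(integer(), 0, 0)),
                by_species = data.frame(species = character(),
                                        label = character(), n = integer(),
                                        stringsAsFactors = FALSE)))
  m <- match(tab$id, taxa$id)
  if (anyNA(m))
    warning(sprintf("id(s) absent from taxon table counted as 'unknown': %s",
                    paste(tab$id[is.na(m)], collapse = ", ")))
  lineage <- ifelse(is.na(m), "unknown", taxa$lineage_group[m])
  species <- ifelse(is.na(m), "unknown", taxa$species[m])
  by_lineage <- as.data.frame.matrix(table(lineage, tab$label))
  by_species <- as.data.frame(table(species = species, label = tab$label),
                              stringsAsFactors = FALSE)
  names(by_species)[3] <- "n"
  by_species <- by_species[by_species$n > 0, ]
  rownames(by_species) <- NULL
  list(by_lineage = by_lineage, by_species = by_species)
}
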