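# Sequence, taxon-table and reference-profile I/O.
#
# A sequence set is a plain data.frame with columns id, description,
# residues, and optionally species, lineage_group, is_fusion. Coordinates in
# every user-facing structure are 1-based and inclusive, following the
# field's residue-numbering convention (e.g. "Gly225").

.aa_valid <- function() c(aa_alphabet(), "X")

#' Recognized lineage groups
#'
#' @return Character vector of the canonical lineage group labels.
#' @export
lineage_groups <- function() {
  c("bryophyte", "other_embryophyte", "charophyte", "other_alga",
    "cyanobacterium", "unknown")
}

# default phylum/clade -> lineage group synonym map (case-insensitive keys)
default_lineage_synonyms <- function() {
  c(bryophyta = "bryophyte", marchantiophyta = "bryophyte",
    anthocerotophyta = "bryophyte",
    lycopodiophyta = "other_embryophyte", polypodiopsida = "other_embryophyte",
    gymnosperms = "other_embryophyte", eudicots = "other_embryophyte",
    monocots = "other_embryophyte", tracheophyta = "other_embryophyte",
    charophyta = "charophyte",
    chlorophyta = "other_alga", ochrophyta = "other_alga", sar = "other_alga",
    rhodophyta = "other_alga", haptophyta = "other_alga",
    cyanobacteria = "cyanobacterium")
}

validate_residues <- function(residues, id) {
  bad <- regexpr(sprintf("[^%s]", paste(.aa_valid(), collapse = "")), residues)
  if (bad > 0)
    stop(sprintf("illegal residue character '%s' in record '%s' at position %d",
                 substr(residues, bad, bad), id, bad))
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#'
#' Deflines are parsed as `id [whitespace] free-text description`; the first
#' whitespace-delimited token is the record id. Residues are uppercased and
#' validated against the twenty amino acid letters plus X.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `description`, `residues`,
#'   `is_fusion` (all `FALSE` on plain reads), in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0)
    stop(sprintf("empty FASTA input: %s", path))
  deflines <- names(set)
  ids <- sub("\\s.*$", "", deflines)
  desc <- ifelse(grepl("\\s", deflines),
                 sub("^\\S+\\s+", "", deflines), "")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  residues <- toupper(as.character(set))
  for (i in seq_along(ids)) {
    if (nchar(residues[i]) == 0)
      stop(sprintf("record '%s' has an empty sequence", ids[i]))
    validate_residues(residues[i], ids[i])
  }
  data.frame(id = ids, description = desc, residues = unname(residues),
             is_fusion = FALSE, stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param records Data.frame with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(desc[[min(i, length(desc))]]))
      paste(records$id[i], desc[[min(i, length(desc))]]) else records$id[i]
    writeLines(paste0(">", header), con)
    s <- records$residues[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a taxon metadata table
#'
#' Tab-separated with a header row and columns `id`, `species`,
#' `lineage_group` and optionally `expected_class`. Lineage strings are
#' resolved through a synonym map (phylum names such as "Ochrophyta" map to
#' canonical groups); unresolved strings map to `unknown` with a warning.
#'
#' @param path Path to the TSV file.
#' @param synonyms Named character vector mapping lower-cased lineage strings
#'   to canonical [lineage_groups()].
#' @return Data.frame with columns `id`, `species`, `lineage_group`,
#'   `expected_class` (NA when absent).
#' @export
read_taxon_table <- function(path, synonyms = default_lineage_synonyms()) {
  if (!file.exists(path)) stop(sprintf("taxon table not found: %s", path))
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    strip.white = TRUE)
  req <- c("id", "species", "lineage_group")
  if (!all(req %in% names(tab)))
    stop(sprintf("taxon table must have columns %s", paste(req, collapse = ", ")))
  if (anyDuplicated(tab$id))
    stop(sprintf("duplicate id(s) in taxon table: %s",
                 paste(unique(tab$id[duplicated(tab$id)]), collapse = ", ")))
  raw <- tab$lineage_group
  canon <- tolower(trimws(sub(",.*$", "", raw)))
  group <- ifelse(canon %in% lineage_groups(), canon,
                  unname(synonyms[canon]))
  if (anyNA(group)) {
    warning(sprintf("unrecognized lineage group(s) mapped to 'unknown': %s",
                    paste(unique(raw[is.na(group)]), collapse = ", ")))
    group[is.na(group)] <- "unknown"
  }
  cls <- if ("expected_class" %in% names(tab)) tab$expected_class else NA_character_
  cls[!is.na(cls) & cls == ""] <- NA
  bad <- !is.na(cls) & !cls %in% c("ASCL", "ORS", "other_PKSIII")
  if (any(bad))
    stop(sprintf("invalid expected_class value(s): %s",
                 paste(unique(cls[bad]), collapse = ", ")))
  data.frame(id = tab$id, species = tab$species, lineage_group = group,
             expected_class = cls, stringsAsFactors = FALSE)
}

# ---- reference profiles ----------------------------------------------------

# Parse a 5-mer signature pattern such as "[GA]FGPG" into a list of allowed
# character sets per position.
parse_motif_pattern <- function(pattern) {
  sets <- list()
  i <- 1
  while (i <= nchar(pattern)) {
    ch <- substr(pattern, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(pattern, i, nchar(pattern)))
      if (j < 0) stop(sprintf("unbalanced '[' in motif pattern '%s'", pattern))
      sets[[length(sets) + 1]] <- strsplit(substr(pattern, i + 1, i + j - 2),
                                           "")[[1]]
      i <- i + j
    } else {
      sets[[length(sets) + 1]] <- ch
      i <- i + 1
    }
  }
  sets
}

deparse_motif_pattern <- function(sets) {
  paste(vapply(sets, function(s)
    if (length(s) > 1) paste0("[", paste(s, collapse = ""), "]") else s,
    character(1)), collapse = "")
}

#' Construct a reference profile
#'
#' A reference profile is an annotated reference sequence carrying the
#' 1-based coordinates used for numbering transfer: the Cys-His-Asn
#' catalytic triad, the (G/A)FGPG signature motif, and the class-specific
#' diagnostic residues.
#'
#' @param name Profile name (e.g. `"PpASCL"`).
#' @param class_tag The profile's own class: `"ASCL"`, `"ORS"` or
#'   `"other_PKSIII"`.
#' @param residues Reference residue string.
#' @param triad Data.frame with columns `position`, `residue` — three rows,
#'   residues C, H, N.
#' @param motif_pattern Signature pattern string, default `"[GA]FGPG"`.
#' @param motif_position Optional 1-based start of the signature on the
#'   reference (NA = anywhere).
#' @param diagnostics Data.frame with columns `position`, `allowed` (string
#'   of allowed residues, e.g. `"AV"`), `class` — may have zero rows.
#' @return Object of class `reference_profile`.
#' @export
reference_profile <- function(name, class_tag, residues, triad,
                              motif_pattern = "[GA]FGPG",
                              motif_position = NA_integer_,
                              diagnostics = data.frame(
                                position = integer(), allowed = character(),
                                class = character(), stringsAsFactors = FALSE)) {
  prof <- structure(
    list(name = name, class = class_tag, residues = toupper(residues),
         triad = triad,
         motif = list(sets = parse_motif_pattern(motif_pattern),
                      pattern = motif_pattern,
                      position = as.integer(motif_position)),
         diagnostics = diagnostics),
    class = "reference_profile")
  validate_reference_profile(prof)
  prof
}

#' Validate a reference profile's self-consistency
#'
#' Checks that every annotated position lies within the reference sequence
#' and that the reference's own residues satisfy every annotation (guarding
#' against off-by-one numbering drift).
#'
#' @param prof A `reference_profile`.
#' @return The profile, invisibly; errors on violation.
#' @export
validate_reference_profile <- function(prof) {
  len <- nchar(prof$residues)
  validate_residues(prof$residues, prof$name)
  if (nrow(prof$triad) != 3 || !identical(sort(prof$triad$residue), c("C", "H", "N")))
    stop(sprintf("profile '%s': triad must annotate exactly C, H and N", prof$name))
  pos <- c(prof$triad$position, prof$diagnostics$position,
           if (!is.na(prof$motif$position))
             prof$motif$position + length(prof$motif$sets) - 1L)
  if (any(pos < 1 | pos > len))
    stop(sprintf("profile '%s': annotated position beyond sequence length (%d)",
                 prof$name, len))
  at <- function(p) substr(prof$residues, p, p)
  for (i in seq_len(3)) {
    p <- prof$triad$position[i]
    if (at(p) != prof$triad$residue[i])
      stop(sprintf(
        "profile '%s' is not self-consistent: expected %s at triad position %d, found %s",
        prof$name, prof$triad$residue[i], p, at(p)))
  }
  for (i in seq_len(nrow(prof$diagnostics))) {
    p <- prof$diagnostics$position[i]
    allowed <- strsplit(prof$diagnostics$allowed[i], "")[[1]]
    if (!at(p) %in% allowed)
      stop(sprintf(
        "profile '%s' is not self-consistent: residue %s at diagnostic position %d not in {%s}",
        prof$name, at(p), p, prof$diagnostics$allowed[i]))
  }
  hits <- find_signature_motif(prof$residues, prof$motif$sets)
  if (!is.na(prof$motif$position)) {
    if (!prof$motif$position %in% hits)
      stop(sprintf("profile '%s': no signature motif at annotated position %d",
                   prof$name, prof$motif$position))
  } else if (length(hits) == 0) {
    stop(sprintf("profile '%s': reference lacks the signature motif", prof$name))
  }
  invisible(prof)
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("<reference_profile> %s (%s), %d aa\n", x$name, x$class,
              nchar(x$residues)))
  cat(sprintf("  triad: %s\n", paste(sprintf("%s%d", x$triad$residue,
                                             x$triad$position), collapse = " ")))
  cat(sprintf("  motif: %s%s\n", x$motif$pattern,
              if (is.na(x$motif$position)) "" else
                sprintf(" at %d", x$motif$position)))
  if (nrow(x$diagnostics))
    cat(sprintf("  diagnostics: %s\n",
                paste(sprintf("%s@%d:{%s}", x$diagnostics$class,
                              x$diagnostics$position, x$diagnostics$allowed),
                      collapse = " ")))
  invisible(x)
}

#' Load reference profiles from FASTA plus annotation table
#'
#' The annotation table is tab-separated with a header and columns
#' `reference`, `feature`, `position`, `residues`, `class`. Each reference
#' needs one `self` row (its own class in `class`), three `triad` rows
#' (`position` + required residue C, H or N), one `motif` row (`residues` =
#' pattern such as `[GA]FGPG`, `position` optional), and any number of
#' `diagnostic` rows (`position`, allowed residue set such as `AV`, and the
#' class tag the position diagnoses). Profiles are validated for
#' self-consistency on load.
#'
#' @param fasta_path FASTA file with the reference sequences (ids matching
#'   the `reference` column).
#' @param annotation_path Annotation TSV as above.
#' @return Named list of `reference_profile` objects.
#' @export
load_reference_profiles <- function(fasta_path, annotation_path) {
  seqs <- read_fasta(fasta_path)
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE,
                    strip.white = TRUE)
  req <- c("reference", "feature", "position", "residues", "class")
  if (!all(req %in% names(ann)))
    stop(sprintf("annotation table must have columns %s",
                 paste(req, collapse = ", ")))
  profiles <- list()
  for (ref in unique(ann$reference)) {
    rows <- ann[ann$reference == ref, ]
    idx <- match(ref, seqs$id)
    if (is.na(idx))
      stop(sprintf("reference '%s' annotated but absent from %s", ref, fasta_path))
    self <- rows[rows$feature == "self", ]
    if (nrow(self) != 1)
      stop(sprintf("reference '%s': need exactly one 'self' row", ref))
    triad <- rows[rows$feature == "triad", ]
    motif <- rows[rows$feature == "motif", ]
    if (nrow(motif) != 1)
      stop(sprintf("reference '%s': need exactly one 'motif' row", ref))
    diag_rows <- rows[rows$feature == "diagnostic", ]
    profiles[[ref]] <- reference_profile(
      name = ref, class_tag = self$class,
      residues = seqs$residues[idx],
      triad = data.frame(position = as.integer(triad$position),
                         residue = triad$residues, stringsAsFactors = FALSE),
      motif_pattern = motif$residues,
      motif_position = suppressWarnings(as.integer(motif$position)),
      diagnostics = data.frame(position = as.integer(diag_rows$position),
                               allowed = diag_rows$residues,
                               class = diag_rows$class,
                               stringsAsFactors = FALSE))
  }
  profiles
}

#' Serialize reference profiles back to FASTA + annotation table
#'
#' Inverse of [load_reference_profiles()]: preserves every annotated
#' position and allowed residue set.
#'
#' @param profiles Named list of `reference_profile` objects.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference_profiles <- function(profiles, fasta_path, annotation_path) {
  recs <- data.frame(
    id = vapply(profiles, `[[`, character(1), "name"),
    residues = vapply(profiles, `[[`, character(1), "residues"),
    stringsAsFactors = FALSE)
  write_fasta(recs, fasta_path)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    rbind(
      data.frame(reference = p$name, feature = "self", position = NA_integer_,
                 residues = "", class = p$class, stringsAsFactors = FALSE),
      data.frame(reference = p$name, feature = "triad",
                 position = p$triad$position, residues = p$triad$residue,
                 class = "", stringsAsFactors = FALSE),
      data.frame(reference = p$name, feature = "motif",
                 position = p$motif$position,
                 residues = deparse_motif_pattern(p$motif$sets),
                 class = "", stringsAsFactors = FALSE),
      if (nrow(p$diagnostics))
        data.frame(reference = p$name, feature = "diagnostic",
                   position = p$diagnostics$position,
                   residues = p$diagnostics$allowed,
                   class = p$diagnostics$class, stringsAsFactors = FALSE))
  }))
  write.table(rows, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta_path, annotation_path))
}
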