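# Synthetic mirror of the published plant/algal type III PKS survey.

#' Composition of the synthetic survey mirror
#'
#' The taxon composition of the plant and algal type III PKS survey: one
#' cyanobacterial outgroup, 35 algal non-ORS/non-ASCL sequences (in five
#' families), 12 charophyte ORS, 11 bryophyte ORS (two from *Takakia
#' lepidozioides*), 14 embryophyte ASCL (one from *Takakia*) and 7
#' embryophyte non-ORS/non-ASCL sequences (one from *Takakia*). Sequence ids
#' and species follow the published survey (whitespace normalized to
#' underscores); the sequences themselves are generated synthetically by
#' [generate_dataset()], which plants each class's diagnostic residues — the
#' file carries composition, not real sequence data.
#'
#' @return Data.frame with columns `id`, `species`, `lineage_group`,
#'   `expected_class`, `family`.
#' @export
survey_composition <- function() {
  path <- system.file("extdata", "survey_composition_synthetic.tsv",
                      package = "pks3class")
  read.delim(path, stringsAsFactors = FALSE, quote = "")
}

#' Generator specification for the survey mirror
#'
#' A [synthetic_family_spec()] whose composition is [survey_composition()]:
#' running [generate_dataset()] on it yields a synthetic dataset with the
#' survey's class census (e.g. the four *Takakia* sequences comprise one
#' ASCL, two ORS and one other type III PKS).
#'
#' @param seed Integer seed.
#' @param tree_height,stem_length,indel_rate Passed through to
#'   [synthetic_family_spec()].
#' @return A `synthetic_family_spec`.
#' @export
survey_spec <- function(seed = 1, tree_height = 0.25, stem_length = 0.3,
                        indel_rate = 0.002) {
  synthetic_family_spec(taxa = survey_composition(), seed = seed,
                        tree_height = tree_height, stem_length = stem_length,
                        indel_rate = indel_rate, outgroup = FALSE)
}
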