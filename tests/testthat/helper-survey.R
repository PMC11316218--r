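# one shared classification run of the synthetic survey mirror, cached so
# several tests can interrogate the same census
.survey_cache <- new.env(parent = emptyenv())

survey_run <- function(seed = 11) {
  key <- paste0("seed", seed)
  if (is.null(.survey_cache[[key]])) {
    gen <- generate_dataset(survey_spec(seed = seed), tempfile("survey"))
    profiles <- load_reference_profiles(gen$paths$references,
                                        gen$paths$annotations)
    recs <- read_fasta(gen$paths$sequences)
    tab <- classification_table(classify_sequences(recs, profiles))
    taxa <- read_taxon_table(gen$paths$taxa)
    .survey_cache[[key]] <- list(gen = gen, tab = tab, taxa = taxa,
                                 profiles = profiles)
  }
  .survey_cache[[key]]
}
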