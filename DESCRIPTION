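Package: pks3class
Title: Classification and Phylogenetic Placement of Type III Polyketide
    Synthases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies type III polyketide synthases (PKSs) in protein
    sequence sets and classifies them into the ASCL (anther-specific
    chalcone synthase-like) and ORS (2'-oxoalkylresorcinol synthase)
    subfamilies. Candidates are validated by the Cys-His-Asn catalytic
    triad and the (G/A)FGPG signature motif; subfamily labels are called
    from diagnostic residues mapped onto reference coordinates through
    pairwise alignment. A companion phylogenetic stage computes maximum
    likelihood pairwise distances under the JTT amino acid substitution
    model, builds neighbor-joining trees with nonparametric bootstrap
    support, roots them on a designated outgroup, and reports clade
    membership and residue/phylogeny concordance. A seeded simulator
    generates labeled protein families with planted catalytic and
    diagnostic residues for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
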