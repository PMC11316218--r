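---
title: "Classifying type III polyketide synthases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying type III polyketide synthases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pks3class)
```

## The problem

Type III polyketide synthases (PKSs) — the chalcone synthase family — are
homodimeric enzymes found across plants, algae and bacteria. Two subfamilies
carry special significance in plant evolution. ASCL (anther-specific
chalcone synthase-like) enzymes synthesize the hydroxylated polyketides that
are cross-linked into sporopollenin, the chemically resistant outer wall of
spores and pollen; the presence of an ASCL gene is a usable marker for
genuine sporopollenin in a genome. ORS (2′-oxoalkylresorcinol synthase)
enzymes, restricted to bryophytes and charophyte algae, are required for
cuticle integrity. Surveys of new genomes therefore need a reproducible
procedure that takes a bag of candidate protein sequences and answers: which
are genuine type III PKSs, and which of those are ASCL, ORS, or neither?

`pks3class` implements that procedure as a pipeline of small, testable
stages:

1. **Candidate validation.** A sequence is accepted as a type III PKS only
   if it carries the catalytic Cys-His-Asn triad at positions homologous to
   an annotated reference, and the (G/A)FGPG signature motif.
2. **Subfamily classification.** Class labels are called from diagnostic
   residues read at reference-numbered coordinates: Gly225 and (Ala/Val)240
   for ASCL (numbering on the ASCL reference), Gln218, (Val/Ala)277 and
   Ala286 for ORS (numbering on the ORS reference). Coordinates are
   transferred onto each query through a global pairwise alignment.
3. **Phylogeny.** A multiple alignment (in-house progressive aligner, or an
   imported external MSA) feeds maximum likelihood pairwise distances under
   the JTT model, a neighbor-joining tree, nonparametric bootstrap support
   and outgroup rooting.
4. **Clade analysis.** Monophyly tests, placement of queries relative to
   labeled references, and a concordance report comparing residue-based and
   tree-based labels.

Every coordinate exposed to the user is 1-based and inclusive, matching the
field's residue-numbering convention ("Gly225").

## Residue classification

### Numbering transfer

Diagnostic positions are annotations on a *reference* sequence; queries
differ from the reference by substitutions and indels. `align_to_reference()`
computes a Needleman–Wunsch global alignment (BLOSUM62, affine gaps, open
11 / extend 1 — the standard protein defaults, overridable via
`default_scoring()`) and `map_position()` walks the alignment columns to
answer "which query residue sits at reference position 225?". A reference
position facing a gap maps to nothing and can never satisfy a requirement;
neither can the unknown residue X.

Each class's diagnostic set is evaluated through *that class's own
reference* — ASCL positions through the ASCL reference alignment, ORS
positions through the ORS alignment — exactly mirroring how the positions
are defined in the literature. The label logic is:

* `not_PKSIII` — triad incomplete, motif absent, or no reference alignment
  reaches the configured score floor;
* `ASCL` / `ORS` — the full diagnostic set of exactly one class satisfied;
* `ambiguous` — both full sets satisfied (not silently resolved; the
  surveys this mirrors never encounter the case);
* `other_PKSIII` — a validated PKS with neither full set.

The signature motif is accepted anywhere in the sequence by default. Its
canonical location near the C-terminus is annotated on the references, but
fusion proteins and fragmentary gene models shift absolute positions, so
requiring the canonical location would create false negatives; the report
lists the observed motif positions so a reader can check.

### Fusion proteins

Algal gene models regularly fuse a PKS domain to unrelated domains. Any
sequence flagged as a fusion, or longer than 1.7× the reference, is first
reduced to the query segment covered by the best *local* alignment to a
reference, padded by a 10-residue margin (`extract_pks_domain()`). A local
score floor (default 100 bits in BLOSUM62 half-bit units) guards against
"extracting" a domain from an unrelated protein.

## Phylogenetic stage

### JTT distances

`jtt_distance()` estimates pairwise divergence (expected substitutions per
site) by maximizing the likelihood of the aligned residue pairs under the
Jones–Taylor–Thornton substitution model, using the published
exchangeabilities and equilibrium frequencies and equal rates across sites.
The rate matrix is scaled to one expected substitution per site at
equilibrium, so branch lengths are in substitutions/site. Columns with a
gap or X in either row are dropped per pair (pairwise deletion; complete
deletion would discard most columns in gappy alignments). The 1-D
likelihood search is a golden-section maximization on [0, 10]; estimates at
the cap of 10 substitutions/site are flagged saturated rather than trusted.
A unit test verifies the optimum against a likelihood grid search whose
transition matrices come from an independent series matrix exponential, and
against `phangorn::dist.ml` as an independent implementation.

### Trees, support, rooting

Neighbor joining (Saitou–Nei, via ape) builds the tree; negative branch
lengths, an artifact of the least-squares update, are clamped to zero with
the clamped total recorded. `bootstrap_support()` resamples alignment
columns with replacement, rebuilds distances and the NJ tree per replicate,
and reports for each internal edge of the point tree the percentage of
replicates containing the same bipartition. Replicate *r* uses a seed
derived deterministically from (seed, r), so runs are exactly reproducible.
The default replicate count in the pipeline is 1,000; tests and the
acceptance run use 20–100 to keep runtimes in seconds-to-minutes.

Rooting places the root at the midpoint of the branch subtending the
designated outgroup (a cyanobacterial PKS in the motivating survey), which
preserves all leaf-to-leaf path lengths; bootstrap labels are moved with
their edges. An optional `nni_refine()` stage hill-climbs over
nearest-neighbor interchanges under a least-squares criterion
(nonnegative branch lengths refit per topology) and never accepts a
worsening move. It is a deliberate simplification of likelihood-based NNI
refinement: the package's scope is distance-based reproduction of
topology-level results, not full ML tree search.

### The progressive aligner

The built-in `progressive_align()` builds a guide tree by neighbor joining
on k-mer distances (k = 3, `1 − shared/min` over distinct k-mer sets),
midpoint-roots it, and aligns profiles up the tree. Profile columns are
residue-frequency vectors; the column score is the substitution-matrix
bilinear form, with the same affine gap convention as the pairwise aligner
(a length-k gap costs open + k·extend, end gaps penalized). For two
sequences this reduces exactly to optimal pairwise alignment — a property
the tests assert against an exhaustive-enumeration oracle and against
`Biostrings::pairwiseAlignment` scores. There is no iterative refinement:
for maximum-fidelity work an externally computed alignment (e.g. MUSCLE)
can be supplied through `import_alignment()`, which validates row lengths,
ids and alphabet. Columns are never filtered by default.

## Clade analysis

Clade operations require a rooted tree. `assign_query_to_clade()` walks
from the query toward the root and lets the first ancestor containing a
labeled reference decide; only references vote, so placement mirrors
dropping an unknown sequence into a labeled tree, and a mixed first
ancestor yields `"unplaced"` rather than a forced call.
`count_maximal_clades()` counts ancestor-free nodes whose entire leaf set
satisfies a predicate; singleton leaves count as clades, which matters when
counting, say, separate algal clades in a tree where one algal sequence
sits alone on a branch. `concordance_report()` joins the residue labels
with the clade assignments; residue evidence and phylogeny are reported
side by side with a concordance flag, never collapsed into a single forced
label, because the two lines of evidence are logically independent and a
disagreement is itself a finding.

## The synthetic data generator

Real reference sequence sets cannot be bundled, and unit tests should not
depend on downloads, so `generate_dataset()` fabricates families with the
statistical structure the analysis assumes:

* a 400-residue background drawn from the JTT equilibrium frequencies (so
  subsequent evolution is stationary), with the triad planted at the
  classic chalcone-synthase coordinates (Cys164, His303, Asn336), the
  GFGPG signature near the C-terminus (372–376), and the ASCL/ORS
  diagnostic residues at their published coordinates (225/240 and
  218/277/286);
* one reference scaffold per class, each a diverged homolog of the shared
  background (0.5 substitutions/site by default, substitutions only, so the
  canonical annotation coordinates still hold); the class's own diagnostics
  are planted and the other classes' diagnostic positions are held at
  disallowed residues;
* families evolved along random trees under JTT with optional indels
  (geometric lengths, mean 3; rate 0.002 events/site per substitution/site
  — a few events per typical path, enough to exercise coordinate
  remapping without shredding the alignment); with
  `preserve_diagnostics = TRUE` every annotated position is held invariant
  and indels keep a 5-residue buffer away, and planted coordinates are
  remapped through every accepted indel;
* random trees with branch lengths bounded away from zero
  (uniform + 0.1, rescaled to the target height), so every internal edge
  carries an identifiable number of expected substitutions — a simulator
  for testing topology recovery should not plant unrecoverable edges;
* optionally, fusion decoration (random flanks) and a highly diverged
  generic-PKS outgroup.

`survey_spec()` fixes the composition to the published survey of plant and
algal type III PKSs — one cyanobacterial outgroup, 35 algal non-ORS/
non-ASCL sequences in five families, 12 charophyte ORS, 11 bryophyte ORS,
14 embryophyte ASCL and 7 embryophyte non-ORS/non-ASCL sequences, with the
four *Takakia lepidozioides* sequences comprising 1 ASCL + 2 ORS + 1 other
— so the survey's census can be reproduced end-to-end from synthetic data
with known truth.

What the generator does *not* emulate: site-rate heterogeneity, structural
or functional constraint beyond the planted positions, compositional bias,
alignment uncertainty in the references, or real paralog histories. In
particular, same-class families radiate from their class scaffold rather
than being interleaved with other lineages along a constrained backbone, so
on the inferred tree adjacent same-class families can coalesce into one
maximal clade — the count of separate algal clades is reported as computed
and may fall below the number of generated families.
Passing the synthetic recovery tests therefore demonstrates that the
pipeline's logic is correct under its own model assumptions — it does not
certify performance on real, messier data, where the external-MSA route
and manual inspection of the evidence report are recommended.

## Numerical and design choices

* **Determinism.** Every stochastic component (generator, bootstrap) is
  seeded; replicate streams are derived from (seed, replicate). Two runs
  with the same config and seed produce byte-identical classification
  tables and Newick files, and a test asserts this.
* **Tie-breaking.** The profile aligner prefers substitution over a gap in
  the second profile over a gap in the first at equal score; NJ inherits
  ape's fixed lowest-index pair joining. Results are reproducible across
  runs and platforms.
* **Degenerate inputs.** Empty FASTA files, ragged alignments, duplicate
  ids, annotation positions beyond the reference length, and references
  violating their own annotations (the classic off-by-one numbering drift)
  all fail fast with named errors rather than propagating silently.
* **Saturation.** Pairs with no shared gap-free columns are an error named
  after the offending pair; pairs at the distance cap are flagged, and only
  an all-saturated matrix aborts a run.
* **Problem sizes.** The test suite runs the survey mirror (80 sequences,
  ~400 aa) for classification, and smaller family sets (6–16 sequences)
  with 10–100 bootstrap replicates for tree-level checks; the acceptance
  script runs the full 80-taxon pipeline with 100 bootstrap replicates.
  These sizes make the whole suite run in about a minute while exercising
  every stage at survey scale.

## Known limitations

* NJ + bootstrap reproduces topology-level conclusions; branch lengths and
  supports will differ from likelihood-based tools, and the optional NNI
  stage optimizes least squares, not likelihood.
* The classifier trusts the reference annotations; a mis-annotated
  reference shifts every call (the self-consistency validator exists
  precisely to catch this at load time).
* `ambiguous` and `unplaced` are deliberate refusals to guess; downstream
  consumers must handle them.
* The bundled survey composition ships with synthetic sequences only; to
  analyze real data, supply real FASTA inputs and a real reference set via
  `load_reference_profiles()`.
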