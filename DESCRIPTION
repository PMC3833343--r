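Package: olfdiverge
Title: Comparative Molecular Evolution and Antennal Receptivity of
    Mosquito Chemosensory Gene Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing the chemosensory gene repertoires of two
    sibling mosquito species from ortholog pairs and single-replicate
    antennal RNA-seq. Implements pairwise codon-counting estimators of
    dN/dS (Nei-Gojobori style) and of the radical-to-conservative
    nonsynonymous rate ratio dR/dC under the Dayhoff residue classes,
    transmembrane-region and charged-residue substitution profiling,
    orthologous-group delineation with gene gain/loss reconciliation from
    bootstrap-annotated gene trees, RPKM quantification with a
    conservative posterior ("reliable") log2 fold change for
    single-replicate comparisons, pseudo-reference construction by
    substituting fixed interspecific differences into a reference genome,
    and an RPKM-weighted antennal odorant-receptivity model with
    Fisher-exact chemical-class enrichment. A synthetic-data generator
    with recorded ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils,
    vcfR,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
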