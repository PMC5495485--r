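Package: chromoflip
Title: Detection, Reconstruction and Simulation of Integrase-Driven
    Chromosomal Inversions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying large-scale chromosomal inversions mediated
    by mobile-element integrases in archaea. Detects inversions and synteny
    breakpoints between closely related genomes by exact-match anchoring and
    chaining, characterizes the inverted-repeat substrates at breakpoints,
    reconstructs parsimonious sequential inversion scenarios restricted to
    repeat-pair endpoints, models site-specific and low-sequence-specificity
    recombination reactions on annotated DNA maps (including restriction
    digest and PCR product prediction), and genotypes inversion alleles and
    plasmid copy number from short sequencing reads. A bundled simulator
    generates genomes with planted repeat pairs, derived genomes via sampled
    inversion histories, mixed-population reads and construct maps with
    known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
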