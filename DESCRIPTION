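Package: prmfrac
Title: Targeted Proteomics Quality Control of Subcellular Fractions by
    Parallel Reaction Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for assessing the purity of cytosolic, mitochondrial
    and nuclear subcellular fractions with parallel reaction monitoring
    (PRM) assays. Designs proteotypic-peptide transition panels from
    protein sequences (in-silico tryptic digestion, candidate filtering,
    b/y fragment-ion monoisotopic mass arithmetic), ships a curated
    marker-protein panel, quantifies transitions from centroided mzML PRM
    runs by extracted-ion-chromatogram integration with peptide-level
    area summation, and scores compartment enrichment with enrichment
    ratios, replicate CV%, one-way ANOVA and Tukey's HSD. Includes a
    synthetic PRM run simulator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mzR,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
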