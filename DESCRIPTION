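Package: ticdiff
Title: Label-Free Differential Protein Abundance from Fragment-Ion Total Ion Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free quantitative proteomics based on protein
    total ion counts (TIC), the per-protein sum of MS/MS fragment-ion
    intensities over identified peptides. Reads peptide-spectrum-match
    tables and Mascot Generic Format spectra, rolls peptide intensities up
    to a protein-by-sample log2 expression matrix with detection calls, and
    tests for differential abundance between two strains with either a
    single-replicate z-score rule (95% cut-off) or a two-replicate
    signal-to-noise (Wstat) statistic with a fold-change filter. Includes
    compartment annotation, Venn overlap analysis against stress
    signatures, hypergeometric category enrichment, closed-form arithmetic
    for membrane and oxidative-stress assays (Laurdan fluidity ratios,
    acyl-chain percentages, relative ergosterol, catalase units, DCF ROS),
    and a synthetic PSM generator with ground truth for validating every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
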