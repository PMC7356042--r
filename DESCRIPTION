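Package: lipmrm
Title: Target Deconvolution from DARTS and Targeted Limited-Proteolysis MRM Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and localizing small-molecule protein targets
    from limited-proteolysis experiments. Implements DARTS (drug affinity
    responsive target stability) protection scoring from spectral-match count
    tables and gel-lane densitometry, in silico tryptic digestion with
    monoisotopic precursor m/z calculation, deterministic MRM transition
    planning, replicate-level fold-change and significance testing for targeted
    limited-proteolysis (t-LiP-MRM) peptide areas, peptide-to-domain mapping
    with orthosteric classification against active-site residue lists, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation of the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
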