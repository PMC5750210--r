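Package: neoedit
Title: Cancer Cell Fraction Inference and Neoantigen Immunoediting Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers per-mutation cancer cell fractions (CCF) from somatic
    variant read counts corrected for tumor purity and local copy number,
    classifies mutations as clonal or subclonal by a grid posterior with a
    95% credible interval or by mutation-multiplicity maximum likelihood,
    clusters clonal architecture with a Dirichlet-process mixture of
    binomials within and between paired samples, applies MHC class I
    neoantigen filters (binding affinity and expression), and produces
    replicate-aware immunoediting reports of mutation and neoantigen gain
    and loss between sample groups. Includes a synthetic tumor-sequencing
    cohort generator with ground truth so the whole pipeline can be
    exercised and validated without external data.
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
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
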