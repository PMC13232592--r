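Package: hidecore
Title: Cross-Species Differential Expression and Regulatory Network
    Analysis of the Infant Prefrontal Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative single-nucleus transcriptomics of the
    developing primate brain: pseudobulk negative-binomial Wald
    differential expression between species, construction of human and
    chimpanzee infant-specific differentially expressed gene sets
    (hiDE/ciDE), overrepresentation and directionality statistics against
    disease risk genes and patient expression changes, gene module score
    trajectories across developmental age, and construction of the
    hiDECORE regulatory network from regulon edges mediated by open
    chromatin carrying human-specific sequence changes (HARs, hINS,
    hDEL). Includes a synthetic data generator with planted ground truth
    so the full pipeline can be exercised and validated without access
    to restricted primary data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
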