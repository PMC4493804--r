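Package: rispipe
Title: Retroviral Vector Integration Site Mapping from LTR-Junction Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies retroviral vector integration sites (RISs) from
    next-generation sequencing reads that span LTR-chromosome junctions.
    Trims LTR and linker-cassette sequence to produce genomic queries,
    aligns them against a reference genome plus the vector, filters
    alignments that cannot be placed unequivocally, clusters candidate
    sites within a +/- 5 bp window into unique RISs with read frequency
    and distinct shear-span counts, annotates each site with gene, TSS
    and custom-feature proximity, and compares the observed integration
    profile against matched random-site controls with a Pearson
    chi-squared goodness-of-fit test. Includes a deterministic built-in
    aligner and a synthetic-data simulator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
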