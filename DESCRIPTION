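Package: mfclone
Title: Clonality and Cross-Modal Analysis of Multifocal Hepatocellular Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify pairs of synchronous liver tumours as
    multicentric occurrence (independent primaries, MO) or intrahepatic
    metastasis (clonally related, IM) from the Jaccard index of shared
    somatic mutations, with supporting per-lesion burden metrics (tumour
    mutational burden, an exome-wide copy-number burden score,
    microsatellite-instability status), trinucleotide mutational-signature
    exposure fitting, two-lesion phylogenies, H&E nucleus morphometry with
    inter-focus feature correlation, cohort-level group comparisons and
    survival analysis, and a seeded synthetic-cohort generator so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    grDevices,
    jsonlite,
    png,
    pracma,
    stats,
    survival,
    utils,
    withr
Suggests:
    ape,
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
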