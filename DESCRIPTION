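Package: sketchlmm
Title: Sketched Linear Mixed Models for Genome-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fast linear mixed-model (LMM) association testing for
    genome-wide association studies using Gaussian matrix sketching.
    The genotype matrix is compressed with seeded random projections on
    both the sample and marker dimensions before the genetic relationship
    matrix (GRM) is formed, so variance components can be estimated by
    Newton's method on a small sketched spectrum and per-marker chi-squared
    score statistics computed against the sketched model. Includes a
    streaming PLINK BED/BIM/FAM reader and writer, principal-component
    covariate construction in sketched-sample space, and a
    mosaic-chromosome genotype and trait simulator with two-population
    founders for end-to-end testing without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
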