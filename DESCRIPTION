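Package: venomevol
Title: Experimental Evolution of Parasitoid Venom Composition from 1D Gel
    Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for experimental-evolution studies of
    parasitoid wasp venom characterized by 1D SDS-PAGE densitometry.
    Provides lane-profile processing (morphological background removal,
    prominence-based peak calling, reference-band matching, quantile
    normalization), distance-based permutational MANOVA with permutations
    constrained within replicates, replicate-centered linear discriminant
    analysis of host-by-generation groups, identification of directly
    selected protein bands through correlation clustering and partial
    correlations, a forward-time haplodiploid Wright-Fisher simulator with
    a doubled unilateral drift test for codominant and dominant venom
    markers, and a Box-Cox mixed-model stage with Tukey comparisons for
    continuous markers. A seeded synthetic-data module emulates the full
    study design so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    multcomp,
    nlme,
    rlang,
    stats,
    utils
Suggests:
    limma,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
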