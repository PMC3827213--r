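Package: cyanoshsp
Title: Motif Annotation, Classification and Phylogeny of Cyanophage and
    Cyanobacterial Small Heat Shock Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing small heat shock proteins (sHSPs) of marine
    cyanophages and their Synechococcus/Prochlorococcus hosts. Implements a
    PROSITE-style pattern engine with the cyanophage signature
    P-P-[YF]-N-[ILV]-[IV]-x(9)-[EQ], PSSM-based delimitation of the
    alpha-crystallin domain (ACD), N-terminal arm and C-terminal extension,
    detection of C-terminal anchoring motifs (classical L-X-I/L/V, the
    A-X-P/L-X-G/L-X-A variants and the hydrophobic triple
    I/V-X-I/L/V-X-I/L/V), A-G and P-G doublets, the conserved beta7 arginine
    and acidic salt-bridge partners in the L57 loop, a rule cascade assigning
    sequences to cyanophage-like, bacterial class A-like, class B/plant-like
    or cyanobacterial-like groups, Poisson-corrected distances with BioNJ
    trees restricted to the ACD plus C-terminal extension, and a seeded
    simulator of labelled sHSP families evolved along a phylogeny.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: MAFFT (for progressive_align())
Config/testthat/edition: 3
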