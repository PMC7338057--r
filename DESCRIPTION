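Package: apaqtl
Title: Alternative Polyadenylation Quantification and cis-apaQTL Mapping
    from 3' Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying alternative polyadenylation (APA) from
    3'-end sequencing and linking it to genetic variation. Implements
    internal-priming read and site filters, multi-library coverage peak
    calling of polyadenylation sites (PAS), hierarchical gene assignment,
    usage-ratio quantification, polyadenylation signal-site scanning,
    Dirichlet-multinomial differential usage testing between nuclear and
    total mRNA fractions, permutation-based cis-apaQTL mapping with
    Benjamini-Hochberg FDR control, and cross-dataset sharing statistics
    (Storey pi1, effect-size concordance, category enrichment, annotation
    overlap bootstrap). Includes a fully self-contained synthetic-study
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
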