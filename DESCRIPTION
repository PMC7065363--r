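Package: methylosip
Title: DNA Stable-Isotope-Probing Analysis and Methanol-Dehydrogenase
    Gene Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for DNA stable-isotope-probing (SIP) experiments
    targeting methylotrophic bacteria. Converts refractometer readings
    to CsCl buoyant densities and designates gradient fractions as heavy
    or light; applies a multi-criterion decision rule (abundance floor,
    heavy-versus-heavy comparison, k-fold heavy/light enrichment, and
    unplanted-control exclusion) to call taxa as 13C labelled from
    fraction-resolved relative-abundance tables; designs degenerate PCR
    primers by scanning DNA alignments for conserved 18-20 nt windows
    and screens them in silico; quantifies methanol-dehydrogenase gene
    clades (mxaF, xoxF1-xoxF5, mdh2) from metagenome hit tables with
    length and read-depth normalization and recA-relative percentages,
    and from qPCR dilution series with standard-curve fitting and 16S
    normalization. Includes a synthetic-experiment generator with known
    labelled, cross-feeding and autotrophic taxa for validating every
    stage without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
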