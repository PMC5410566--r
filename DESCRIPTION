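Package: dnajfam
Title: Genome Survey Toolkit for DnaJ/Hsp40 (J-Protein) Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for genome-wide surveys of the
    DnaJ/Hsp40 (J-protein) co-chaperone gene family: candidate filtering on
    J-domain completeness, five-group domain-architecture classification
    (J-domain, HPD tripeptide, CxxCxGxG zinc-finger repeats, C-terminal
    extent), chromosome-ordered family naming, tandem-duplication detection
    by distance, coverage and identity criteria, protein molecular weight and
    theoretical isoelectric point, promoter cis-element scanning with IUPAC
    motifs (heat-shock elements and hormone/stress motifs), tissue
    expression-pattern profiling with hierarchical clustering, and qPCR
    relative expression by the 2^-ddCt method. Ships the published pepper
    (Capsicum annuum) 76-member CaDnaJ catalog as a typed fixture and a
    synthetic-data generator that plants known domain architectures, tandem
    duplicates, promoter motifs and expression/Ct signals with
    machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    ape,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
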