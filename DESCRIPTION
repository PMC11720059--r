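Package: spliceneo
Title: Splice-Junction Neoantigen Candidate Evaluation with Patient
    Harmonic-Mean Best Rank Scores
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packaged", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluates tumor splice-junction events as neoantigen
    candidates. From per-sample aligned reads, splice-junction catalogs
    of normal controls, and patient HLA genotypes, the pipeline extracts
    junction-spanning reads, assembles isoform contigs, selects the
    expressed reading frame by local protein alignment, enumerates
    junction-spanning peptide k-mers, and aggregates per-allele MHC
    binding ranks into Patient Harmonic-mean Best Rank (PHBR) scores.
    Matched wild-type junctions are scored for comparison, principal
    candidates are filtered, and responder versus nonresponder
    differential-binding summaries are produced.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    tools,
    utils
Suggests:
    Rsamtools,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
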