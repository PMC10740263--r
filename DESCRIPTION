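Package: igprofile
Title: Profile HMM Annotation of Immunoglobulin Variable Domains Under IMGT Numbering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds profile hidden Markov models from user-supplied V- and
    J-region germline amino-acid sequences for any species, aligns antibody
    sequences to them under the IMGT unique numbering scheme, merges multiple
    partial alignments from the same variable domain into one consensus
    numbering (so ultralong CDR3 loops, as found in cattle, are annotated
    without any length cap), validates the consensus with heuristics derived
    from the model, and extracts the seven framework and
    complementarity-determining regions (FR1-FR4, CDR1-CDR3) as FASTA and BED.
    Supports reduced amino-acid alphabets (20 down to 3 symbols), six-frame
    translation with stop-codon filtering for nucleotide input, a model
    registry, a deterministic synthetic-repertoire generator with ground-truth
    region coordinates, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    Biostrings,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
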