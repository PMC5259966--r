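Package: protlang
Title: Amino-Acid n-Gram Language Models for Protein Sequence Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds amino-acid n-gram Markov models from labeled protein
    corpora and combines them with class priors into a naive-Bayes log-odds
    decision rule that screens query protein sequences for their probability
    of being native human gene-coding proteins. Includes FASTA input with
    residue sanitization, maximum-likelihood estimation with optional additive
    smoothing, held-out perplexity for model-order selection, a greedy
    sequence-identity clustering stage for training-corpus de-duplication,
    and a fully seeded Markov-chain simulator for generating labeled
    protein-like corpora used in parameter-recovery and classification-power
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
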