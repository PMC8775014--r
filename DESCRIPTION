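Package: pmmcodec
Title: Lossless Sequence Compression with Partition Markov Models and
    Canonical Huffman Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Partition Markov Models (PMMs) to categorical sequences
    over a finite alphabet by Bayesian Information Criterion (BIC)
    maximisation, builds conditional canonical Huffman codebooks per state
    or per part, and serialises model plus data into a self-describing
    bitstream with exact per-field bit accounting. Grouping Markov states
    into parts that share a conditional transition law shrinks the model
    description transmitted alongside the coded data, improving total
    compression for sources such as DNA sequences. The fitted PMM also
    yields a plug-in estimate of the process entropy, the minimum expected
    codeword length per symbol. Includes a simulator for PMM-generated
    sequences, by-states versus by-parts benchmark experiments, FASTA
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    rlang,
    seqinr,
    stats,
    tibble
Suggests:
    dplyr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
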