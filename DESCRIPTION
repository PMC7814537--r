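Package: pairconsensus
Title: Pair Consensus Decoding of CTC Basecaller Probability Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consensus decoding for nanopore-style CTC basecaller output.
    Given two softmax probability profiles derived from the same DNA duplex
    (for example the template and complement reads of a 1D2 pair), finds the
    single sequence maximizing the product of the per-read sequence
    probabilities with a banded two-dimensional prefix beam search. The band
    is an alignment envelope built from a preliminary Viterbi decoding of each
    read, a banded Needleman-Wunsch guide alignment of the two basecalls, and
    a sequence-to-signal map. Includes single-read CTC decoders (Viterbi,
    prefix beam search, exhaustive enumeration for testing), profile and FASTA
    input/output, an identity evaluator, and a ground-truthed simulator of
    softmax profiles so the whole system runs without real reads or a trained
    neural network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    tibble,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
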