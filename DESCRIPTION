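Package: premascan
Title: Microhomology-Mediated End Joining Deletion Prediction and Target-Site Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the deletion alleles produced by microhomology-mediated
    end joining (MMEJ) at programmable-nuclease cut sites. Enumerates direct
    sequence repeats (microhomology arms of at least 3 bp) flanking a
    double-strand break, scores each candidate deletion with the Bae-style
    Pattern Score, and classifies loci by a two-criterion competition scheme
    (arm spacing of at most 5 bp; top-to-second score ratio of at least 1.5)
    into four groups, recommending Group 4 sites as likely to yield a single
    predominant MMEJ allele (PreMA). Includes a PAM/TALEN scanner over FASTA
    input, repair-outcome accounting from observed allele tables (mutagenic
    efficiency, Microhomology Fraction, Top MH Fraction, PreMA call), and a
    synthetic-locus generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
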