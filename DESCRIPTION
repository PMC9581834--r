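Package: ppcdss
Title: Privacy-Preserving Similar-Patient Queries via Secure Multiparty
    Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clinical decision support without data pooling: clinicians
    additively secret-share patient records (mutation-indicator genotype
    bit strings, treatment, time-to-treatment-failure) among non-colluding
    computing parties, and a querying clinician learns the average
    time-to-treatment-failure per treatment over patients whose genotype
    lies within a Hamming-distance threshold of the query genotype -- and
    nothing else. Implements exact prime-field arithmetic up to 128 bits,
    additive n-out-of-n secret sharing, a trusted-dealer offline phase
    (Beaver multiplication triples and shared random bits), an oblivious
    online engine (opening, Beaver multiplication, XOR, Hamming distance,
    statistically masked threshold comparison, masked aggregation), a
    plaintext reference oracle, a synthetic cohort generator, and cost
    accounting that certifies obliviousness and linear scaling in the
    database size.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
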