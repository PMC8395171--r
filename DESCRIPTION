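Package: oligofish
Title: Cross-Species Oligo-FISH Chromosome Painting Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening oligonucleotide chromosome-painting
    libraries against a target genome with a matched-length retention rule,
    deriving per-chromosome probe count matrices and windowed density
    profiles, predicting fluorescence in situ hybridization (FISH) signal
    patterns, planning sequential-FISH probe panels that uniquely identify
    every chromosome of a complement, and building karyotype tables and
    idiograms from metaphase arm measurements.  Includes a fully seeded
    synthetic-data generator (reference genome, painting-oligo library,
    diverged polyploid target, noisy arm measurements) with a complete
    ground-truth log for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
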