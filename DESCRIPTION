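Package: deamtest
Title: Authenticity Testing of Ancient DNA from 5' C-to-T Deamination Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to authenticate putatively ancient DNA read sets from
    low-coverage alignments. Computes the 5' C-to-T substitution profile of
    aligned reads (SAM/BAM with MD tags or a reference FASTA), scores its
    exponential decay with a one-sided t-test on the rate of a nonlinear
    least-squares fit, and compares that goodness-of-fit p-value against
    resampling-based empirical distributions built from bona fide ancient or
    modern libraries, yielding an empirical p-value for the ancient origin of
    the test reads. Includes the standard aDNA filtering stack (mapping
    quality, length, trinucleotide-entropy low-complexity filter, coordinate
    duplicate removal), a parameterized deamination read simulator for ground
    truth and power analysis, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    minpack.lm,
    optparse,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
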