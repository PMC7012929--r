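Package: rnadomains
Title: Local Secondary-Structure Domain Detection in Long Non-Coding RNAs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Locates stable local secondary-structure domains in long
    non-coding RNAs. Computes base-pairing probability matrices by a
    McCaskill-style inside-outside partition function under a configurable
    simplified pairing model (with a brute-force enumeration oracle and
    import of externally computed matrices), predicts gamma-centroid
    secondary structures, decomposes sequences into fixed-size blocks and
    scores every run of consecutive blocks by normalized inside and
    inside-outside pairing statistics to extract self-contained structural
    domains. Also provides the sequence, interval, in-vitro T7 transcript
    and concentration-equivalence arithmetic used when designing and dosing
    lncRNA fragments, a seeded synthetic fixture generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
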