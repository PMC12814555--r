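Package: moclosim
Title: Simulation of Golden Gate and Modular Cloning Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and simulating large Golden Gate / Modular
    Cloning (MoClo) campaigns. Simulates Type IIS restriction digestion and
    overhang-directed one-pot assembly for batches of reactions specified in
    tabular campaign files, resolving human part names to a database of
    GenBank plasmid records through mapping tables. Generates the companion
    data needed to run a campaign at the bench: assembled output plasmid
    maps, simulated verification gels (PCR and restriction digests),
    equimolar input-plasmid dilution plans, liquid-handler picklists, and
    bookkeeping tables registering the produced plasmids for reuse. Includes
    a typed-assembly grammar system for MoClo kits and a deterministic
    generator of miniature fixture kits for testing and teaching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
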