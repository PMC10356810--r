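Package: SomaticSelect
Title: Selection of Structural Features in Somatic Missense Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical framework for detecting selection of structural and
    functional features among somatic missense mutations in normal tissues
    and cancers. Builds a neutral null model over every possible coding
    single-nucleotide variant from a trinucleotide mutational spectrum,
    tests observed mutations for enrichment of Boolean features (exact
    two-tailed binomial test) or continuous structural scores such as
    folding free-energy change or distance to a binding partner (two-tailed
    Monte Carlo test), unmasks weaker selection through an iterative
    exclude-and-retest layering procedure, and summarises stability
    selection per gene with an outlier-robust CDF-shift statistic suitable
    for classifying genes as fitness-suppressors or fitness-enhancers.
    Includes a full synthetic-data generator (transcripts, spectra, toy
    structures, free-energy tables, mutation sets with planted selection)
    so every analysis step can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
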