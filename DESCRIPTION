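Package: panEC
Title: Pan- and Core-Genome Analysis of Enzyme Commission Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the functional (Enzyme Commission number)
    repertoire of a bacterial culture collection against metagenomes such as
    human gut microbiomes. Implements homology-based EC annotation transfer
    (e-value filtering, density-based clustering of BLAST hits in
    identity-coverage space, GO-term union with Pfam domain hits, GO-to-EC
    mapping), quality-control filtering of strain assemblies, pan/core EC-set
    algebra with cross-coverage statistics, metabolic superpathway coverage
    summaries with hierarchical clustering, bootstrap resampling nulls for
    strain-set selection, and a synthetic-data generator that emulates the
    statistical structure of such data so the full pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
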