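Package: seedledger
Title: Seed-Stock and Plant-Line Registry with Pedigree, GMO and MTA Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A laboratory registry for plant lines and their genetic features.
    Tracks the inheritance of individual mutations and transgenes through
    crosses and secondary mutagenesis, distinguishes transgenic (GMO) from
    endogenous (non-GMO) modifications, propagates Material Transfer Agreement
    constraints through pedigrees, manages controlled vocabularies with usage
    counting and role-based access, provides SQL-LIKE-style wildcard search,
    renders genealogies as Graphviz DOT, and exchanges lines between databases
    via a redacting JSON interchange format. Includes a command-line interface
    and a seeded synthetic-pedigree generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
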