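Package: taxpub2wiki
Title: Journal-to-Wiki Publishing Bridge for Taxonomic Treatments
Version: 0.1.0
Authors@R:
    person("Species Pages", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Converts taxonomic journal articles marked up in a TaxPub/NLM-style
    XML vocabulary into per-treatment MediaWiki pages, and builds joint
    journal-plus-wiki bibliographic references for versioned wiki pages.
    Parses MediaWiki XML export dumps to attribute contributors to any
    numbered revision of a page, renders the combined reference in plain
    text, BibTeX, RIS and wikitext, and ships deterministic synthetic
    generators for both input formats so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    yaml,
    utils,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    stringi,
    withr
Config/testthat/edition: 3
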