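Package: varkin
Title: Annotate and Compare Direct-to-Consumer Genotype Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates raw direct-to-consumer genotype files (23andMe tab-separated
    dialect) against a variant-effect knowledge base, classifies zygosity,
    carrier status and rarity, partitions annotated variants across two to four
    people into membership classes, applies combinable facet filters and text
    search, and computes deterministic geometry for four comparison views
    (table, linear, sunburst, two-set Venn) with SVG output. Includes a
    Mendelian family simulator (Hardy-Weinberg parents, transmitted children)
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
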