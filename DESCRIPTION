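Package: semnetmine
Title: Semantic Network Mining of MEDLINE Literature Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing MeSH co-occurrence semantic
    networks from plain-text MEDLINE bibliographic records. Parses the
    tag-based PubMed export format, applies reproducible corpus selection
    criteria with an exact exclusion log, treats major-topic (asterisked)
    MeSH terms and descriptor/qualifier combinations as distinct concepts,
    projects the article-concept incidence structure onto weighted
    concept-concept and article-article networks, computes degree/rank
    topology reports and core-periphery partitions, extracts
    seed-plus-first-neighbour induced subnetworks, tallies publications by
    country and year, and generates synthetic MEDLINE corpora with
    Zipf-skewed vocabulary usage for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
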