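test_that("bipartite memberships map records to labels, once each", {
  rec <- bib_record(1L, "T", parse_mesh_field(
    c("Humans", "*Health Equity", "Humans")), 2020L)
  corp <- apply_selection_criteria(list(rec))
  bip <- build_bipartite(corp)
  expect_equal(nrow(bip$memberships), 2L)   # duplicate label collapsed
  expect_setequal(bip$memberships$label, c("Humans", "*Health Equity"))
  merged <- build_bipartite(corp, mode = "merged")
  expect_setequal(merged$memberships$label, c("Humans", "Health Equity"))
})

test_that("an empty corpus projects to an empty graph", {
  bip <- build_bipartite(apply_selection_criteria(list()))
  expect_equal(igraph::vcount(project_concepts(bip)), 0L)
  expect_equal(igraph::vcount(project_articles(bip)), 0L)
})

test_that("the worked four-article corpus yields the hand-enumerated network", {
  net <- project_concepts(build_bipartite(toy_corpus()))
  expect_equal(igraph::vcount(net), 5L)
  expect_equal(igraph::ecount(net), 7L)
  w <- edge_weights(net)
  expect_equal(w[["Health Equity||Humans"]], 2)
  expect_equal(w[["Humans||Vulnerable Populations"]], 2)
  expect_equal(w[["Culture||Humans"]], 2)
  expect_equal(w[["Humans||Trust"]], 1)
  expect_equal(w[["Health Equity||Vulnerable Populations"]], 1)
  expect_equal(w[["Culture||Health Equity"]], 1)
  expect_equal(w[["Culture||Trust"]], 1)
  expect_equal(sum(w), 10)   # C(3,2)+C(3,2)+C(2,2)+C(3,2)
})

test_that("the article projection of the worked corpus matches brute force", {
  corp <- toy_corpus()
  net <- project_articles(build_bipartite(corp))
  w <- edge_weights(net)
  expect_equal(w[["1||2"]], 2)   # share Humans, Health Equity
  expect_equal(w[["1||3"]], 2)   # share Humans, Vulnerable Populations
  expect_equal(w[["2||4"]], 2)   # share Humans, Culture
  expect_equal(w[["1||4"]], 1)
  expect_equal(w[["2||3"]], 1)
  expect_equal(w[["3||4"]], 1)
  expect_equal(w, oracle_article_weights(corp))
})

test_that("one article with m labels projects to a complete graph of weight 1", {
  rec <- bib_record(1L, "T", mesh_entities(sprintf("Label %d", 1:6)), 2020L)
  net <- project_concepts(build_bipartite(apply_selection_criteria(list(rec))))
  expect_equal(igraph::vcount(net), 6L)
  expect_equal(igraph::ecount(net), choose(6, 2))
  expect_true(all(igraph::E(net)$weight == 1))
})

test_that("articles with disjoint and with identical label sets behave as expected", {
  recs <- list(
    bib_record(1L, "T1", mesh_entities(c("A 1", "A 2")), 2020L),
    bib_record(2L, "T2", mesh_entities(c("B 1", "B 2")), 2020L),
    bib_record(3L, "T3", mesh_entities(c("B 1", "B 2")), 2020L))
  net <- project_articles(build_bipartite(apply_selection_criteria(recs)))
  w <- edge_weights(net)
  expect_length(w, 1L)
  expect_equal(w[["2||3"]], 2)   # identical sets of size 2
})

test_that("projections match the pair-enumeration oracle on random corpora", {
  for (seed in 1:25) {
    corp <- small_corpus(seed)
    bip <- build_bipartite(corp)
    expect_identical(edge_weights(project_concepts(bip)),
                     oracle_concept_weights(corp), label = paste("seed", seed))
    expect_identical(edge_weights(project_articles(bip)),
                     oracle_article_weights(corp), label = paste("seed", seed))
  }
})

test_that("edge weights conserve the per-article pair totals", {
  for (seed in c(3, 17, 99)) {
    corp <- small_corpus(seed)
    net <- project_concepts(build_bipartite(corp))
    expect_equal(sum(igraph::E(net)$weight), pairs_per_article_total(corp))
  }
})

test_that("adding an article never decreases a weight or a degree", {
  corp_small <- small_corpus(8)
  extra <- bib_record(
    999999L, "Extra", mesh_entities(c("Concept 001", "Concept 002")), 2020L)
  corp_big <- apply_selection_criteria(c(corp_small$records, list(extra)))
  w1 <- edge_weights(project_concepts(build_bipartite(corp_small)))
  net2 <- project_concepts(build_bipartite(corp_big))
  w2 <- edge_weights(net2)
  expect_true(all(names(w1) %in% names(w2)))
  expect_true(all(w2[names(w1)] >= w1))
  d1 <- igraph::degree(project_concepts(build_bipartite(corp_small)))
  d2 <- igraph::degree(net2)
  expect_true(all(d2[names(d1)] >= d1))
})

test_that("a label on every article is adjacent to every other node", {
  params <- generator_params(n_records = 40L, vocab_size = 30L,
                             universal_prob = 1, seed = 21L)
  corp <- apply_selection_criteria(generate_corpus(params))
  net <- project_concepts(build_bipartite(corp))
  expect_equal(unname(igraph::degree(net)["Humans"]),
               igraph::vcount(net) - 1L)
})

test_that("minimum-weight filtering drops weak edges but keeps nodes", {
  net <- project_concepts(build_bipartite(toy_corpus()))
  f <- filter_min_weight(net, 2)
  expect_equal(igraph::vcount(f), 5L)
  expect_equal(igraph::ecount(f), 3L)
  expect_true(all(igraph::E(f)$weight >= 2))
})

test_that("edge lists round-trip through the TSV export", {
  net <- project_concepts(build_bipartite(toy_corpus()))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 7L)
  expect_equal(sort(names(back)), c("source", "target", "weight"))
  expect_equal(sum(back$weight), 10)
})
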