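star_graph <- function(leaves = 5L) {
  g <- igraph::make_star(leaves + 1L, mode = "undirected", center = 1L)
  igraph::V(g)$name <- c("center", sprintf("leaf %d", seq_len(leaves)))
  igraph::E(g)$weight <- 1
  g
}

test_that("star-graph statistics match the closed form", {
  rep5 <- compute_node_stats(star_graph(5L))
  expect_equal(rep5$nodes$label[1L], "center")
  expect_equal(rep5$nodes$k[1L], 5L)
  expect_equal(rep5$nodes$R[1L], 1L)
  expect_true(all(rep5$nodes$k[-1L] == 1L))
  expect_equal(rep5$global$density, 1 / 3)
  expect_equal(rep5$global$components, 1L)
  # center closeness 1 (adjacent to everything), leaves 5/9
  expect_equal(rep5$nodes$closeness[1L], 1)
  expect_equal(rep5$nodes$closeness[2L], 5 / 9)
})

test_that("complete-graph statistics match the closed form", {
  g <- igraph::make_full_graph(6L)
  igraph::V(g)$name <- sprintf("v%d", 1:6)
  igraph::E(g)$weight <- 1
  rep6 <- compute_node_stats(g)
  expect_true(all(rep6$nodes$k == 5L))
  expect_equal(rep6$global$density, 1)
  expect_true(all(rep6$nodes$clustering == 1))
  expect_true(all(rep6$nodes$betweenness == 0))
})

test_that("the worked corpus ranks with ties broken by label", {
  net <- project_concepts(build_bipartite(toy_corpus()))
  rep4 <- compute_node_stats(net)
  got <- stats::setNames(rep4$nodes$R, rep4$nodes$label)
  expect_equal(got[["Humans"]], 1L)
  expect_equal(got[["Culture"]], 2L)        # k=3 tie, C before E
  expect_equal(got[["Health Equity"]], 3L)
  expect_equal(got[["Trust"]], 4L)          # k=2 tie, T before V
  expect_equal(got[["Vulnerable Populations"]], 5L)
  expect_equal(stats::setNames(rep4$nodes$k, rep4$nodes$label),
               c(Humans = 4L, Culture = 3L, `Health Equity` = 3L,
                 Trust = 2L, `Vulnerable Populations` = 2L))
  expect_equal(stats::setNames(rep4$nodes$strength, rep4$nodes$label)[["Humans"]], 7L)
})

test_that("rank is a bijection, non-increasing in degree, order-independent", {
  for (seed in 1:30) {
    g <- random_network(seed)
    rep_g <- compute_node_stats(g)
    expect_setequal(rep_g$nodes$R, seq_len(igraph::vcount(g)))
    expect_true(all(diff(rep_g$nodes$k) <= 0L))
    # permute vertex order; the label -> rank map must not change
    perm <- with_seed_local(seed + 1000, sample(igraph::vcount(g)))
    g2 <- igraph::permute(g, perm)
    rep_g2 <- compute_node_stats(g2)
    m1 <- stats::setNames(rep_g$nodes$R, rep_g$nodes$label)
    m2 <- stats::setNames(rep_g2$nodes$R, rep_g2$nodes$label)
    expect_identical(m1[order(names(m1), method = "radix")],
                     m2[order(names(m2), method = "radix")])
  }
})

test_that("handshake and histogram invariants hold on random networks", {
  for (seed in c(2, 12, 77)) {
    g <- random_network(seed)
    rep_g <- compute_node_stats(g)
    expect_equal(sum(rep_g$nodes$k), 2L * igraph::ecount(g))
    expect_equal(sum(rep_g$global$degree_distribution$count),
                 igraph::vcount(g))
  }
})

test_that("closeness of isolated nodes is zero; components are scaled", {
  g <- igraph::make_graph(~ a - b, c)   # one edge plus an isolate
  igraph::E(g)$weight <- 1
  rep_g <- compute_node_stats(g)
  cls <- stats::setNames(rep_g$nodes$closeness, rep_g$nodes$label)
  expect_equal(cls[["c"]], 0)
  expect_equal(cls[["a"]], 1 / 2)   # (2-1)/(3-1) * (2-1)/1
  expect_equal(rep_g$global$components, 2L)
})

test_that("empty networks are rejected", {
  expect_error(compute_node_stats(igraph::make_empty_graph(0)), "empty")
})

test_that("top_ranked truncates and preserves rank order", {
  net <- project_concepts(build_bipartite(toy_corpus()))
  rep4 <- compute_node_stats(net)
  expect_equal(top_ranked(rep4, 1L)$label, "Humans")
  expect_equal(nrow(top_ranked(rep4, 3L)), 3L)
  expect_equal(nrow(top_ranked(rep4, 100L)), 5L)
  expect_equal(top_ranked(rep4, 100L)$R, 1:5)
})

test_that("core-periphery splits by degree quantile", {
  rep_star <- compute_node_stats(star_graph(5L))
  cp <- core_periphery(rep_star, 0.1)
  expect_equal(sum(cp == "core"), 1L)
  expect_equal(names(cp)[cp == "core"], "center")
  rep4 <- compute_node_stats(project_concepts(build_bipartite(toy_corpus())))
  cp4 <- core_periphery(rep4, 0.4)
  expect_setequal(names(cp4)[cp4 == "core"],
                  c("Humans", "Culture", "Health Equity"))
  expect_length(cp4, 5L)
  expect_error(core_periphery(rep4, 1.0), "between")
  expect_error(core_periphery(rep4, 0), "between")
})

test_that("the report exports to CSV plus JSON global statistics", {
  rep4 <- compute_node_stats(project_concepts(build_bipartite(toy_corpus())))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_topology_report(rep4, csv, js)
  back <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(back$label, rep4$nodes$label)
  glob <- jsonlite::read_json(js)
  expect_equal(glob$nodes, 5L)
  expect_equal(glob$edges, 7L)
  expect_equal(sum(unlist(glob$degree_histogram)), 5L)
})
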