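test_that("integration collapses orientation, drops self-loops, unions
          sources", {
  net <- integrate_edge_lists(list(
    s1 = data.frame(a = "ga", b = "gb"),
    s2 = data.frame(a = "gb", b = "ga")))
  expect_equal(nrow(net$edges), 1)
  expect_setequal(net$nodes, c("GA", "GB"))
  expect_true(all(net$sources))

  net2 <- integrate_edge_lists(data.frame(a = c("ga", "ga"),
                                          b = c("ga", "gb")))
  expect_equal(nrow(net2$edges), 1)   # self-loop dropped

  expect_error(integrate_edge_lists(data.frame(a = "x", b = "x")),
               "empty")
})

test_that("the union of overlapping sources matches an independent
          hand-enumeration", {
  s1 <- data.frame(a = c("a", "b", "c", "d", "e"),
                   b = c("b", "c", "d", "e", "f"))
  s2 <- data.frame(a = c("b", "c", "a", "f", "g"),
                   b = c("a", "b", "c", "g", "h"))
  s3 <- data.frame(a = c("a", "h", "c", "e", "d"),
                   b = c("b", "i", "d", "f", "e"))
  # independent set union on canonical keys
  canon <- function(s) unique(paste(pmin(toupper(s$a), toupper(s$b)),
                                    pmax(toupper(s$a), toupper(s$b))))
  expected <- unique(c(canon(s1), canon(s2), canon(s3)))
  net <- integrate_edge_lists(list(s1, s2, s3))
  expect_equal(nrow(net$edges), length(expected))
  expect_setequal(paste(net$edges$a, net$edges$b), expected)
})

test_that("integration is idempotent", {
  set.seed(5)
  ed <- data.frame(a = sample(letters[1:10], 30, TRUE),
                   b = sample(letters[1:10], 30, TRUE))
  net <- integrate_edge_lists(ed)
  again <- integrate_edge_lists(net$edges)
  expect_identical(again$edges, net$edges)
  expect_identical(again$nodes, net$nodes)
})

test_that("identifier normalisation merges isoforms and case variants", {
  net <- integrate_edge_lists(data.frame(a = c("At1g01010.1", "AT1G01010"),
                                         b = c("at1g02020", "AT1G02020.2")))
  expect_equal(nrow(net$edges), 1)
  expect_setequal(net$nodes, c("AT1G01010", "AT1G02020"))
})

test_that("edge weights equal direct gene-similarity calls and missing
          endpoints become non-traversable", {
  g <- toy_ontology3()
  amap <- annotation_map(list(GA = "GO:A", GB = "GO:A", GC = "GO:B",
                              GD = character(0)), g)
  net <- integrate_edge_lists(data.frame(
    a = c("ga", "ga", "gb", "gc"),
    b = c("gb", "gc", "gc", "gd")))
  wnet <- weight_network(net, amap, g)
  key <- paste(wnet$edges$a, wnet$edges$b)
  w <- stats::setNames(wnet$weights, key)
  expect_identical(w[["GA GB"]], 1)                      # identical terms
  expect_equal(w[["GA GC"]], gene_similarity("GA", "GC", amap, g))
  expect_equal(w[["GB GC"]], gene_similarity("GB", "GC", amap, g))
  expect_true(is.na(w[["GC GD"]]))                       # unannotated
  expect_identical(wnet$traversable, !is.na(wnet$weights))
  expect_equal(wnet$n_retained, 3)
  expect_equal(wnet$n_dropped, 1)
})

test_that("weighting is order-independent", {
  fx <- generate_fixture(fixture_spec(aspects = "BP", n_genes = 40,
                                      n_mirnas = 10, n_families = 2,
                                      n_stress_groups = 1,
                                      stress_group_size = 2,
                                      n_clusters = 1, seed = 21))
  ed <- fx$network$edges
  net1 <- integrate_edge_lists(ed)
  net2 <- integrate_edge_lists(ed[rev(seq_len(nrow(ed))), ])
  w1 <- weight_network(net1, fx$annotations$BP, fx$ontology$BP)
  w2 <- weight_network(net2, fx$annotations$BP, fx$ontology$BP)
  expect_identical(w1$edges, w2$edges)
  expect_identical(w1$weights, w2$weights)
})

test_that("aspect-specific networks share topology, differing only in
          weights", {
  fx <- generate_fixture(fixture_spec(n_genes = 40, n_mirnas = 10,
                                      n_families = 2, n_terms = 20,
                                      n_stress_groups = 1,
                                      stress_group_size = 2,
                                      n_clusters = 1, seed = 22))
  ws <- lapply(c("BP", "CC", "MF"), function(a) {
    weight_network(fx$network, fx$annotations[[a]], fx$ontology[[a]])
  })
  expect_identical(ws[[1]]$edges, ws[[2]]$edges)
  expect_identical(ws[[2]]$edges, ws[[3]]$edges)
  expect_identical(ws[[1]]$aspect, "BP")
  expect_identical(ws[[3]]$aspect, "MF")
})

test_that("topology summaries match closed forms and an independent
          recount", {
  tri <- integrate_edge_lists(data.frame(a = c("a", "b", "c"),
                                         b = c("b", "c", "a")))
  expect_equal(topology_summary(tri),
               data.frame(proteins = 3, interactions = 3, degree_max = 2,
                          degree_min = 2, degree_average = 2))
  star <- integrate_edge_lists(data.frame(a = "hub",
                                          b = paste0("leaf", 1:4)))
  s <- topology_summary(star)
  expect_equal(s$degree_max, 4)
  expect_equal(s$degree_min, 1)
  expect_equal(s$degree_average, 1.6)

  set.seed(31)
  ed <- unique(data.frame(a = sample(sprintf("N%02d", 1:50), 120, TRUE),
                          b = sample(sprintf("N%02d", 1:50), 120, TRUE)))
  net <- integrate_edge_lists(ed)
  got <- topology_summary(net)
  # independent recount from the canonical edge table
  deg <- table(c(net$edges$a, net$edges$b))
  expect_equal(got$proteins, length(deg))
  expect_equal(got$interactions, nrow(net$edges))
  expect_equal(got$degree_max, max(deg))
  expect_equal(got$degree_min, min(deg))
  expect_equal(got$degree_average, round(2 * nrow(net$edges) / length(deg), 2))
})

test_that("weighted networks round-trip through the 3-column TSV", {
  g <- toy_ontology3()
  amap <- annotation_map(list(GA = "GO:A", GB = "GO:B", GC = character(0)),
                         g)
  net <- integrate_edge_lists(data.frame(a = c("ga", "gb"),
                                         b = c("gb", "gc")))
  wnet <- weight_network(net, amap, g)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_wppin(wnet, f)
  back <- read_wppin(f)
  expect_identical(back$edges, wnet$edges)
  expect_equal(back$weights, wnet$weights, tolerance = 1e-12)
  expect_identical(back$traversable, wnet$traversable)
})

test_that("MITAB interactor columns are extracted", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("uniprotkb:P1|intact:EBI-1\tuniprotkb:P2\trest\tcols",
               "uniprotkb:P3\tuniprotkb:P1\t-\t-"), f)
  tab <- read_mitab(f)
  expect_equal(tab$a, c("P1", "P3"))
  expect_equal(tab$b, c("P2", "P1"))
})
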