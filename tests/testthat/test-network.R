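test_that("export_networkin_input expands (accession, site) rows", {
  rec <- data.frame(spot_id = c("FAK2_572_584", "VGFR2_989_1001", "X_1_13"),
                    symbol = c("PTK2B", "KDR", "XX"),
                    uniprot_accession = c("Q14289", "P35968", "P00001"),
                    p_value = c(0.01, 0.02, 0.5),
                    fold_change = c(0.55, 0.51, 1.0),
                    direction = c("down", "down", "ns"),
                    stringsAsFactors = FALSE)
  rec$phospho_positions <- list(c(573L, 579L, 580L), 996L, 5L)
  out <- export_networkin_input(rec)
  expect_equal(nrow(out), 4)               # 3 sites + 1 site; ns skipped
  expect_equal(out$position[out$substrate_accession == "Q14289"],
               c(573L, 579L, 580L))
  expect_equal(out$position[out$substrate_accession == "P35968"], 996L)

  expect_equal(nrow(export_networkin_input(rec[0, ])), 0)

  rec$uniprot_accession[1] <- ""
  expect_warning(out2 <- export_networkin_input(rec), "without accession")
  expect_equal(nrow(out2), 1)
})

test_that("build_ppin de-duplicates, drops loops and honours the whitelist", {
  p <- build_ppin(data.frame(a = c("A", "B", "A"), b = c("B", "A", "A")))
  expect_equal(igraph::vcount(p$graph), 2)
  expect_equal(igraph::ecount(p$graph), 1)

  empty <- build_ppin(data.frame(a = character(0), b = character(0)))
  expect_equal(igraph::vcount(empty$graph), 0)

  tri <- build_ppin(data.frame(a = c("A", "B", "A"), b = c("B", "C", "C")))
  expect_equal(igraph::ecount(tri$graph), 3)

  wl <- build_ppin(data.frame(a = c("A", "B"), b = c("B", "C")),
                   node_whitelist = c("A", "B", "D"))
  expect_setequal(igraph::V(wl$graph)$name, c("A", "B", "D"))
  expect_equal(igraph::ecount(wl$graph), 1)  # D isolated, B-C dropped

  expect_error(build_ppin(data.frame(a = c("A", ""), b = c("B", "C"))),
               "malformed")
  expect_error(build_ppin("/no/such/file.tsv"), "not found")
})

test_that("centralities match the spec's worked examples", {
  path <- centrality_metrics(build_ppin(data.frame(a = c("A", "B"),
                                                   b = c("B", "C"))))$metrics
  expect_equal(path$degree[path$node == "B"], 2)
  expect_equal(path$betweenness[path$node == "B"], 1)  # the only other-pair
  # K4: every pair adjacent, betweenness all 0
  k4 <- expand.grid(a = LETTERS[1:4], b = LETTERS[1:4],
                    stringsAsFactors = FALSE)
  k4 <- k4[k4$a < k4$b, ]
  m4 <- centrality_metrics(build_ppin(k4))$metrics
  expect_equal(m4$betweenness, rep(0, 4))
  # star: center has maximal closeness
  star <- centrality_metrics(build_ppin(data.frame(a = "c",
                                                   b = c("l1", "l2", "l3"))))
  ms <- star$metrics
  expect_true(all(ms$closeness[ms$node == "c"] > ms$closeness[ms$node != "c"]))
})

test_that("centralities equal brute force on all graphs with <= 5 nodes", {
  # the full <= 6 sweep runs in the acceptance suite
  for (n in 1:5)
    for (adj in enumerate_graphs(n))
      expect_true(centralities_match(adj))
})

test_that("sum of degrees is twice the edge count", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    el <- data.frame(a = sample(LETTERS[1:n], 25, TRUE),
                     b = sample(LETTERS[1:n], 25, TRUE))
    el <- el[el$a != el$b, ]
    p <- centrality_metrics(build_ppin(el))
    expect_equal(sum(p$metrics$degree), 2 * igraph::ecount(p$graph))
  }
})

test_that("top_decile uses interpolated percentiles with ties included", {
  g <- build_ppin(data.frame(a = "c", b = paste0("l", 1:9)))  # star, 10 nodes
  expect_equal(top_decile(g, "degree"), "c")                  # single largest
  # all values equal -> everyone ties at the threshold
  pair <- build_ppin(data.frame(a = c("A", "C"), b = c("B", "D")))
  expect_setequal(top_decile(pair, "degree"), c("A", "B", "C", "D"))
  empty <- build_ppin(data.frame(a = character(0), b = character(0)))
  expect_equal(top_decile(empty, "degree"), character(0))
  expect_error(top_decile(g, "pagerank"), "unknown metric")
})

test_that("compare_networks partitions the union into disjoint sets", {
  a <- build_ppin(data.frame(a = c("A", "B"), b = c("B", "C")))
  b <- build_ppin(data.frame(a = c("B", "C"), b = c("C", "D")))
  v <- compare_networks(a, b)
  expect_equal(v$only_a, "A")
  expect_setequal(v$shared, c("B", "C"))
  expect_equal(v$only_b, "D")
  expect_equal(length(intersect(v$only_a, v$shared)), 0)
  expect_setequal(c(v$only_a, v$shared, v$only_b), LETTERS[1:4])

  same <- compare_networks(a, a)
  expect_equal(same$only_a, character(0))
  expect_equal(same$only_b, character(0))

  disj <- compare_networks(a, build_ppin(data.frame(a = "X", b = "Y")))
  expect_equal(disj$shared, character(0))

  # metric-restricted comparison uses top-decile sets
  vt <- compare_networks(a, b, metric = "degree")
  expect_setequal(c(vt$only_a, vt$shared, vt$only_b),
                  union(top_decile(a, "degree"), top_decile(b, "degree")))
})

test_that("read_predictions parses a predictor-style TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("substrate_symbol\tsite_position\tpredicted_interactor\tscore",
               "PTK2B\t573\tFRK\t2.51", "KDR\t996\tFRK\t3.02"), f)
  p <- read_predictions(f)
  expect_equal(nrow(p), 2)
  expect_equal(p$site_position, c(573L, 996L))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2"), f2)
  expect_error(read_predictions(f2), "needs columns")
})
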