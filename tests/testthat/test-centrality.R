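pathGraph <- function() igraph::make_graph(~ A - B, B - C)
triangle <- function() igraph::make_graph(~ A - B, B - C, C - A)
star4 <- function() igraph::make_star(5, mode = "undirected")

test_that("degree: triangle, path, and adjacency-row-sum oracle", {
  expect_equal(unname(degreeCentrality(triangle())), c(2, 2, 2))
  set.seed(101)
  for (rep in 1:8) {
    g <- randomConnectedGraph(sample(4:8, 1), 0.5)
    expect_equal(unname(degreeCentrality(g)), oracleDegree(g))
  }
})

test_that("closeness: path interior/ends, universal node, disconnection", {
  cl <- closenessCentrality(pathGraph())
  expect_equal(cl[["B"]], 1)
  expect_equal(cl[["A"]], 2 / 3)
  # universal node in an 11-node graph: closeness exactly 1
  g <- hubExampleGraph()
  expect_equal(closenessCentrality(g)[["H01"]], 1)
  # disconnected: component-size correction applies and isolates get 0
  g2 <- igraph::make_graph(~ A - B, C - D) + igraph::vertices("E")
  cl2 <- closenessCentrality(g2)
  expect_equal(cl2[["E"]], 0)
  expect_equal(cl2[["A"]], 1 * (1 / 4))   # r=2: (r-1)/S * (r-1)/(n-1)
})

test_that("betweenness: path, complete graph, enumeration oracle", {
  bt <- betweennessCentrality(pathGraph())
  expect_equal(bt[["B"]], 1)
  expect_equal(bt[["A"]], 0)
  expect_equal(unname(betweennessCentrality(igraph::make_full_graph(4))),
               rep(0, 4))
  set.seed(102)
  for (rep in 1:8) {
    g <- randomConnectedGraph(sample(4:8, 1), 0.4)
    expect_equal(unname(betweennessCentrality(g)), oracleBetweenness(g),
                 tolerance = 1e-12)
  }
})

test_that("eigenvector: symmetry on K3, star ratio 2, dense eigensolver oracle", {
  ev <- eigenvectorCentrality(triangle())
  expect_equal(unname(ev), rep(1 / sqrt(3), 3), tolerance = 1e-9)
  evs <- eigenvectorCentrality(star4())
  expect_equal(evs[[1]] / evs[[2]], 2, tolerance = 1e-8)  # centre/leaf = sqrt(4)
  expect_equal(sum(evs^2), 1, tolerance = 1e-9)           # unit 2-norm
  set.seed(103)
  for (rep in 1:8) {
    g <- randomConnectedGraph(sample(4:8, 1), 0.5)
    expect_equal(unname(eigenvectorCentrality(g)), oracleEigenvector(g),
                 tolerance = 1e-7)
  }
  # nodes outside the largest component get 0
  g2 <- igraph::disjoint_union(igraph::make_full_graph(4),
                               igraph::make_full_graph(2))
  ev2 <- eigenvectorCentrality(g2)
  expect_equal(unname(ev2[5:6]), c(0, 0))
  expect_true(all(ev2[1:4] > 0))
})

test_that("LAC: triangle, star centre, induced-degree oracle, bound", {
  expect_equal(unname(lacCentrality(triangle())), rep(1, 3))
  expect_equal(lacCentrality(star4())[[1]], 0)
  set.seed(104)
  for (rep in 1:8) {
    g <- randomConnectedGraph(sample(4:8, 1), 0.5)
    expect_equal(unname(lacCentrality(g)), oracleLac(g))
    expect_true(all(lacCentrality(g) <= pmax(degreeCentrality(g) - 1, 0)))
  }
})

test_that("network centrality: triangle, star, triangle-count oracle, bound", {
  expect_equal(unname(networkCentrality(triangle())), rep(2, 3))
  expect_equal(networkCentrality(star4())[[1]], 0)
  set.seed(105)
  for (rep in 1:8) {
    g <- randomConnectedGraph(sample(4:8, 1), 0.5)
    expect_equal(unname(networkCentrality(g)), oracleNetwork(g))
    expect_true(all(networkCentrality(g) <= degreeCentrality(g) + 1e-12))
  }
})

test_that("degree sums to twice the edge count on arbitrary graphs", {
  set.seed(106)
  for (rep in 1:6) {
    g <- igraph::sample_gnp(sample(5:30, 1), 0.2)
    expect_equal(sum(degreeCentrality(g)), 2 * igraph::ecount(g))
  }
})

test_that("centralityTable lays out all six measures per node", {
  g <- hubExampleGraph()
  tab <- centralityTable(g)
  expect_equal(names(tab), c("name", "betweenness", "closeness", "degree",
                             "eigenvector", "lac", "network"))
  expect_equal(nrow(tab), 11L)
  expect_equal(tab$degree[tab$name == "H01"], 10)
})

test_that("centralities reject directed or non-simple graphs", {
  gd <- igraph::make_graph(c("A", "B"), directed = TRUE)
  expect_error(degreeCentrality(gd), "undirected")
  gl <- igraph::make_graph(c("A", "A", "A", "B"), directed = FALSE)
  expect_error(lacCentrality(gl), "simple")
})
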