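path_graph <- function(n) {
  igraph::make_graph(rep(seq_len(n), each = 2)[2:(2 * n - 1)], directed = FALSE) |>
    igraph::set_vertex_attr("name", value = paste0("n", seq_len(n)))
}

test_that("RWR fixed points match closed forms", {
  # single node with a self-seed: score 1
  g1 <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices("solo")
  r1 <- rwr(g1, "solo", restart = 0.5)
  expect_equal(r1$scores$score, 1)
  # two nodes, one edge, one seed, r = 0.75: solve the 2x2 system exactly
  g2 <- igraph::make_graph(c("a", "b"), directed = FALSE)
  r2 <- rwr(g2, "a", restart = 0.75, tol = 1e-12)
  W <- matrix(c(0, 1, 1, 0), 2)
  exact <- solve(diag(2) - 0.25 * W, 0.75 * c(1, 0))
  expect_equal(r2$scores$score[match(c("a", "b"), r2$scores$gene)], exact,
               tolerance = 1e-9)
  expect_equal(sum(r2$scores$score), 1, tolerance = 1e-9)
  expect_error(rwr(g2, "zz"), "seed")
})

test_that("iterative RWR agrees with the direct linear solve", {
  set.seed(8)
  for (rep_i in 1:3) {
    g <- igraph::sample_gnp(40, 0.12)
    igraph::V(g)$name <- paste0("v", 1:40)
    seeds <- sample(igraph::V(g)$name, 3)
    res <- rwr(g, seeds, restart = 0.75, tol = 1e-10)
    W <- as.matrix(causalmap:::transition_matrix(g))
    p0 <- as.numeric(igraph::V(g)$name %in% seeds) / 3
    exact <- solve(diag(40) - 0.25 * W, 0.75 * p0)
    expect_lt(max(abs(res$scores$score - exact)), 1e-6)
    expect_true(res$converged)
    # fixed-point residual below tolerance
    p <- res$scores$score
    expect_lt(sum(abs(p - 0.25 * as.numeric(W %*% p) - 0.75 * p0)), 1e-6)
  }
})

test_that("ranks follow N - r_order and rank differences behave", {
  g <- path_graph(6)
  res <- rwr(g, "n1", restart = 0.75)
  sc <- res$scores
  expect_equal(sort(sc$rank), 0:5)
  expect_equal(sc$gene[which.max(sc$score)], sc$gene[which.max(sc$rank)])
  # no added seeds: identical runs, zero rank difference
  rc0 <- rank_comparison(g, "n1", character(), "n4")
  expect_equal(rc0$rank_difference, 0)
  expect_equal(rc0$score_with, rc0$score_without)
  # adding a seed adjacent to the test gene raises its score
  rc <- rank_comparison(g, "n1", "n5", "n4")
  expect_gt(rc$score_with, rc$score_without)
  expect_error(rank_comparison(g, "n1", "n4", "n4"), "seed")
})

test_that("network clusters respect the reaction-step limit", {
  # a -> x -> y -> b is 3 steps; b ... c is 4 steps
  gd <- igraph::graph_from_literal(a -+ x, x -+ y, y -+ b,
                                   b -+ s1, s1 -+ s2, s2 -+ s3, s3 -+ c)
  cl <- network_clusters(gd, c("a", "b", "c"), max_steps = 3)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$members$name, c("a", "x", "y", "b"))
  expect_setequal(cl[[1]]$members$name[cl[[1]]$members$role == "connector"],
                  c("x", "y"))
  # two seeds joined by a direct edge form a 2-seed cluster
  g2 <- igraph::graph_from_literal(p -+ q)
  cl2 <- network_clusters(g2, c("p", "q"))
  expect_length(cl2, 1)
  expect_setequal(cl2[[1]]$members$name, c("p", "q"))
  # a seed with no <=3-step partner joins no cluster
  g3 <- igraph::graph_from_literal(p -+ q, z -+ w)
  cl3 <- network_clusters(g3, c("p", "q", "z"))
  expect_length(cl3, 1)
  expect_false("z" %in% cl3[[1]]$members$name)
  # seed order does not matter
  cl_rev <- network_clusters(gd, c("c", "b", "a"), max_steps = 3)
  expect_equal(lapply(cl, function(x) x$members),
               lapply(cl_rev, function(x) x$members))
})

test_that("connectors lie on shortest seed-to-seed paths", {
  set.seed(21)
  g <- igraph::sample_gnp(25, 0.12, directed = TRUE)
  igraph::V(g)$name <- paste0("m", 1:25)
  seeds <- paste0("m", 1:6)
  cl <- network_clusters(g, seeds, max_steps = 3)
  d <- igraph::distances(g, mode = "out")
  for (comp in cl) {
    for (conn in comp$members$name[comp$members$role == "connector"]) {
      on_path <- FALSE
      for (a in seeds) for (b in seeds) {
        if (a == b || !is.finite(d[a, b]) || d[a, b] > 3) next
        if (d[a, conn] + d[conn, b] == d[a, b]) on_path <- TRUE
      }
      expect_true(on_path)
    }
  }
})

test_that("edge lists and SIF round-trip through readers", {
  edges <- tibble::tibble(gene_a = c("a", "b"), gene_b = c("b", "c"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(edges, tsv)
  g <- read_network(tsv)
  expect_equal(igraph::ecount(g), 2)
  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("a\tpp\tb", "b\tpp\tc", "c\tpp\tc"), sif)
  g2 <- read_network(sif)
  expect_equal(igraph::ecount(g2), 2)          # self-loop dropped
  expect_setequal(igraph::V(g2)$name, c("a", "b", "c"))
})
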