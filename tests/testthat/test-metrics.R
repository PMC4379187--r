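test_that("modularity matches hand-computed and degenerate cases", {
  A <- two_triangles()
  expect_equal(modularity_q(A, rep(1, 6)), 0)
  expect_equal(modularity_q(A, rep(1:2, each = 3)), 0.5)
  expect_error(modularity_q(matrix(0, 3, 3), c(1, 2, 3)), "edgeless")
  expect_error(modularity_q(A, c(1, 2)), "every vertex")
})

test_that("modularity is invariant to relabeling and vertex order", {
  set.seed(21)
  A <- random_graph(12, 0.3)
  part <- sample(1:3, 12, replace = TRUE)
  q <- modularity_q(A, part)
  expect_equal(modularity_q(A, c("x", "y", "z")[part]), q)
  p <- sample(12)
  expect_equal(modularity_q(A[p, p], part[p]), q)
})

test_that("modularity agrees with igraph on random partitions", {
  net <- load_fixture("karate")$network
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  set.seed(31)
  for (i in 1:5) {
    part <- sample(1:4, 34, replace = TRUE)
    expect_equal(modularity_q(net, part), igraph::modularity(g, part),
                 tolerance = 1e-12)
  }
})

test_that("overlapping modularity reduces to modularity on partitions", {
  A <- two_triangles()
  cov <- cover(list(1:3, 4:6), 6)
  expect_equal(overlapping_modularity(A, cov), 0.5)
  set.seed(5)
  for (i in 1:5) {
    B <- random_graph(10, 0.4)
    if (sum(B) == 0) next
    part <- sample(1:3, 10, replace = TRUE)
    cv <- cover(split(1:10, part), 10)
    expect_equal(overlapping_modularity(B, cv), modularity_q(B, part),
                 tolerance = 1e-12)
  }
  # every vertex in every community factors out to 0
  cov_all <- cover(list(1:6, 1:6, 1:6), 6)
  expect_equal(overlapping_modularity(A, cov_all), 0, tolerance = 1e-12)
  expect_error(overlapping_modularity(A, cover(list(1:3), 6)), "unassigned")
})

test_that("nmi is symmetric, label-invariant, and 0 for independence", {
  a <- c(1, 1, 2, 2)
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, c(2, 2, 1, 1)), 1)
  expect_equal(nmi(a, c(1, 2, 1, 2)), 0)
  set.seed(17)
  x <- sample(1:3, 30, replace = TRUE)
  y <- sample(1:4, 30, replace = TRUE)
  expect_equal(nmi(x, y), nmi(y, x))
  expect_true(nmi(x, y) >= 0 && nmi(x, y) <= 1)
  # both-trivial partitions agree perfectly by convention
  expect_equal(nmi(rep(1, 5), rep(2, 5)), 1)
  expect_error(nmi(1:3, 1:4), "length")
})

test_that("nmi agrees with igraph's sum-normalized variant", {
  set.seed(23)
  for (i in 1:5) {
    x <- sample(1:3, 40, replace = TRUE)
    y <- sample(1:3, 40, replace = TRUE)
    expect_equal(nmi(x, y), igraph::compare(x, y, method = "nmi"),
                 tolerance = 1e-12)
  }
})

test_that("enrichment matches pair enumeration", {
  # mu identically 1: both means equal
  cov <- cover(list(1:2, 3:4), 4)
  mu1 <- matrix(1, 4, 4)
  expect_equal(enrichment(cov, mu1), 1)
  expect_equal(enrichment(cover(list(1:4), 4), mu1), 1)
  # mu = 1 exactly on the within pairs (1,2) and (3,4): numerator 1,
  # denominator 2/6
  mu <- matrix(0, 4, 4)
  mu[1, 2] <- mu[2, 1] <- 1
  mu[3, 4] <- mu[4, 3] <- 1
  expect_equal(enrichment(cov, mu), 3)
  # callable similarity gives the same answer
  f <- function(i, j) as.numeric((i == 1 & j == 2) | (i == 3 & j == 4))
  expect_equal(enrichment(cov, f), 3)
  expect_error(enrichment(cov, matrix(0, 4, 4)), "identically 0")
  # concentration inside communities implies enrichment >= 1
  set.seed(2)
  blocks <- rep(1:2, each = 5)
  sim <- outer(blocks, blocks, "==") * 1
  diag(sim) <- 0
  cv <- cover(split(1:10, blocks), 10)
  expect_gte(enrichment(cv, sim), 1)
})

test_that("quality_report emits one tidy row per metric", {
  net <- network(two_triangles())
  cov <- cover(list(1:3, 4:6), 6)
  rep <- quality_report(net, cov, ground_truth = rep(1:2, each = 3))
  expect_true(all(c("modularity", "nmi", "overlapping_modularity",
                    "n_communities") %in% rep$metric))
  expect_equal(rep$value[rep$metric == "modularity"], 0.5)
  expect_equal(rep$value[rep$metric == "nmi"], 1)
})
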