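#' Four-block planted-partition benchmark
#'
#' The classic 128-vertex test graph: `n_communities` blocks of `size`
#' vertices with independent Bernoulli edges, within-block probability
#' `p_in = z_in / (size - 1)` and between-block probability
#' `p_out = z_out / (n - size)`, where `z_in = expected_degree - z_out`.
#' Every vertex then has expected degree `expected_degree` (16 by default),
#' split into `z_in` within-community and `z_out` between-community links;
#' raising `z_out` blurs the planted structure.
#'
#' @param z_out Expected number of between-community links per vertex, in
#'   `[0, expected_degree]`.
#' @param seed Integer RNG seed.
#' @param n_communities Number of planted blocks.
#' @param size Vertices per block.
#' @param expected_degree Expected total degree per vertex.
#' @return A list with `network` (a [network()], simple 0/1 graph) and
#'   `ground_truth` (the planted [cover()]).
#' @export
#' @examples
#' b <- planted_partition(z_out = 2, seed = 1)
#' b$network
planted_partition <- function(z_out, seed, n_communities = 4, size = 32,
                              expected_degree = 16) {
  stopifnot(z_out >= 0, z_out <= expected_degree,
            n_communities >= 2, size >= 2)
  n <- n_communities * size
  z_in <- expected_degree - z_out
  p_in <- z_in / (size - 1)
  p_out <- z_out / (n - size)
  if (p_in > 1 || p_out > 1) {
    stop("induced edge probability exceeds 1", call. = FALSE)
  }
  block <- rep(seq_len(n_communities), each = size)
  set.seed(seed)
  a <- bernoulli_blocks(n, function(i, j) {
    ifelse(block[i] == block[j], p_in, p_out)
  })
  truth <- cover(split(seq_len(n), block), n)
  list(network = network(a), ground_truth = truth)
}

#' Two-level hierarchical benchmark
#'
#' 512 vertices arranged in 16 communities of 32, nested in 4 super
#' communities of 128. Independent Bernoulli edges at three rates: each
#' vertex has on average `k1` links to the 31 others in its community
#' (`p1 = k1/31`), `k2` links to the other 96 vertices of its super
#' community (`p2 = k2/96`), and `k3` links to the remaining 384 vertices
#' (`p3 = k3/384`). Raising `k3` (and `k2`) blurs both levels.
#'
#' @param k3 Expected number of links to the rest of the network.
#' @param seed Integer RNG seed.
#' @param k1,k2 Expected within-community and within-supercommunity link
#'   counts (both default 16, the standard configuration).
#' @return A list with `network`, `level1` (the coarse [cover()] of 4
#'   supercommunities) and `level2` (the fine cover of 16 communities).
#' @export
hierarchical_benchmark <- function(k3, seed, k1 = 16, k2 = 16) {
  stopifnot(k1 >= 0, k2 >= 0, k3 >= 0)
  p1 <- k1 / 31
  p2 <- k2 / 96
  p3 <- k3 / 384
  if (max(p1, p2, p3) > 1) {
    stop("induced edge probability exceeds 1", call. = FALSE)
  }
  n <- 512
  fine <- rep(seq_len(16), each = 32)
  coarse <- rep(seq_len(4), each = 128)
  set.seed(seed)
  a <- bernoulli_blocks(n, function(i, j) {
    ifelse(fine[i] == fine[j], p1, ifelse(coarse[i] == coarse[j], p2, p3))
  })
  list(
    network = network(a),
    level1 = cover(split(seq_len(n), coarse), n),
    level2 = cover(split(seq_len(n), fine), n)
  )
}

# symmetric 0/1 adjacency with zero diagonal; prob(i, j) vectorized over
# upper-triangle index pairs
bernoulli_blocks <- function(n, prob) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- prob(idx[, 1], idx[, 2])
  a <- matrix(0, n, n)
  a[idx] <- as.numeric(runif(nrow(idx)) < p)
  a + t(a)
}
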