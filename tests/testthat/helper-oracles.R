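# small graphs built in code, and independent numeric oracles

# two disjoint triangles (6 vertices)
two_triangles <- function() {
  a <- matrix(0, 6, 6)
  a[cbind(c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6))] <- 1
  a + t(a)
}

# two disjoint k-cliques
two_cliques <- function(k = 6) {
  a <- matrix(0, 2 * k, 2 * k)
  a[seq_len(k), seq_len(k)] <- 1
  a[k + seq_len(k), k + seq_len(k)] <- 1
  diag(a) <- 0
  a
}

# Erdos-Renyi-ish symmetric 0/1 matrix
random_graph <- function(n, p = 0.3) {
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  a[up] <- as.numeric(runif(sum(up)) < p)
  a + t(a)
}

# central finite differences of the penalized objective, entry by entry
fd_gradient <- function(A, U, lambda, h = 1e-6) {
  g <- matrix(0, nrow(U), ncol(U))
  for (i in seq_len(nrow(U))) {
    for (k in seq_len(ncol(U))) {
      up <- U; up[i, k] <- up[i, k] + h
      dn <- U; dn[i, k] <- dn[i, k] - h
      g[i, k] <- (objective_loss(A, up, lambda)$loss -
                    objective_loss(A, dn, lambda)$loss) / (2 * h)
    }
  }
  g
}

# direct (dense) evaluation of the objective, independent of the package's
# trace-based shortcut
loss_direct <- function(A, U, lambda) {
  sum((A - U %*% t(U))^2) + lambda * sum(sqrt(colSums(U^2)))
}
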