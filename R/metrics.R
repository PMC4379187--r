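#' Newman-Girvan modularity of a hard partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * [c_i == c_j]` with `k_i` the
#' (weighted) vertex degree and `m` half the total weight. The sum includes
#' the diagonal terms, so a single-community partition gives exactly 0.
#'
#' @param x A [network()] or symmetric nonnegative adjacency matrix with at
#'   least one edge.
#' @param partition Community label per vertex (any atomic type), or a
#'   disjoint [cover()].
#' @return Modularity `Q` (at most 1).
#' @export
#' @examples
#' tri2 <- local({
#'   a <- matrix(0, 6, 6)
#'   a[cbind(c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6))] <- 1
#'   a + t(a)
#' })
#' modularity_q(tri2, c(1, 1, 1, 2, 2, 2))  # 0.5
modularity_q <- function(x, partition) {
  A <- as_adjacency(x)
  if (inherits(partition, "gsnmf_cover")) partition <- as_partition(partition)
  if (length(partition) != nrow(A)) {
    stop("partition must label every vertex", call. = FALSE)
  }
  two_m <- sum(A)
  if (two_m == 0) stop("modularity undefined on an edgeless network",
                       call. = FALSE)
  deg <- rowSums(A)
  q <- 0
  for (c in unique(partition)) {
    idx <- which(partition == c)
    q <- q + sum(A[idx, idx]) / two_m - (sum(deg[idx]) / two_m)^2
  }
  q
}

#' Overlapping modularity of a cover
#'
#' Membership-count extension of Newman-Girvan modularity:
#' `Q_ov = (1/2m) * sum_c sum_{i,j in c} (A_ij - k_i k_j / 2m) / (O_i O_j)`,
#' where `O_i` is the number of communities containing vertex `i`. It reduces
#' exactly to [modularity_q()] when the cover is a partition, which is all
#' the threshold sweep in [extract_cover()] requires of it.
#'
#' @inheritParams modularity_q
#' @param cov A [cover()] assigning every vertex to at least one community.
#' @return Overlapping modularity `Q_ov`.
#' @export
overlapping_modularity <- function(x, cov) {
  A <- as_adjacency(x)
  stopifnot(inherits(cov, "gsnmf_cover"))
  n <- nrow(A)
  O <- tabulate(unlist(cov$communities), n)
  if (any(O == 0)) stop("cover leaves vertices unassigned", call. = FALSE)
  two_m <- sum(A)
  if (two_m == 0) stop("modularity undefined on an edgeless network",
                       call. = FALSE)
  deg <- rowSums(A)
  q <- 0
  for (idx in cov$communities) {
    w <- 1 / O[idx]
    q <- q + sum((A[idx, idx, drop = FALSE] -
                    outer(deg[idx], deg[idx]) / two_m) * outer(w, w))
  }
  q / two_m
}

#' Normalized mutual information between two hard partitions
#'
#' `NMI = 2 I(a; b) / (H(a) + H(b))` computed from the contingency table.
#' Equals 1 for identical partitions up to relabeling, 0 for independent
#' ones, and is symmetric in its arguments. When both partitions are the
#' trivial single community (both entropies zero) the value is defined as 1,
#' since identical trivial partitions agree perfectly.
#'
#' @param a,b Community label vectors over the same vertex set, or disjoint
#'   [cover()]s.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  if (inherits(a, "gsnmf_cover")) a <- as_partition(a)
  if (inherits(b, "gsnmf_cover")) b <- as_partition(b)
  if (length(a) != length(b)) stop("partitions differ in length", call. = FALSE)
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab)
  pb <- colSums(tab)
  ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (ha + hb == 0) return(1)
  ex <- outer(pa, pb)
  mi <- sum(ifelse(tab > 0, tab * log(tab / ex), 0))
  2 * mi / (ha + hb)
}

#' Enrichment of vertex-pair metadata similarity within communities
#'
#' The mean of a binary pair-similarity `mu(i, j)` over unordered distinct
#' vertex pairs that share at least one community, divided by its mean over
#' all unordered distinct pairs. Values above 1 indicate that similar pairs
#' are concentrated inside communities; the denominator is the baseline
#' similarity of the vertex set.
#'
#' @param cov A non-empty [cover()].
#' @param similarity Either a symmetric 0/1 (or logical) N x N matrix, or a
#'   vectorized function `f(i, j)` of vertex indices returning 0/1.
#' @return Enrichment ratio (>= 0).
#' @export
enrichment <- function(cov, similarity) {
  stopifnot(inherits(cov, "gsnmf_cover"))
  n <- cov$n_vertices
  if (is.function(similarity)) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    mu <- matrix(0, n, n)
    mu[idx] <- as.numeric(similarity(idx[, 1], idx[, 2]))
    mu <- mu + t(mu)
  } else {
    mu <- as.matrix(similarity)
    stopifnot(nrow(mu) == n, ncol(mu) == n)
    mu <- (mu + t(mu)) / 2
    diag(mu) <- 0
  }
  shared <- matrix(FALSE, n, n)
  for (idx in cov$communities) shared[idx, idx] <- TRUE
  diag(shared) <- FALSE
  up <- upper.tri(mu)
  denom <- mean(mu[up])
  if (denom == 0) stop("enrichment undefined: similarity is identically 0",
                       call. = FALSE)
  if (!any(shared[up])) stop("cover has no within-community pair", call. = FALSE)
  mean(mu[up & shared]) / denom
}

#' Quality report for a detected community structure
#'
#' Convenience wrapper producing one tidy row per applicable metric:
#' modularity of the hard partition, overlapping modularity of the cover,
#' and NMI against a ground-truth partition when one is supplied.
#'
#' @param x A [network()].
#' @param cov A [cover()] (overlapping allowed).
#' @param partition Optional hard partition (defaults to `cov` when disjoint).
#' @param ground_truth Optional reference partition or disjoint [cover()].
#' @return A tibble with columns `metric` and `value`.
#' @export
quality_report <- function(x, cov = NULL, partition = NULL,
                           ground_truth = NULL) {
  rows <- list()
  if (is.null(partition) && !is.null(cov)) {
    partition <- tryCatch(as_partition(cov), error = function(e) NULL)
  }
  if (!is.null(partition)) {
    rows$modularity <- modularity_q(x, partition)
    if (!is.null(ground_truth)) {
      rows$nmi <- nmi(partition, ground_truth)
    }
  }
  if (!is.null(cov)) {
    rows$overlapping_modularity <- overlapping_modularity(x, cov)
    rows$n_communities <- cov$n_communities
    rows$n_overlapping_vertices <-
      sum(tabulate(unlist(cov$communities), cov$n_vertices) > 1)
  }
  tibble::tibble(metric = names(rows), value = unlist(rows, use.names = FALSE))
}
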