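#' Drop empty communities from a fitted membership matrix
#'
#' The group-sparsity penalty empties surplus columns of `U`; at convergence
#' those columns are numerically tiny rather than exactly zero. A column is
#' pruned when its l2 norm is below `col_tol` times the largest column norm.
#' The number of surviving columns is the model's automatically selected
#' community count.
#'
#' @param U Membership matrix or a [snmf_fit()] result.
#' @param col_tol Relative column-norm threshold (default `1e-6`).
#' @param abs_tol Absolute column-norm floor. At extreme penalties the whole
#'   matrix converges to zero (the model selects "no communities"); without
#'   an absolute floor the relative rule would keep the largest of the
#'   vanishing columns.
#' @return A list with `membership` (surviving columns, original order) and
#'   `kept` (their original column indices). Pruning every column (legal when
#'   the network is essentially empty) yields a 0-column matrix.
#' @export
prune_communities <- function(U, col_tol = 1e-6, abs_tol = 1e-6) {
  U <- as_membership(U)
  stopifnot(col_tol >= 0, abs_tol >= 0)
  cn <- sqrt(colSums(U^2))
  kept <- if (col_tol == 0) {
    seq_len(ncol(U))
  } else {
    which(cn >= pmax(col_tol * max(cn), abs_tol))
  }
  list(membership = U[, kept, drop = FALSE], kept = kept)
}

#' Hard partition from a membership matrix
#'
#' Assigns each vertex to the community with its largest membership
#' propensity (ties broken by lowest column index).
#'
#' @param U Membership matrix (>= 1 column) or a [snmf_fit()] result.
#' @return Integer vector of community labels (column indices of `U`).
#' @export
hard_partition <- function(U) {
  U <- as_membership(U)
  if (ncol(U) < 1) stop("membership matrix has no columns", call. = FALSE)
  apply(U, 1, which.max)
}

#' Rescale each row of a membership matrix to [0, 1]
#'
#' Per row, maps the minimum entry to 0 and the maximum to 1 by the affine
#' map `(U[i,k] - min_i) / (max_i - min_i)`; intermediate entries land in
#' between. Constant rows, where the map is 0/0, fall back to the argmax-only
#' membership: 1 at the first maximal column, 0 elsewhere.
#'
#' @param U Membership matrix with at least 2 columns.
#' @return Matrix of the same shape with entries in `[0, 1]`.
#' @export
rescale_rows <- function(U) {
  U <- as_membership(U)
  if (ncol(U) < 2) stop("rescaling needs >= 2 columns", call. = FALSE)
  lo <- apply(U, 1, min)
  hi <- apply(U, 1, max)
  rng <- hi - lo
  out <- (U - lo) / ifelse(rng == 0, 1, rng)
  flat <- rng == 0
  if (any(flat)) {
    out[flat, ] <- 0
    out[cbind(which(flat), apply(U[flat, , drop = FALSE], 1, which.max))] <- 1
  }
  out
}

#' Extract an overlapping cover by a threshold sweep
#'
#' Rescales each row of `U` to `[0, 1]`, then for each threshold `t` in the
#' grid assigns vertex `i` to every community `k` with rescaled value
#' strictly above `t`. A vertex whose memberships are all thresholded away is
#' assigned to its argmax community, so every cover assigns each vertex to at
#' least one community. Among the candidate covers the one maximizing
#' [overlapping_modularity()] is returned; ties go to the smallest threshold.
#'
#' @param x A [network()] (or adjacency matrix) the quality metric is
#'   evaluated on.
#' @param U Pruned membership matrix (see [prune_communities()]).
#' @param thresholds Numeric grid in `[0, 1)`.
#' @return A list with `cover` (a [cover()]), `threshold` (the selected
#'   value) and `quality` (its overlapping modularity). A single-column `U`
#'   yields the trivial one-community cover with threshold `NA`.
#' @export
#' @examples
#' d <- load_fixture("dolphins")
#' fit <- snmf_fit(d$network, k_init = 20, lambda = 1.7, n_restarts = 5, seed = 1)
#' pruned <- prune_communities(fit)
#' extract_cover(d$network, pruned$membership)
extract_cover <- function(x, U, thresholds = seq(0, 0.95, by = 0.05)) {
  A <- as_adjacency(x)
  U <- as_membership(U)
  labels <- network_labels(x, nrow(A))
  stopifnot(nrow(U) == nrow(A))
  if (ncol(U) == 1) {
    cov1 <- cover(list(seq_len(nrow(U))), nrow(U), labels)
    return(list(cover = cov1, threshold = NA_real_,
                quality = overlapping_modularity(x, cov1)))
  }
  stopifnot(length(thresholds) >= 1, all(thresholds >= 0), all(thresholds < 1))
  R <- rescale_rows(U)
  amax <- hard_partition(U)
  best <- NULL
  for (t in sort(thresholds)) {
    M <- R > t
    empty <- rowSums(M) == 0
    M[cbind(which(empty), amax[empty])] <- TRUE
    comms <- lapply(seq_len(ncol(M)), function(k) which(M[, k]))
    comms <- comms[lengths(comms) > 0]
    cv <- cover(comms, nrow(U), labels)
    q <- overlapping_modularity(x, cv)
    if (is.null(best) || q > best$quality + 1e-12) {
      best <- list(cover = cv, threshold = t, quality = q)
    }
  }
  best
}

#' Per-vertex membership entropy
#'
#' Each row of `U` is normalized to a probability distribution over
#' communities; the entropy `H_i = -sum_k p_ik log2 p_ik` (in bits, with
#' `0 log 0 = 0`) measures how uncertain — how "active" — vertex `i`'s
#' community allocation is. Vertices shared between communities show up as
#' entropy spikes. All-zero rows get entropy 0 by convention.
#'
#' @param U Membership matrix or [snmf_fit()] result.
#' @param labels Optional vertex labels for the output.
#' @return A tibble with columns `vertex` and `entropy` (bits); values lie
#'   in `[0, log2(K)]`.
#' @export
membership_entropy <- function(U, labels = NULL) {
  if (inherits(U, "gsnmf_fit") && is.null(labels)) labels <- U$vertex_labels
  U <- as_membership(U)
  rs <- rowSums(U)
  P <- U / ifelse(rs == 0, 1, rs)
  h <- -rowSums(ifelse(P > 0, P * log2(P), 0))
  tibble::tibble(
    vertex = labels %||% paste0("v", seq_len(nrow(U))),
    entropy = h
  )
}
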