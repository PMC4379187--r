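#' End-to-end community detection on a network
#'
#' Convenience pipeline: fit the group-sparse factorization, prune empty
#' communities, derive the hard partition, extract the overlapping cover by
#' the threshold sweep, and compute per-vertex membership entropy.
#'
#' @inheritParams snmf_fit
#' @param k_init Initial community count K0; defaults to half the vertex
#'   count, capped at 64. The penalty prunes the surplus.
#' @param col_tol Column-pruning tolerance, see [prune_communities()].
#' @param thresholds Threshold grid for [extract_cover()].
#' @return A list of class `gsnmf_result`: `fit` (the [snmf_fit()] object),
#'   `membership` (pruned matrix), `n_communities`, `partition` (integer
#'   labels), `cover`, `threshold`, `entropy` (tibble), plus the call
#'   parameters.
#' @export
#' @examples
#' res <- detect_communities(load_fixture("karate")$network,
#'                           k_init = 17, lambda = 1.7,
#'                           n_restarts = 5, seed = 42)
#' res$n_communities
detect_communities <- function(x, lambda, k_init = NULL, n_restarts = 10,
                               max_iter = 1000, rel_tol = 1e-6, seed = NULL,
                               col_tol = 1e-6,
                               thresholds = seq(0, 0.95, by = 0.05)) {
  A <- as_adjacency(x)
  n <- nrow(A)
  if (is.null(k_init)) k_init <- max(2L, min(ceiling(n / 2), 64L))
  fit <- snmf_fit(x, k_init = k_init, lambda = lambda,
                  n_restarts = n_restarts, max_iter = max_iter,
                  rel_tol = rel_tol, seed = seed)
  pr <- prune_communities(fit$membership, col_tol)
  labels <- network_labels(x, n)
  if (length(pr$kept) == 0) {
    part <- integer(n)
    cov <- NULL
    thr <- NA_real_
  } else {
    part <- hard_partition(pr$membership)
    ec <- extract_cover(x, pr$membership, thresholds)
    cov <- ec$cover
    thr <- ec$threshold
  }
  structure(
    list(
      fit = fit,
      membership = pr$membership,
      kept = pr$kept,
      n_communities = length(pr$kept),
      partition = part,
      cover = cov,
      threshold = thr,
      entropy = membership_entropy(pr$membership, labels),
      lambda = lambda,
      k_init = k_init,
      vertex_labels = labels
    ),
    class = "gsnmf_result"
  )
}

#' @export
print.gsnmf_result <- function(x, ...) {
  ov <- if (is.null(x$cover)) 0L else {
    sum(tabulate(unlist(x$cover$communities), length(x$vertex_labels)) > 1)
  }
  cat(sprintf(
    paste0("<gsnmf_result> lambda = %g, K0 = %d -> %d communities\n",
           "  overlapping vertices: %d (cover threshold %s)\n",
           "  loss %.6g = error %.6g + penalty %.6g\n"),
    x$lambda, x$k_init, x$n_communities, ov,
    format(x$threshold), x$fit$loss, x$fit$error_term, x$fit$reg_term
  ))
  invisible(x)
}
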