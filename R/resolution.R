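#' Scan the resolution parameter to expose multi-scale structure
#'
#' Runs one full multi-restart fit per value of `lambda_grid` and records,
#' for each, the reconstruction error, the (weighted) penalty term, their
#' ratio, the surviving community count and the hard partition. As the
#' resolution parameter grows the penalty empties more columns, so the
#' community count decreases — scanning it from large to small walks the
#' network's hierarchy from coarse to fine.
#'
#' @inheritParams snmf_fit
#' @param lambda_grid Ascending nonnegative resolution values.
#' @param seed Master seed; the fit at grid position `g` uses `seed + g - 1`
#'   so every row is reproducible. Besides its random restarts, each fit gets
#'   one warm-start restart continued from the previous grid point's
#'   solution, which stabilizes the path at strong penalties.
#' @param col_tol Column-pruning tolerance, see [prune_communities()].
#' @return A tibble of class `resolution_profile`, one row per lambda, with
#'   columns `lambda`, `n_communities`, `error_term`, `reg_term`
#'   (`lambda * ||U||_2,1`), `ratio` (`reg_term / error_term`), `loss` and a
#'   `partition` list-column (labels over the pruned communities).
#' @seealso [recommend_lambda()]
#' @export
#' @examples
#' net <- load_fixture("karate")$network
#' prof <- resolution_scan(net, k_init = 17, lambda_grid = c(1, 2, 3.5),
#'                         n_restarts = 3, seed = 1)
#' prof[, c("lambda", "n_communities", "ratio")]
resolution_scan <- function(x, k_init, lambda_grid = seq(0.1, 4, by = 0.1),
                            n_restarts = 10, max_iter = 1000, rel_tol = 1e-6,
                            seed = NULL, col_tol = 1e-6) {
  stopifnot(length(lambda_grid) >= 1, all(lambda_grid >= 0),
            !is.unsorted(lambda_grid))
  prev_U <- NULL
  rows <- purrr::imap(lambda_grid, function(lam, g) {
    fit <- snmf_fit(x, k_init = k_init, lambda = lam, n_restarts = n_restarts,
                    max_iter = max_iter, rel_tol = rel_tol,
                    seed = if (is.null(seed)) NULL else seed + g - 1L,
                    warm_start = prev_U)
    prev_U <<- fit$membership
    pr <- prune_communities(fit$membership, col_tol)
    part <- if (length(pr$kept) >= 1) hard_partition(pr$membership)
            else integer(nrow(fit$membership))
    tibble::tibble(
      lambda = lam,
      n_communities = length(pr$kept),
      error_term = fit$error_term,
      reg_term = fit$reg_term,
      ratio = fit$reg_term / fit$error_term,
      loss = fit$loss,
      partition = list(part)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("resolution_profile", class(out))
  out
}

#' Recommend a resolution parameter from a scan
#'
#' Picks the scan row whose penalty-to-error ratio is closest to
#' `target_ratio` (ties to the smaller lambda). Empirically, when the
#' penalty term is about half the reconstruction error the surviving
#' community count sits close to the network's natural one, which makes
#' ratio 0.5 a robust default operating point.
#'
#' @param profile A [resolution_scan()] result.
#' @param target_ratio Ratio to aim for (default 0.5).
#' @param weighted If `TRUE` (default) the ratio compares the lambda-weighted
#'   penalty `lambda * ||U||_2,1`, i.e. the two terms exactly as they enter
#'   the objective; if `FALSE` the bare `||U||_2,1` is compared instead.
#' @return A list with `lambda` and `row` (the selected one-row profile).
#' @export
recommend_lambda <- function(profile, target_ratio = 0.5, weighted = TRUE) {
  stopifnot(nrow(profile) >= 1)
  r <- profile$ratio
  if (!weighted) r <- ifelse(profile$lambda > 0, r / profile$lambda, NA_real_)
  d <- abs(r - target_ratio)
  d[!is.finite(d)] <- Inf
  i <- which.min(d)  # which.min takes the first minimum: ties -> smaller lambda
  list(lambda = profile$lambda[i], row = profile[i, ])
}

#' @export
print.resolution_profile <- function(x, ...) {
  cat(sprintf("<resolution_profile> %d lambda values in [%g, %g]\n",
              nrow(x), min(x$lambda), max(x$lambda)))
  NextMethod()
}

#' Plot a resolution profile
#'
#' Shows the surviving community count and the penalty/error ratio across
#' the scanned resolution values.
#'
#' @param object A [resolution_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.resolution_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "lambda", "n_communities", "ratio"),
    cols = c("n_communities", "ratio"),
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$lambda, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "resolution parameter", y = NULL)
}

#' Distinct partitions along a scan, coarse to fine
#'
#' Summarizes the hierarchy exposed by a scan: one row per distinct
#' surviving community count, keeping the best-loss row at each count,
#' ordered from coarse (large lambda) to fine.
#'
#' @param profile A [resolution_scan()] result.
#' @return A `resolution_profile` tibble with one row per community count.
#' @export
hierarchy_levels <- function(profile) {
  out <- dplyr::slice_min(
    dplyr::group_by(tibble::as_tibble(profile), .data$n_communities),
    .data$loss, n = 1, with_ties = FALSE
  )
  out <- dplyr::arrange(dplyr::ungroup(out), .data$n_communities)
  class(out) <- c("resolution_profile", class(out))
  out
}
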