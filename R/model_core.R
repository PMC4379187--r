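#' Expected adjacency matrix of a membership matrix
#'
#' Under the generative model the expected weight between vertices `i` and
#' `j` is `sum_k U[i, k] * U[j, k]`, i.e. the model's reconstruction of the
#' network is `U %*% t(U)`.
#'
#' @param U Nonnegative numeric matrix (N x K) of membership propensities.
#' @return Symmetric nonnegative N x N matrix.
#' @export
expected_adjacency <- function(U) {
  tcrossprod(as_membership(U))
}

#' l2,1 norm of a membership matrix
#'
#' The sum over columns of each column's Euclidean norm. Penalizing it drives
#' whole columns (communities) to zero, which is how the model selects the
#' number of communities.
#'
#' @inheritParams expected_adjacency
#' @return Nonnegative scalar.
#' @export
l21_norm <- function(U) {
  sum(sqrt(colSums(as_membership(U)^2)))
}

as_membership <- function(U) {
  if (inherits(U, "gsnmf_fit")) U <- U$membership
  U <- as.matrix(U)
  if (!is.numeric(U) || any(U < 0) || anyNA(U)) {
    stop("membership matrix must be nonnegative and finite", call. = FALSE)
  }
  U
}

#' Penalized factorization objective
#'
#' The loss is the squared Frobenius reconstruction error plus the weighted
#' group-sparsity penalty:
#' `||A - U U'||_F^2 + lambda * ||U||_{2,1}`.
#'
#' @param A Symmetric nonnegative adjacency matrix, or a [network()].
#' @param U Nonnegative membership matrix (N x K).
#' @param lambda Nonnegative resolution parameter weighting the penalty.
#' @return A list with components `loss`, `error_term` (`||A - UU'||_F^2`)
#'   and `reg_term` (`lambda * ||U||_{2,1}`).
#' @export
#' @examples
#' a <- matrix(c(0, 1, 1, 0), 2, 2)
#' objective_loss(a, matrix(1, 2, 1), lambda = 2)
objective_loss <- function(A, U, lambda) {
  A <- as_adjacency(A)
  U <- as_membership(U)
  if (nrow(U) != nrow(A)) stop("dimension mismatch", call. = FALSE)
  stopifnot(lambda >= 0)
  err <- loss_error_term(sum(A^2), A %*% U, U)
  reg <- lambda * l21_norm(U)
  list(loss = err + reg, error_term = err, reg_term = reg)
}

# ||A - UU'||_F^2 without forming UU': ||A||^2 - 2 tr(U'AU) + ||U'U||^2.
# Clamped at 0 against cancellation noise.
loss_error_term <- function(sumA2, AU, U) {
  max(0, sumA2 - 2 * sum(AU * U) + sum(crossprod(U)^2))
}

#' Gradient of the penalized objective
#'
#' Entry `(i, k)` is `(-4 A U + 4 U U'U)[i, k] + lambda * U[i, k] / ||U[, k]||`.
#' The penalty term is undefined for an all-zero column, so those raise an
#' error; callers prune or floor degenerate columns first.
#'
#' @inheritParams objective_loss
#' @return N x K numeric matrix.
#' @export
membership_gradient <- function(A, U, lambda) {
  A <- as_adjacency(A)
  U <- as_membership(U)
  if (nrow(U) != nrow(A)) stop("dimension mismatch", call. = FALSE)
  cn <- sqrt(colSums(U^2))
  if (lambda > 0 && any(cn == 0)) {
    stop("gradient undefined for all-zero column(s): ",
         paste(which(cn == 0), collapse = ", "), call. = FALSE)
  }
  g <- -4 * (A %*% U) + 4 * U %*% crossprod(U)
  if (lambda > 0) g <- g + lambda * sweep(U, 2, cn, "/")
  g
}

#' One multiplicative update step
#'
#' Each entry is multiplied by the ratio of the negative to the positive part
#' of the gradient,
#' `U[i,k] <- U[i,k] * (4AU)[i,k] / ((4UU'U)[i,k] + lambda U[i,k]/||U[,k]|| + eps)`,
#' which preserves nonnegativity and leaves exact zeros at zero. `eps` floors
#' every denominator (including the column norm) so that near-empty columns,
#' which the group-sparsity penalty deliberately creates, decay smoothly to
#' zero instead of producing NaN.
#'
#' @inheritParams objective_loss
#' @param eps Positive numeric floor for denominators.
#' @return Updated membership matrix, entrywise nonnegative.
#' @export
update_step <- function(A, U, lambda, eps = 1e-10) {
  A <- as_adjacency(A)
  U <- as_membership(U)
  stopifnot(nrow(U) == nrow(A), lambda >= 0, eps > 0)
  update_step_(A, U, lambda, eps)
}

# internal hot path: no validation, optionally reuses AU. `damping` mixes
# the plain multiplicative ratio with the identity, U <- U*((1-d) + d*r):
# same fixed points, but the averaged map suppresses the period-2
# oscillation the plain ratio exhibits on dense matrices.
update_step_ <- function(A, U, lambda, eps, AU = A %*% U, damping = 1) {
  denom <- 4 * (U %*% crossprod(U))
  if (lambda > 0) {
    cn <- pmax(sqrt(colSums(U^2)), eps)
    denom <- denom + lambda * sweep(U, 2, cn, "/")
  }
  r <- (4 * AU) / (denom + eps)
  if (damping >= 1) U * r else U * ((1 - damping) + damping * r)
}

#' Fit the group-sparse symmetric factorization of a network
#'
#' Runs the multiplicative update from `n_restarts` independent random
#' initializations and keeps the restart with the lowest final objective.
#' Each restart iterates until the relative per-iteration decrease of the
#' loss drops below `rel_tol` or `max_iter` is reached. Entries of the
#' initial matrices are i.i.d. Uniform(0, 1) scaled by
#' `sqrt(mean(A) / k_init)` so that `UU'` starts at the magnitude of `A`.
#'
#' @param x A [network()] or a symmetric nonnegative adjacency matrix.
#' @param k_init Initial (maximum) number of communities K0. With a
#'   sufficiently large `k_init` the group-sparsity penalty empties the
#'   surplus columns, selecting the community count automatically; see
#'   [prune_communities()].
#' @param lambda Resolution parameter (penalty weight); larger values yield
#'   fewer, larger communities.
#' @param n_restarts Number of independent random initializations.
#' @param max_iter Maximum multiplicative updates per restart.
#' @param rel_tol Relative loss-decrease stopping tolerance.
#' @param seed Master seed; one child seed per restart is drawn from it, so a
#'   fit is fully reproducible. `NULL` leaves the RNG state alone.
#' @param eps Numeric floor for denominators.
#' @param init Optional list of `n_restarts` nonnegative N x K matrices to
#'   use instead of random initializations (for reproducibility studies).
#' @param warm_start Optional membership matrix appended as one extra
#'   deterministic restart (zero-padded or truncated to `k_init` columns).
#'   Used by [resolution_scan()] to continue along the resolution path.
#' @param damping Averaging weight in `(0, 1]` applied to the multiplicative
#'   ratio each iteration (`1` = the plain rule). The default `0.5` is the
#'   standard stabilized map for symmetric factorizations: it has the same
#'   fixed points as the plain rule but suppresses its period-2 oscillation
#'   on dense matrices.
#' @return An object of class `gsnmf_fit`: a list with `membership` (N x K
#'   matrix, K = `k_init`), `loss`, `error_term`, `reg_term`,
#'   `loss_trajectory`, `n_iterations`, `converged`, `restart_losses`,
#'   `seed_used`, `lambda`, `k_init` and `vertex_labels`.
#' @seealso [prune_communities()], [hard_partition()], [extract_cover()],
#'   [resolution_scan()]
#' @export
#' @examples
#' net <- load_fixture("karate")$network
#' fit <- snmf_fit(net, k_init = 17, lambda = 1.7, n_restarts = 3, seed = 1)
#' glance(fit)
snmf_fit <- function(x, k_init, lambda, n_restarts = 10, max_iter = 1000,
                     rel_tol = 1e-6, seed = NULL, eps = 1e-10, init = NULL,
                     warm_start = NULL, damping = 0.5) {
  A <- as_adjacency(x)
  n <- nrow(A)
  stopifnot(k_init >= 1, lambda >= 0, n_restarts >= 1, max_iter >= 1,
            rel_tol > 0, eps > 0)
  labels <- network_labels(x, n)

  if (is.null(init)) {
    if (!is.null(seed)) set.seed(seed)
    child_seeds <- sample.int(.Machine$integer.max, n_restarts)
    scale <- sqrt(mean(A) / k_init)
    # restarts cycle through increasing initialization scales: at strong
    # penalties a small-norm start can collapse every column to zero before
    # any community forms, while larger starts reach the sparse optima
    mult <- rep(c(1, 1, 2, 4), length.out = n_restarts)
    init <- lapply(seq_len(n_restarts), function(r) {
      set.seed(child_seeds[r])
      matrix(runif(n * k_init), n, k_init) * (scale * mult[r])
    })
  } else {
    stopifnot(length(init) == n_restarts)
    child_seeds <- rep(NA_integer_, n_restarts)
  }
  if (!is.null(warm_start)) {
    W <- as_membership(warm_start)
    stopifnot(nrow(W) == n)
    if (ncol(W) < k_init) {
      W <- cbind(W, matrix(0, n, k_init - ncol(W)))
    }
    init <- c(init, list(W[, seq_len(k_init), drop = FALSE]))
    child_seeds <- c(child_seeds, NA_integer_)
  }

  sumA2 <- sum(A^2)
  runs <- lapply(init, function(U) {
    traj <- numeric(0)
    prev <- Inf
    converged <- FALSE
    iter <- 0L
    best_U <- U
    best_loss <- Inf
    AU <- A %*% U
    while (iter < max_iter) {
      U <- update_step_(A, U, lambda, eps, AU, damping)
      iter <- iter + 1L
      AU <- A %*% U
      cur <- loss_error_term(sumA2, AU, U) + lambda * l21_norm(U)
      traj[iter] <- cur
      if (cur < best_loss) {
        best_loss <- cur
        best_U <- U
      }
      if (is.finite(prev) && abs(prev - cur) < rel_tol * max(abs(prev), eps)) {
        converged <- TRUE
        break
      }
      prev <- cur
    }
    err <- loss_error_term(sumA2, A %*% best_U, best_U)
    list(U = best_U, loss = err + lambda * l21_norm(best_U), error_term = err,
         traj = traj, iter = iter, converged = converged)
  })

  losses <- vapply(runs, `[[`, 0, "loss")
  best <- which.min(losses)  # ties -> lowest restart index
  b <- runs[[best]]
  structure(
    list(
      membership = b$U,
      loss = b$loss,
      error_term = b$error_term,
      reg_term = b$loss - b$error_term,
      loss_trajectory = b$traj,
      n_iterations = b$iter,
      converged = b$converged,
      restart_losses = losses,
      best_restart = best,
      seed_used = child_seeds[best],
      lambda = lambda,
      k_init = as.integer(k_init),
      vertex_labels = labels
    ),
    class = "gsnmf_fit"
  )
}

#' @export
print.gsnmf_fit <- function(x, ...) {
  kept <- prune_communities(x$membership)$kept
  cat(sprintf(
    paste0("<gsnmf_fit> N = %d, K0 = %d, lambda = %g\n",
           "  loss %.6g (error %.6g + penalty %.6g) after %d iterations%s\n",
           "  surviving communities: %d\n"),
    nrow(x$membership), x$k_init, x$lambda,
    x$loss, x$error_term, x$reg_term, x$n_iterations,
    if (x$converged) "" else " (max_iter reached)", length(kept)
  ))
  invisible(x)
}

#' @rdname snmf_fit
#' @param x,object A `gsnmf_fit`.
#' @param ... Unused.
#' @export
tidy.gsnmf_fit <- function(x, ...) {
  U <- x$membership
  tibble::tibble(
    vertex = rep(x$vertex_labels, ncol(U)),
    community = rep(seq_len(ncol(U)), each = nrow(U)),
    membership = as.vector(U)
  )
}

#' @rdname snmf_fit
#' @export
glance.gsnmf_fit <- function(x, ...) {
  tibble::tibble(
    n_vertices = nrow(x$membership),
    k_init = x$k_init,
    lambda = x$lambda,
    loss = x$loss,
    error_term = x$error_term,
    reg_term = x$reg_term,
    n_iterations = x$n_iterations,
    converged = x$converged,
    n_communities = length(prune_communities(x$membership)$kept)
  )
}

#' @rdname snmf_fit
#' @export
autoplot.gsnmf_fit <- function(object, ...) {
  df <- tidy.gsnmf_fit(object)
  df$vertex <- factor(df$vertex, levels = object$vertex_labels)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$community), y = .data$vertex, fill = .data$membership
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "community", y = "vertex", fill = "U[i,k]",
                  title = sprintf("Membership matrix (lambda = %g)",
                                  object$lambda))
}

#' Complementary-slackness residual at a candidate solution
#'
#' At a constrained stationary point of the penalized objective every entry
#' satisfies `gradient[i,k] * U[i,k] = 0` (either the entry is at the zero
#' boundary or the gradient vanishes). The residual is the maximum absolute
#' value of that elementwise product; it converges to zero as the fit is run
#' to tighter tolerance, and is the package's numerical check of the update
#' rule's correctness. Columns with zero norm contribute nothing (their
#' entries are all zero).
#'
#' @inheritParams objective_loss
#' @return Nonnegative scalar, `max(abs(gradient * U))`.
#' @export
kkt_residual <- function(A, U, lambda) {
  A <- as_adjacency(A)
  U <- as_membership(U)
  cn <- sqrt(colSums(U^2))
  g <- -4 * (A %*% U) + 4 * U %*% crossprod(U)
  if (lambda > 0) {
    nz <- cn > 0
    if (any(nz)) {
      g[, nz] <- g[, nz] + lambda * sweep(U[, nz, drop = FALSE], 2, cn[nz], "/")
    }
  }
  max(abs(g * U))
}
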