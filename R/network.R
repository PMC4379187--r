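#' Construct a network from an adjacency matrix
#'
#' A `gsnmf_network` wraps a dense symmetric nonnegative adjacency matrix
#' together with ordered vertex labels. Edge weights are arbitrary nonnegative
#' reals; simple unweighted graphs use weight 1. The diagonal is zero unless
#' self-loops are explicitly present in the input.
#'
#' @param adjacency Symmetric nonnegative numeric matrix (N x N).
#' @param labels Character vector of N unique vertex labels. Defaults to
#'   existing dimnames or `"v1" ... "vN"`.
#' @return An object of class `gsnmf_network` with fields `adjacency`,
#'   `labels`, `n_vertices`, `n_edges` (number of unordered linked pairs,
#'   excluding self-loops).
#' @export
#' @examples
#' a <- matrix(c(0, 1, 1, 0), 2, 2)
#' network(a, c("a", "b"))
network <- function(adjacency, labels = NULL) {
  if (!is.matrix(adjacency) || !is.numeric(adjacency)) {
    stop("`adjacency` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("`adjacency` must be square", call. = FALSE)
  if (any(adjacency < 0)) stop("`adjacency` must be nonnegative", call. = FALSE)
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    stop("`adjacency` must be symmetric", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- rownames(adjacency) %||% paste0("v", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels)) {
    stop("`labels` must be ", n, " unique strings", call. = FALSE)
  }
  adjacency <- unname(adjacency)
  off <- adjacency
  diag(off) <- 0
  structure(
    list(
      adjacency = adjacency,
      labels = labels,
      n_vertices = n,
      n_edges = sum(off[upper.tri(off)] > 0)
    ),
    class = "gsnmf_network"
  )
}

#' @export
print.gsnmf_network <- function(x, ...) {
  w <- x$adjacency[upper.tri(x$adjacency)]
  cat(sprintf(
    "<gsnmf_network> %d vertices, %d edges%s\n",
    x$n_vertices, x$n_edges,
    if (all(w %in% c(0, 1))) " (unweighted)" else " (weighted)"
  ))
  invisible(x)
}

# Accept either a gsnmf_network or a bare symmetric matrix everywhere.
as_adjacency <- function(x) {
  if (inherits(x, "gsnmf_network")) x$adjacency else network(x)$adjacency
}

network_labels <- function(x, n) {
  if (inherits(x, "gsnmf_network")) x$labels else paste0("v", seq_len(n))
}

#' Edges of a network as a tibble
#'
#' @param x A [network()] object.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to` (vertex labels) and `weight`,
#'   one row per unordered linked pair.
#' @export
as_tibble.gsnmf_network <- function(x, ...) {
  idx <- which(upper.tri(x$adjacency, diag = TRUE) & x$adjacency > 0,
               arr.ind = TRUE)
  tibble::tibble(
    from = x$labels[idx[, 1]],
    to = x$labels[idx[, 2]],
    weight = x$adjacency[idx]
  )
}

#' Read an undirected network from a whitespace-delimited edge list
#'
#' Each non-comment line holds `"u v"` (or `"u v w"` when `weighted = TRUE`).
#' Lines starting with `#` or `%` are comments. An edge listed once induces
#' both `A[i, j]` and `A[j, i]`; a pair listed repeatedly keeps the last
#' weight seen. Vertices are indexed in first-appearance order.
#'
#' @param path Path to the edge-list file.
#' @param weighted If `TRUE`, a third token per line is parsed as a
#'   nonnegative real edge weight; otherwise every edge has weight 1.
#' @return A [network()] object.
#' @export
read_edge_list <- function(path, weighted = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|#|%)", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  lineno <- which(keep)
  want <- if (weighted) 3L else 2L
  nt <- lengths(toks)
  # allow a weight column to be present but ignored when weighted = FALSE
  bad <- if (weighted) nt != 3L else !(nt %in% c(2L, 3L))
  if (any(bad)) {
    stop(sprintf("malformed edge-list line %d: expected %d tokens, got %d",
                 lineno[which(bad)[1]], want, nt[which(bad)[1]]),
         call. = FALSE)
  }
  from <- vapply(toks, `[[`, "", 1L)
  to <- vapply(toks, `[[`, "", 2L)
  if (weighted) {
    w <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 3L)))
    if (anyNA(w)) {
      stop(sprintf("malformed edge-list line %d: weight does not parse",
                   lineno[which(is.na(w))[1]]), call. = FALSE)
    }
    if (any(w < 0)) {
      stop(sprintf("negative weight on line %d", lineno[which(w < 0)[1]]),
           call. = FALSE)
    }
  } else {
    w <- rep(1, length(from))
  }
  labels <- unique(c(rbind(from, to)))
  n <- length(labels)
  a <- matrix(0, n, n)
  i <- match(from, labels)
  j <- match(to, labels)
  # later duplicates overwrite earlier ones
  a[cbind(i, j)] <- w
  a[cbind(j, i)] <- w
  network(a, labels)
}

#' Write a network as a whitespace-delimited edge list
#'
#' @param x A [network()] object.
#' @param path Output file path.
#' @param weighted Include the weight as a third column.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path, weighted = !all(x$adjacency %in% c(0, 1))) {
  ed <- as_tibble.gsnmf_network(x)
  lines <- if (weighted) {
    sprintf("%s %s %.10g", ed$from, ed$to, ed$weight)
  } else {
    sprintf("%s %s", ed$from, ed$to)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a community cover
#'
#' A cover is a list of vertex-index sets, possibly overlapping and (after
#' pruning) possibly non-covering. Hard partitions are the disjoint special
#' case.
#'
#' @param communities List of integer vectors of vertex indices (1-based).
#' @param n_vertices Number of vertices in the underlying network.
#' @param labels Optional vertex labels carried along for serialization.
#' @return An object of class `gsnmf_cover`.
#' @export
cover <- function(communities, n_vertices, labels = NULL) {
  communities <- unname(lapply(communities,
                               function(v) sort(unique(as.integer(v)))))
  if (any(lengths(communities) == 0)) {
    stop("communities must be non-empty", call. = FALSE)
  }
  idx <- unlist(communities, use.names = FALSE)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_vertices)) {
    stop("vertex index out of range", call. = FALSE)
  }
  structure(
    list(
      communities = communities,
      n_communities = length(communities),
      n_vertices = as.integer(n_vertices),
      labels = labels %||% paste0("v", seq_len(n_vertices))
    ),
    class = "gsnmf_cover"
  )
}

#' @export
print.gsnmf_cover <- function(x, ...) {
  ov <- sum(tabulate(unlist(x$communities), x$n_vertices) > 1)
  cat(sprintf("<gsnmf_cover> %d communities over %d vertices (%d overlapping)\n",
              x$n_communities, x$n_vertices, ov))
  invisible(x)
}

#' Convert a cover to a hard-partition labeling if it is disjoint
#'
#' @param x A [cover()].
#' @return Integer vector of community labels, or an error if the cover
#'   overlaps or leaves vertices unassigned.
#' @export
as_partition <- function(x) {
  stopifnot(inherits(x, "gsnmf_cover"))
  counts <- tabulate(unlist(x$communities), x$n_vertices)
  if (any(counts != 1L)) {
    stop("cover is not a partition (overlapping or uncovered vertices)",
         call. = FALSE)
  }
  lab <- integer(x$n_vertices)
  for (k in seq_along(x$communities)) lab[x$communities[[k]]] <- k
  lab
}

#' Read communities from a file (one community per line)
#'
#' The format matches the LFR-benchmark ground-truth convention: each line
#' lists the vertex labels of one community, whitespace-delimited. Overlap is
#' allowed; empty lines are ignored.
#'
#' @param path Path to the community file.
#' @param labels Character vector of known vertex labels, in network order.
#' @return A [cover()].
#' @export
read_communities <- function(path, labels) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*($|#|%)", lines)]
  comms <- lapply(strsplit(trimws(lines), "\\s+"), function(tok) {
    idx <- match(tok, labels)
    if (anyNA(idx)) {
      stop("unknown vertex label: ", tok[which(is.na(idx))[1]], call. = FALSE)
    }
    idx
  })
  cover(comms, length(labels), labels)
}

#' Write a cover to a community file (one community per line)
#'
#' @param x A [cover()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_communities <- function(x, path) {
  stopifnot(inherits(x, "gsnmf_cover"))
  writeLines(
    vapply(x$communities, function(v) paste(x$labels[v], collapse = " "), ""),
    path
  )
  invisible(path)
}

#' Load an embedded canonical test network
#'
#' Four small benchmark networks ship with the package as plain-text edge
#' lists with ground-truth groupings: Zachary's karate club (34 vertices,
#' 78 edges, 2 factions), the Doubtful Sound dolphin social network
#' (62 vertices, 159 edges, 2 groups), American college football
#' (115 vertices, 613 edges, 12 conferences), and a political-books
#' co-purchase surrogate. The karate and football fixtures are the published
#' edge lists; the dolphins fixture is a transcription of the published
#' network matching its vertex/edge counts and degree statistics. The
#' `"polbooks"` fixture is a *synthetic* stand-in: a three-block network
#' matching the published summary statistics (105 vertices, 441 edges,
#' groups of 49/43/13), not the original co-purchase data.
#'
#' @param name One of `"karate"`, `"dolphins"`, `"polbooks"`, `"football"`.
#' @return A list with elements `network` (a [network()]) and `ground_truth`
#'   (a [cover()]).
#' @export
#' @examples
#' load_fixture("karate")$network
load_fixture <- function(name) {
  files <- c(karate = "karate", dolphins = "dolphins",
             polbooks = "polbooks_synthetic", football = "football")
  if (length(name) != 1 || !name %in% names(files)) {
    stop("unknown fixture; available: ", paste(names(files), collapse = ", "),
         call. = FALSE)
  }
  stem <- files[[name]]
  edge_path <- system.file("extdata", paste0(stem, ".txt"), package = "gsnmf",
                           mustWork = TRUE)
  truth_path <- system.file("extdata", paste0(stem, "_truth.txt"),
                            package = "gsnmf", mustWork = TRUE)
  net <- read_edge_list(edge_path)
  list(network = net, ground_truth = read_communities(truth_path, net$labels))
}
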