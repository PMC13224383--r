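#' Build a symmetrized k-nearest-neighbor graph on cell coordinates
#'
#' Exact Euclidean k-NN with a deterministic index-order tiebreak: each cell's
#' neighbors are the first k others when sorted by (distance, index). The
#' result is symmetrized by union (a pair is kept when either endpoint lists
#' the other), matching the usual undirected neighborhood-graph reading;
#' mutual symmetrization (intersection) is available as an option.
#'
#' @param coords N x 2 numeric matrix.
#' @param k neighbor count, `1 <= k < N`.
#' @param symmetrize `"union"` (default) or `"mutual"`.
#' @param duplicates `"error"` (default) to reject duplicated coordinates, or
#'   `"jitter"` to perturb them deterministically by a negligible amount.
#' @param seed seed for the jitter (only used when `duplicates = "jitter"`).
#' @return An m x 2 integer matrix of undirected pairs with `pair[, 1] <
#'   pair[, 2]`, ordered lexicographically.
#' @export
build_knn_graph <- function(coords, k, symmetrize = c("union", "mutual"),
                            duplicates = c("error", "jitter"), seed = 1L) {
  symmetrize <- match.arg(symmetrize)
  duplicates <- match.arg(duplicates)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 cells", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (", n, ")",
                   call. = FALSE)
  if (anyDuplicated(coords)) {
    if (duplicates == "error") {
      stop("duplicate coordinates present; set duplicates = \"jitter\" to perturb them",
           call. = FALSE)
    }
    eps <- 1e-9 * max(1, max(abs(coords)))
    dup <- duplicated(coords)
    coords[dup, ] <- coords[dup, , drop = FALSE] +
      withr::with_seed(seed, matrix(runif(2 * sum(dup), -eps, eps), ncol = 2))
  }
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  pairs_i <- integer(0)
  pairs_j <- integer(0)
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    nb[i, ] <- ord[seq_len(k)]
  }
  a <- rep(seq_len(n), each = k)
  b <- as.integer(t(nb))
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi)
  if (symmetrize == "union") {
    keep <- !duplicated(key)
  } else {
    keep <- duplicated(key)            # second occurrence => both directions listed
  }
  lo <- lo[keep]; hi <- hi[keep]
  ord <- order(lo, hi)
  cbind(parent = lo[ord], child = hi[ord])  # names overwritten by callers
}

#' Orient neighbor pairs along decreasing isodepth into a DAG
#'
#' Each undirected pair (i, j) becomes the directed edge i -> j when
#' `d_i > d_j` (and j -> i when `d_j > d_i`). Pairs with exactly equal
#' potential are dropped and counted, preserving the strict rule that every
#' edge descends the potential — which guarantees acyclicity, re-verified on
#' the result.
#'
#' @param pairs m x 2 integer matrix of undirected pairs.
#' @param field an `isodepth_field` (or numeric potential vector).
#' @param k optional neighbor count recorded for provenance.
#' @return An object of class `spatial_dag`: list with `n_vertices`, `edges`
#'   (m' x 2 integer matrix, columns parent/child), `potential`,
#'   `n_dropped_ties`, `k`.
#' @export
orient_edges <- function(pairs, field, k = NA_integer_) {
  d <- if (is(field, "isodepth_field")) field$values else as.numeric(field)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) > 0 && max(pairs) > length(d)) {
    stop("pair indices exceed the number of vertices", call. = FALSE)
  }
  if (nrow(pairs) == 0L) {
    edges <- matrix(integer(0), 0, 2)
    ties <- 0L
  } else {
    di <- d[pairs[, 1]]
    dj <- d[pairs[, 2]]
    tie <- di == dj
    ties <- sum(tie)
    fwd <- di > dj & !tie
    parent <- ifelse(fwd, pairs[, 1], pairs[, 2])[!tie]
    child <- ifelse(fwd, pairs[, 2], pairs[, 1])[!tie]
    edges <- cbind(parent = as.integer(parent), child = as.integer(child))
    if (nrow(edges) > 0) edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  if (nrow(edges) > 0 && any(d[edges[, 1]] <= d[edges[, 2]])) {
    stop("internal error: an oriented edge does not strictly descend the potential",
         call. = FALSE)
  }
  structure(list(n_vertices = length(d), edges = edges, potential = d,
                 n_dropped_ties = as.integer(ties), k = k),
            class = "spatial_dag")
}

#' @export
print.spatial_dag <- function(x, ...) {
  cat("spatial_dag:", x$n_vertices, "vertices,", nrow(x$edges), "edges")
  if (x$n_dropped_ties > 0) cat(" (", x$n_dropped_ties, " tie pair(s) dropped)", sep = "")
  cat("\n")
  invisible(x)
}

#' Reverse every edge of a spatial DAG
#'
#' Equivalent to re-orienting the same neighbor pairs under the inverted
#' potential, which is how the opposite direction of information flow is
#' probed.
#'
#' @param dag a `spatial_dag`.
#' @return A `spatial_dag` with reversed edges and negated potential ordering.
#' @export
reverse_dag <- function(dag) {
  stopifnot(is(dag, "spatial_dag"))
  edges <- dag$edges[, c(2, 1), drop = FALSE]
  colnames(edges) <- c("parent", "child")
  if (nrow(edges) > 0) edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  out <- dag
  out$edges <- edges
  out$potential <- max(dag$potential) - dag$potential
  out
}

#' Per-lag ancestor-aggregation operators
#'
#' For lag l, the operator is the row-normalized l-th power of the transposed
#' 0/1 adjacency matrix: entry (v, u) is positive iff a directed walk of
#' length l runs u -> ... -> v, with weight proportional to the number of
#' such walks, and each nonzero row sums to one so a vertex's lag-l feature
#' is a (walk-weighted) average over its l-step ancestors. Vertices with no
#' l-step ancestor get an all-zero row.
#'
#' @param dag a `spatial_dag`.
#' @param max_lag maximum lag L (>= 1).
#' @return An object of class `lag_operators`: list with `ops` (list of L
#'   sparse N x N matrices) and `max_lag`.
#' @export
build_lag_operators <- function(dag, max_lag) {
  stopifnot(is(dag, "spatial_dag"))
  L <- as.integer(max_lag)
  if (L < 1L) stop("max_lag must be >= 1", call. = FALSE)
  n <- dag$n_vertices
  if (nrow(dag$edges) == 0L) {
    M <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  } else {
    M <- Matrix::sparseMatrix(i = dag$edges[, 2], j = dag$edges[, 1], x = 1,
                              dims = c(n, n))
  }
  row_normalize <- function(A) {
    rs <- Matrix::rowSums(A)
    sc <- ifelse(rs > 0, 1 / rs, 0)
    Matrix::Diagonal(x = sc) %*% A
  }
  ops <- vector("list", L)
  P <- M
  ops[[1]] <- row_normalize(P)
  if (L > 1L) {
    for (l in 2:L) {
      P <- P %*% M
      ops[[l]] <- row_normalize(P)
    }
  }
  structure(list(ops = ops, max_lag = L, n_vertices = n), class = "lag_operators")
}

#' Topological order of a DAG (Kahn's algorithm)
#'
#' Returns a vertex ordering in which every edge points forward, or raises if
#' the graph contains a cycle. Exposed mainly for validation.
#'
#' @param edges m x 2 integer matrix (parent, child).
#' @param n_vertices vertex count.
#' @return Integer vector of length `n_vertices`.
#' @export
topological_order <- function(edges, n_vertices) {
  indeg <- integer(n_vertices)
  adj <- vector("list", n_vertices)
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      p <- edges[e, 1]; c_ <- edges[e, 2]
      indeg[c_] <- indeg[c_] + 1L
      adj[[p]] <- c(adj[[p]], c_)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != n_vertices) stop("graph contains a cycle", call. = FALSE)
  out
}

#' Export DAG edges as TSV
#'
#' @param dag a `spatial_dag`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dag <- function(dag, path) {
  stopifnot(is(dag, "spatial_dag"))
  write.table(data.frame(parent = dag$edges[, 1], child = dag$edges[, 2]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
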