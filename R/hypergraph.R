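#' Hypergraph objects
#'
#' A hypergraph over n sample vertices is stored as a sparse binary incidence
#' matrix H (vertices x hyperedges) together with the diagonal quantities that
#' define its unnormalized Laplacian: per-hyperedge weights w(e), vertex
#' degrees d(v) = sum_e w(e) H(v,e), and hyperedge degrees f(e) = sum_v H(v,e)
#' (the column sums of H). The Laplacian is
#'
#'   L = Dv - H W De^-1 H^T
#'
#' where Dv, W and De are the diagonal matrices of d(v), w(e) and f(e). The
#' second term, `adjacency_like`, plays the role of the adjacency matrix in a
#' simple graph and is what the regularized factorization update needs
#' separately from Dv.
#'
#' @param incidence sparse or dense binary vertex-by-hyperedge matrix.
#' @param edge_weights non-negative per-hyperedge weights.
#' @return An object of class `hypergraph` with fields `n_vertices`,
#'   `n_hyperedges`, `incidence`, `edge_weights`, `vertex_degrees`,
#'   `edge_degrees`, `adjacency_like` and `laplacian`.
#' @keywords internal
new_hypergraph <- function(incidence, edge_weights) {
  H <- methods::as(methods::as(incidence, "CsparseMatrix"), "dMatrix")
  n <- nrow(H)
  ne <- ncol(H)
  w <- as.numeric(edge_weights)
  assert_that(length(w) == ne, "edge_weights length must equal number of hyperedges")
  assert_that(all(w >= 0), "edge_weights must be non-negative")
  f <- Matrix::colSums(H)
  assert_that(all(f >= 1), "every hyperedge must contain at least one vertex")
  dv <- as.numeric(H %*% w)
  # E = H W De^-1 H^T realized by scaling columns of H by w/f
  Hs <- H %*% Matrix::Diagonal(ne, w / f)
  E <- Matrix::tcrossprod(Hs, H)
  L <- Matrix::Diagonal(n, dv) - E
  structure(list(
    n_vertices = n,
    n_hyperedges = ne,
    incidence = H,
    edge_weights = w,
    vertex_degrees = dv,
    edge_degrees = f,
    adjacency_like = E,
    laplacian = L
  ), class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("Hypergraph: %d vertices, %d hyperedges\n",
              x$n_vertices, x$n_hyperedges))
  cat(sprintf("  hyperedge degrees: %s\n",
              paste(utils::head(x$edge_degrees, 8), collapse = ", ")))
  cat(sprintf("  total vertex degree: %.4g\n", sum(x$vertex_degrees)))
  invisible(x)
}

#' Build a k-nearest-neighbor hypergraph over samples
#'
#' One hyperedge per sample: hyperedge i contains the centroid vertex i plus
#' its `g` nearest neighbors in Euclidean distance (ties broken by sample
#' index, so the construction is deterministic). The hyperedge weight is the
#' heat-kernel sum over its members,
#'
#'   w(e_i) = sum_{j in e_i} exp(-||v_i - v_j||^2 / delta_i),
#'   delta_i = (1/g) * sum_{j in e_i} ||v_i - v_j||^2,
#'
#' the centroid's own zero distance contributing exp(0) = 1. When all members
#' coincide with the centroid (delta_i = 0) the continuity limit w = g + 1 is
#' used.
#'
#' @param points numeric n x p matrix, one sample per row.
#' @param g neighbor count (>= 1); needs at least g + 1 points.
#' @return A [hypergraph][new_hypergraph] with n hyperedges.
#' @examples
#' pts <- cbind(c(0, 1, 2, 3, 4))
#' hg <- build_knn_hypergraph(pts, g = 2)
#' hg$edge_degrees  # all 3 = centroid + 2 neighbors
#' @export
build_knn_hypergraph <- function(points, g) {
  points <- as.matrix(points)
  check_matrix(points, "points")
  n <- nrow(points)
  assert_that(length(g) == 1 && g >= 1 && g == round(g), "g must be a positive integer")
  assert_that(n >= g + 1, sprintf("need at least g + 1 = %d points, got %d", g + 1, n))
  d2 <- as.matrix(stats::dist(points))^2
  members <- vector("list", n)
  w <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ], seq_len(n))     # stable: ties by sample index
    nb <- setdiff(ord, i)[seq_len(g)]
    e <- c(i, nb)
    delta <- sum(d2[i, e]) / g
    w[i] <- if (delta > 0) sum(exp(-d2[i, e] / delta)) else g + 1
    members[[i]] <- e
  }
  H <- Matrix::sparseMatrix(
    i = unlist(members),
    j = rep(seq_len(n), vapply(members, length, 1L)),
    x = 1, dims = c(n, n)
  )
  new_hypergraph(H, w)
}

#' Build a hypergraph from an explicit hyperedge list
#'
#' Construction path for worked examples and tests: each element of `edges`
#' is a vector of vertex indices forming one hyperedge. Weights default to 1.
#'
#' @param edges list of integer vectors (1-based vertex indices), each
#'   non-empty.
#' @param weights optional per-hyperedge weights (default all 1).
#' @param n_vertices optional vertex count (default: largest index used).
#' @return A [hypergraph][new_hypergraph].
#' @examples
#' hg <- hypergraph_from_edges(list(c(1, 2, 3), c(3, 4, 5), c(5, 6, 7, 8)))
#' hg$edge_degrees  # 3, 3, 4
#' @export
hypergraph_from_edges <- function(edges, weights = NULL, n_vertices = NULL) {
  assert_that(is.list(edges) && length(edges) >= 1, "edges must be a non-empty list")
  sizes <- vapply(edges, length, 1L)
  assert_that(all(sizes >= 1), "every hyperedge must be non-empty")
  idx <- unlist(edges)
  assert_that(all(idx == round(idx)) && all(idx >= 1), "vertex indices must be positive integers")
  n <- if (is.null(n_vertices)) max(idx) else n_vertices
  assert_that(max(idx) <= n, "vertex index exceeds n_vertices")
  if (is.null(weights)) weights <- rep(1, length(edges))
  H <- Matrix::sparseMatrix(
    i = idx,
    j = rep(seq_along(edges), sizes),
    x = 1, dims = c(n, length(edges))
  )
  # duplicated vertex within an edge would make H binary anyway; forbid it
  assert_that(all(H@x == 1), "a hyperedge lists the same vertex twice")
  new_hypergraph(H, weights)
}

#' Hypergraph smoothness penalty Tr(V L V^T)
#'
#' The manifold regularizer on a k x n coefficient matrix whose columns are
#' sample embeddings: equal (up to numerical rounding) to the pairwise form
#' (1/2) sum_e sum_{(i,j) in e} (w(e)/f(e)) ||s_i - s_j||^2.
#'
#' @param V numeric k x n matrix (columns are samples).
#' @param laplacian n x n hypergraph (or graph) Laplacian, or a `hypergraph`
#'   object.
#' @return scalar penalty, >= 0 up to rounding for a PSD Laplacian.
#' @export
hypergraph_regularizer <- function(V, laplacian) {
  if (inherits(laplacian, "hypergraph")) laplacian <- laplacian$laplacian
  V <- as.matrix(V)
  check_matrix(V, "V")
  assert_that(nrow(laplacian) == ncol(laplacian), "laplacian must be square")
  assert_that(ncol(V) == nrow(laplacian),
              "ncol(V) must equal the Laplacian dimension")
  as.numeric(sum(as.matrix(V %*% laplacian) * V))
}

# Mutual-kNN adjacency over sample rows; binary weights by default,
# heat-kernel weights exp(-d^2 / sigma) with sigma the mean squared distance
# over retained pairs when weighting = "heat".
simple_graph_parts <- function(points, g, weighting = c("binary", "heat")) {
  weighting <- match.arg(weighting)
  points <- as.matrix(points)
  check_matrix(points, "points")
  n <- nrow(points)
  assert_that(g >= 1 && g == round(g), "g must be a positive integer")
  assert_that(n >= g + 1, sprintf("need at least g + 1 = %d points, got %d", g + 1, n))
  d2 <- as.matrix(stats::dist(points))^2
  nn <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ], seq_len(n))
    nn[i, setdiff(ord, i)[seq_len(g)]] <- TRUE
  }
  A <- (nn & t(nn)) * 1               # mutual kNN, symmetric by construction
  if (weighting == "heat") {
    keep <- A > 0
    sigma <- mean(d2[keep])
    if (is.nan(sigma) || sigma <= 0) sigma <- 1
    A <- ifelse(keep, exp(-d2 / sigma), 0)
  }
  list(adjacency = A, degrees = rowSums(A))
}

#' Simple-graph Laplacian over a mutual kNN graph
#'
#' Pairwise-relation counterpart of [build_knn_hypergraph()], used by the
#' graph-regularized (GNMF/RGNMF) solver variants: vertices i and j are
#' connected when each is among the other's `g` nearest neighbors. Binary
#' weights by default; `weighting = "heat"` uses a heat kernel.
#'
#' @inheritParams build_knn_hypergraph
#' @param weighting `"binary"` (default) or `"heat"`.
#' @return symmetric positive semidefinite n x n Laplacian matrix D - A.
#' @export
build_simple_graph_laplacian <- function(points, g, weighting = c("binary", "heat")) {
  parts <- simple_graph_parts(points, g, weighting)
  diag(parts$degrees, nrow = length(parts$degrees)) - parts$adjacency
}

#' Export a hypergraph as plain-text tables
#'
#' Writes a two-column membership TSV (`edge_id`, `vertex_id`) and a
#' two-column per-edge weight TSV (`edge_id`, `weight`). There is no standard
#' interchange format for hypergraphs, so these are deliberately minimal.
#'
#' @param hg a `hypergraph`.
#' @param membership_path,weights_path output file paths.
#' @return invisibly, the membership data frame.
#' @export
write_hypergraph <- function(hg, membership_path, weights_path) {
  assert_that(inherits(hg, "hypergraph"), "hg must be a hypergraph")
  idx <- Matrix::which(hg$incidence != 0, arr.ind = TRUE)
  mem <- data.frame(edge_id = idx[, 2], vertex_id = idx[, 1])
  mem <- mem[order(mem$edge_id, mem$vertex_id), ]
  utils::write.table(mem, membership_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(edge_id = seq_len(hg$n_hyperedges), weight = hg$edge_weights),
    weights_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mem)
}
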