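#' L2,1 norm of a matrix
#'
#' Row-wise Euclidean norms summed: `sum_i ||M[i, ]||_2`. Applied to the
#' transposed residual of an expression matrix (samples in columns) this is
#' the robust per-sample loss used by the solver.
#'
#' @param M numeric matrix.
#' @return scalar.
#' @examples
#' l21_norm(diag(2))            # 2
#' l21_norm(rbind(c(3, 4), 0))  # 5
#' @export
l21_norm <- function(M) {
  M <- as.matrix(M)
  check_matrix(M, "M")
  sum(sqrt(rowSums(M^2)))
}

#' Per-sample residual reweighting
#'
#' The diagonal of the iteratively-reweighted-least-squares matrix D that
#' turns the per-sample L2,1 loss into a weighted Frobenius surrogate:
#'
#'   D_jj = 1 / sqrt(||x_j - U v_j||^2 + gamma)
#'
#' with gamma a small smoothing constant keeping D finite at exact fits.
#' Columns fit poorly (outliers) receive small weights, which is the
#' robustness mechanism of the l21 solver.
#'
#' @param X m x n data matrix.
#' @param U m x k basis.
#' @param V k x n coefficients.
#' @param gamma smoothing constant > 0 (default 1e-8).
#' @return strictly positive length-n vector.
#' @export
residual_weights <- function(X, U, V, gamma = 1e-8) {
  assert_that(gamma > 0, "gamma must be > 0")
  R <- X - U %*% V
  1 / sqrt(colSums(R^2) + gamma)
}

#' Objective value of the regularized factorization
#'
#' Data-fit term plus manifold penalty: with `norm = "l21"` the fit term is
#' the sum of per-sample residual norms `sum_j ||x_j - U v_j||_2` (the L2,1
#' norm of the transposed residual); with `norm = "frobenius"` it is the
#' squared Frobenius norm. The penalty is `alpha * Tr(V L V^T)` when a
#' Laplacian is supplied.
#'
#' @inheritParams residual_weights
#' @param laplacian optional n x n Laplacian (or `hypergraph` object);
#'   `NULL` drops the penalty.
#' @param alpha penalty weight >= 0.
#' @param norm `"l21"` or `"frobenius"`.
#' @return finite scalar.
#' @export
rhnmf_objective <- function(X, U, V, laplacian = NULL, alpha = 0,
                            norm = c("l21", "frobenius")) {
  norm <- match.arg(norm)
  assert_that(nrow(U) == nrow(X) && ncol(V) == ncol(X) && ncol(U) == nrow(V),
              "dimension mismatch among X, U, V")
  R <- X - U %*% V
  fit <- if (norm == "l21") sum(sqrt(colSums(R^2))) else sum(R^2)
  pen <- if (!is.null(laplacian) && alpha > 0) {
    alpha * hypergraph_regularizer(V, laplacian)
  } else 0
  fit + pen
}

# Multiplicative updates. `d` is the diagonal of D (length n); eps floors the
# denominator so zero entries never divide (multiplicative zeros stay zero).

#' @rdname rhnmf_fit
#' @param d positive length-n vector, diagonal of the reweighting matrix D.
#' @param eps denominator floor guarding against 0/0 (default 1e-12).
#' @export
update_u <- function(X, U, V, d, eps = 1e-12) {
  Xd <- X * rep(d, each = nrow(X))
  num <- Xd %*% t(V)
  Vd <- V * rep(d, each = nrow(V))
  den <- U %*% tcrossprod(Vd, V)
  U * (num / (den + eps))
}

#' @rdname rhnmf_fit
#' @param E n x n adjacency-like part of the Laplacian (enters the
#'   numerator), or `NULL` when unregularized.
#' @param dv vertex degrees, diagonal of Dv (enters the denominator).
#' @export
update_v <- function(X, U, V, d, E = NULL, dv = NULL, alpha = 0, eps = 1e-12) {
  Xd <- X * rep(d, each = nrow(X))
  num <- crossprod(U, Xd)
  Vd <- V * rep(d, each = nrow(V))
  den <- crossprod(U) %*% Vd
  if (!is.null(E) && alpha > 0) {
    num <- num + alpha * (V %*% E)
    den <- den + alpha * (V * rep(dv, each = nrow(V)))
  }
  V * (num / (den + eps))
}

#' Solver configuration
#'
#' Bundles every knob of the factorization family. The flags select the
#' variant: `norm = "frobenius", manifold = "none"` is classical NMF;
#' `norm = "l21"` alone is robust NMF; adding `manifold = "simple_graph"` or
#' `"hypergraph"` gives the graph- and hypergraph-regularized variants
#' (GNMF/HNMF with the Frobenius loss, RGNMF/RHNMF with the robust loss).
#'
#' @param k factorization rank (>= 1).
#' @param alpha manifold penalty weight >= 0 (ignored when
#'   `manifold = "none"`).
#' @param norm residual loss, `"l21"` (robust, per-sample) or `"frobenius"`.
#' @param manifold `"none"`, `"simple_graph"` or `"hypergraph"`.
#' @param g neighbor count for the kNN (hyper)graph (default 5).
#' @param max_iter maximum update sweeps (default 1000).
#' @param tol relative objective-change stopping threshold (default 1e-6).
#' @param gamma L2,1 smoothing constant > 0 (default 1e-8).
#' @param seed RNG seed for the random initialization.
#' @param preprocess `"none"` (default) or `"log1p"` applied to X before
#'   fitting.
#' @return a `fit_config` list.
#' @export
fit_config <- function(k, alpha = 0, norm = c("l21", "frobenius"),
                       manifold = c("none", "simple_graph", "hypergraph"),
                       g = 5, max_iter = 1000, tol = 1e-6, gamma = 1e-8,
                       seed = 1, preprocess = c("none", "log1p")) {
  norm <- match.arg(norm)
  manifold <- match.arg(manifold)
  preprocess <- match.arg(preprocess)
  assert_that(length(k) == 1 && k >= 1 && k == round(k), "k must be a positive integer")
  assert_that(alpha >= 0, "alpha must be >= 0")
  assert_that(gamma > 0, "gamma must be > 0")
  assert_that(max_iter >= 1, "max_iter must be >= 1")
  assert_that(tol >= 0, "tol must be >= 0")
  structure(list(k = as.integer(k), alpha = alpha, norm = norm,
                 manifold = manifold, g = as.integer(g),
                 max_iter = as.integer(max_iter), tol = tol, gamma = gamma,
                 seed = as.integer(seed), preprocess = preprocess),
            class = "fit_config")
}

#' Default grid for the penalty weight alpha
#'
#' `10^r` for r = -5, ..., 5, the conventional cross-validation grid for the
#' manifold penalty.
#' @return numeric vector of length 11, ascending.
#' @export
alpha_grid <- function() 10^(-5:5)

#' Fit the robust hypergraph-regularized NMF family
#'
#' Factorizes a non-negative m x n expression matrix X (genes in rows,
#' samples in columns) as X ~ U V with U (m x k) and V (k x n) non-negative,
#' minimizing
#'
#'   sum_j ||x_j - U v_j||_2  +  alpha * Tr(V L V^T)
#'
#' for the robust `"l21"` loss (squared Frobenius for `"frobenius"`), where L
#' is the kNN hypergraph or simple-graph Laplacian over samples (absent for
#' `manifold = "none"`). Each sweep recomputes the per-sample weights D, then
#' applies the multiplicative updates
#'
#'   u_ik <- u_ik (X D V^T)_ik / (U V D V^T)_ik
#'   v_kj <- v_kj (U^T X D + alpha V E)_kj / (U^T U V D + alpha V Dv)_kj
#'
#' with D = I fixed for the Frobenius loss (recovering the classical
#' Lee-Seung rules and their graph-regularized extensions). Iteration stops
#' when the relative objective change drops below `tol` or after `max_iter`
#' sweeps. U and V are initialized Uniform(0,1) scaled by sqrt(mean(X)/k),
#' under `config$seed`; the caller's RNG state is untouched.
#'
#' @param X non-negative numeric matrix, genes x samples.
#' @param config a [fit_config()].
#' @return `rhnmf_fit` object: `U`, `V`, `objective_trajectory`,
#'   `final_residual_weights` (diagonal of D), `iterations_run`, `converged`,
#'   `config`, and the `laplacian` used (or NULL).
#' @examples
#' sim <- generate_dataset(synth_params(m = 60, n = 40, c = 2, seed = 1))
#' fit <- rhnmf_fit(sim$X, fit_config(k = 2, alpha = 1, manifold = "hypergraph",
#'                                    max_iter = 100, seed = 1))
#' plot(fit$objective_trajectory, type = "l")
#' @export
rhnmf_fit <- function(X, config) {
  assert_that(inherits(config, "fit_config"), "config must come from fit_config()")
  X <- as.matrix(X)
  check_nonnegative(X, "X")
  if (config$preprocess == "log1p") X <- log1p(X)
  m <- nrow(X); n <- ncol(X); k <- config$k
  assert_that(k <= min(m, n), sprintf("k = %d exceeds min(dim(X)) = %d", k, min(m, n)))

  parts <- switch(config$manifold,
    none = NULL,
    hypergraph = {
      hg <- build_knn_hypergraph(t(X), config$g)
      list(E = as.matrix(hg$adjacency_like), dv = hg$vertex_degrees,
           L = as.matrix(hg$laplacian))
    },
    simple_graph = {
      sg <- simple_graph_parts(t(X), config$g)
      list(E = sg$adjacency, dv = sg$degrees,
           L = diag(sg$degrees, nrow = n) - sg$adjacency)
    })
  alpha <- if (is.null(parts)) 0 else config$alpha

  init <- with_seed(config$seed, {
    s <- sqrt(mean(X) / k)
    list(U = matrix(stats::runif(m * k), m, k) * s,
         V = matrix(stats::runif(k * n), k, n) * s)
  })
  U <- init$U; V <- init$V

  traj <- numeric(config$max_iter)
  converged <- FALSE
  d <- rep(1, n)
  obj_prev <- Inf
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    if (config$norm == "l21") d <- residual_weights(X, U, V, config$gamma)
    U <- update_u(X, U, V, d)
    V <- update_v(X, U, V, d, E = parts$E, dv = parts$dv, alpha = alpha)
    obj <- rhnmf_objective(X, U, V, laplacian = parts$L, alpha = alpha,
                           norm = config$norm)
    traj[it] <- obj
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) <= config$tol * max(abs(obj_prev), .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  if (config$norm == "l21") d <- residual_weights(X, U, V, config$gamma)

  structure(list(
    U = U, V = V,
    objective_trajectory = traj[seq_len(it)],
    final_residual_weights = d,
    iterations_run = it,
    converged = converged,
    config = config,
    laplacian = parts$L,
    gene_ids = rownames(X),
    sample_ids = colnames(X)
  ), class = "rhnmf_fit")
}

#' @export
print.rhnmf_fit <- function(x, ...) {
  cfg <- x$config
  variant <- paste0(
    if (cfg$norm == "l21") "L2,1" else "Frobenius", " loss, ",
    switch(cfg$manifold, none = "no manifold penalty",
           simple_graph = sprintf("simple-graph penalty (alpha = %g)", cfg$alpha),
           hypergraph = sprintf("hypergraph penalty (alpha = %g)", cfg$alpha)))
  cat(sprintf("Non-negative factorization (%s)\n", variant))
  cat(sprintf("  U: %d x %d, V: %d x %d\n", nrow(x$U), ncol(x$U),
              nrow(x$V), ncol(x$V)))
  cat(sprintf("  %d iterations, converged: %s, final objective: %.6g\n",
              x$iterations_run, x$converged,
              x$objective_trajectory[x$iterations_run]))
  invisible(x)
}
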