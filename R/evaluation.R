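#' Cluster samples from the coefficient matrix
#'
#' K-means on the columns of V (the low-dimensional sample embeddings), with
#' `n_init` restarts, fully seeded.
#'
#' @param V k x n coefficient matrix; columns are samples.
#' @param n_clusters number of clusters (<= n).
#' @param seed RNG seed.
#' @param n_init number of k-means restarts (best within-cluster sum kept).
#' @return integer labels in 1..n_clusters, length n.
#' @export
cluster_coefficients <- function(V, n_clusters, seed = 1, n_init = 10) {
  V <- as.matrix(V)
  check_matrix(V, "V")
  n <- ncol(V)
  assert_that(n_clusters >= 1 && n_clusters <= n,
              sprintf("n_clusters must be in 1..%d", n))
  if (n_clusters == 1) return(rep(1L, n))
  if (n_clusters == n) return(seq_len(n))  # every sample its own cluster
  with_seed(seed, {
    km <- stats::kmeans(t(V), centers = n_clusters, nstart = n_init,
                        iter.max = 100)
    as.integer(km$cluster)
  })
}

# Shortest-augmenting-path (Kuhn-Munkres) solver for the square assignment
# problem, minimizing total cost. Returns the column assigned to each row.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)       # p[j + 1]: row matched to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

#' Optimal mapping between predicted and true label alphabets
#'
#' Kuhn-Munkres assignment on the confusion matrix: the injective map from
#' predicted labels to true labels that maximizes the number of matched
#' samples. Predicted labels left over when there are more predicted than
#' true classes map to NA.
#'
#' @param pred_labels,true_labels equal-length label vectors (any atomic
#'   type).
#' @return named vector: names are the distinct predicted labels, values the
#'   assigned true labels (NA = unmatched). Attribute `"matched"` holds the
#'   number of correctly mapped samples.
#' @export
best_mapping <- function(pred_labels, true_labels) {
  assert_that(length(pred_labels) >= 1, "empty labelings")
  assert_that(length(pred_labels) == length(true_labels),
              "label vectors must have equal length")
  pf <- factor(pred_labels)
  tf <- factor(true_labels)
  conf <- table(pf, tf)
  r <- nrow(conf); cc <- ncol(conf)
  s <- max(r, cc)
  M <- matrix(0, s, s)
  M[seq_len(r), seq_len(cc)] <- conf
  a <- solve_assignment(max(M) - M)
  map_idx <- a[seq_len(r)]
  vals <- ifelse(map_idx <= cc, levels(tf)[map_idx], NA)
  matched <- sum(M[cbind(seq_len(r), map_idx)])
  structure(stats::setNames(vals, levels(pf)), matched = matched)
}

#' Clustering accuracy (AC)
#'
#' Fraction of samples whose predicted label, after the optimal
#' Kuhn-Munkres relabeling of [best_mapping()], equals the true label.
#' Invariant to any bijective relabeling of either argument; always at least
#' 1/n and exactly 1 iff the partitions coincide up to relabeling.
#'
#' @inheritParams best_mapping
#' @return fraction in `[0, 1]`.
#' @examples
#' accuracy(c(2, 2, 1, 1), c(1, 1, 2, 2))  # 1: a pure relabeling
#' @export
accuracy <- function(pred_labels, true_labels) {
  m <- best_mapping(pred_labels, true_labels)
  as.numeric(attr(m, "matched")) / length(pred_labels)
}

#' Normalized mutual information (NMI) between two partitions
#'
#' Mutual information of the label contingency table divided by the larger
#' of the two partition entropies. A partition with a single class has zero
#' entropy; the degenerate 0/0 is defined as 0. Symmetric and invariant to
#' relabeling; in `[0, 1]`.
#'
#' @inheritParams best_mapping
#' @return fraction in `[0, 1]`.
#' @export
nmi <- function(pred_labels, true_labels) {
  assert_that(length(pred_labels) >= 1, "empty labelings")
  assert_that(length(pred_labels) == length(true_labels),
              "label vectors must have equal length")
  n <- length(pred_labels)
  conf <- table(pred_labels, true_labels)
  p <- conf / n
  pi_ <- rowSums(p)
  pj <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pi_, pj)[nz]))
  h1 <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  h2 <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  den <- max(h1, h2)
  if (den == 0) return(0)
  min(max(mi / den, 0), 1)
}

# Stratified fold assignment: samples of each class are dealt round-robin
# (after a seeded shuffle) so every fold sees every class where possible.
stratified_folds <- function(labels, n_folds, seed = 1) {
  n <- length(labels)
  assert_that(n_folds >= 2 && n_folds <= n,
              "need at least 2 folds and no more folds than samples")
  with_seed(seed, {
    fold <- integer(n)
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Select the manifold penalty weight by cross-validation
#'
#' For each alpha on the grid, the data are split into `n_folds` stratified
#' folds; for each fold the model is fitted on the fold's complement and the
#' clustering accuracy of those samples against their labels is recorded.
#' The alpha with the highest mean accuracy wins; ties go to the smallest
#' alpha (least regularization at equal fit).
#'
#' @param X non-negative genes x samples matrix.
#' @param labels ground-truth sample labels, length `ncol(X)`.
#' @param grid candidate alphas (default [alpha_grid()]); sorted ascending
#'   internally.
#' @param n_folds number of folds (default 5).
#' @param config a [fit_config()] template; its `alpha` is overridden per
#'   grid point.
#' @return list with `best_alpha`, and `mean_ac` per grid value.
#' @export
select_alpha <- function(X, labels, grid = alpha_grid(), n_folds = 5, config) {
  assert_that(length(grid) >= 1, "grid must be non-empty")
  assert_that(length(labels) == ncol(X), "labels must match ncol(X)")
  grid <- sort(grid)
  fold <- stratified_folds(labels, n_folds, seed = config$seed)
  n_classes <- length(unique(labels))
  mean_ac <- vapply(grid, function(a) {
    cfg <- config
    cfg$alpha <- a
    accs <- vapply(seq_len(n_folds), function(f) {
      keep <- fold != f
      cfg$seed <- config$seed + f
      fit <- rhnmf_fit(X[, keep, drop = FALSE], cfg)
      pred <- cluster_coefficients(fit$V, n_classes, seed = cfg$seed)
      accuracy(pred, labels[keep])
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  list(best_alpha = grid[which.max(mean_ac)],
       grid = grid, mean_ac = mean_ac)
}

#' Repeated fit-and-cluster evaluation
#'
#' Runs the full fit + k-means pipeline `n_runs` times under distinct seeds
#' and summarizes AC and NMI as mean and standard deviation, the format used
#' to report clustering benchmarks.
#'
#' @param X non-negative genes x samples matrix.
#' @param config a [fit_config()]; run r uses seed `config$seed + r - 1`.
#' @param true_labels ground-truth labels, length `ncol(X)`.
#' @param n_runs number of repeats (>= 1).
#' @param n_clusters clusters for k-means; default = number of distinct true
#'   labels.
#' @return object of class `repeated_evaluation` with per-run values and
#'   `ac_mean`, `ac_sd`, `nmi_mean`, `nmi_sd`.
#' @export
repeated_evaluation <- function(X, config, true_labels, n_runs = 50,
                                n_clusters = length(unique(true_labels))) {
  assert_that(n_runs >= 1, "n_runs must be >= 1")
  ac <- numeric(n_runs)
  nm <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    fit <- rhnmf_fit(X, cfg)
    pred <- cluster_coefficients(fit$V, n_clusters, seed = cfg$seed)
    ac[r] <- accuracy(pred, true_labels)
    nm[r] <- nmi(pred, true_labels)
  }
  sd0 <- function(x) if (length(x) == 1) 0 else stats::sd(x)
  structure(list(ac = ac, nmi = nm,
                 ac_mean = mean(ac), ac_sd = sd0(ac),
                 nmi_mean = mean(nm), nmi_sd = sd0(nm),
                 n_runs = n_runs),
            class = "repeated_evaluation")
}

#' @export
print.repeated_evaluation <- function(x, ...) {
  cat(sprintf("%d runs\n  AC  (%%): %.2f ± %.2f\n  NMI (%%): %.2f ± %.2f\n",
              x$n_runs, 100 * x$ac_mean, 100 * x$ac_sd,
              100 * x$nmi_mean, 100 * x$nmi_sd))
  invisible(x)
}
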