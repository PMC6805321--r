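#' Parameters of the synthetic expression generator
#'
#' Defaults describe a desk-scale analogue of a 3-class multi-view expression
#' matrix: 300 genes by 150 samples in 3 balanced classes, rank-3 ground
#' truth, mild additive noise and (optionally) a fraction of heavy-tailed
#' outlier samples.
#'
#' @param m number of genes (rows).
#' @param n number of samples (columns).
#' @param c number of sample classes.
#' @param k ground-truth rank (default `c`; must be >= c).
#' @param noise_sd standard deviation of the additive Gaussian noise,
#'   clipped at zero (default 0.1 against planted loadings of order 1).
#' @param outlier_fraction fraction of columns replaced by outliers, in
#'   `[0, 1)`.
#' @param outlier_scale multiplier on the capped half-Cauchy outlier entries
#'   (default 1: outlier entries sit on the data's own scale — typical value
#'   around the planted loading magnitude of 1 — with a heavy tail capped an
#'   order of magnitude above, emulating corrupted rather than astronomically
#'   wrong samples).
#' @param planted_gene_count genes with elevated class-specific loading per
#'   class (default 10).
#' @param seed RNG seed.
#' @return a `synth_params` list.
#' @export
synth_params <- function(m = 300, n = 150, c = 3, k = c, noise_sd = 0.1,
                         outlier_fraction = 0, outlier_scale = 1,
                         planted_gene_count = 10, seed = 1) {
  assert_that(m >= 1 && n >= 1 && c >= 1, "m, n, c must be >= 1")
  assert_that(k >= c, "k must be >= c (one factor per class)")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(outlier_fraction >= 0 && outlier_fraction < 1,
              "outlier_fraction must be in [0, 1)")
  assert_that(outlier_scale > 0, "outlier_scale must be > 0")
  assert_that(c <= n, "need at least one sample per class")
  assert_that(planted_gene_count * c <= m,
              "planted_gene_count * c must not exceed m")
  structure(list(m = as.integer(m), n = as.integer(n), c = as.integer(c),
                 k = as.integer(k), noise_sd = noise_sd,
                 outlier_fraction = outlier_fraction,
                 outlier_scale = outlier_scale,
                 planted_gene_count = as.integer(planted_gene_count),
                 seed = as.integer(seed)),
            class = "synth_params")
}

#' Generate a block-structured non-negative expression matrix
#'
#' Ground truth is a non-negative factorization X0 = U V: each class owns one
#' coefficient row (indicator of its samples plus a small uniform background)
#' and a disjoint set of planted genes with loadings of order 1 (background
#' loadings an order of magnitude smaller). Observed data add truncated
#' Gaussian noise, and `outlier_fraction` of the columns are replaced by
#' capped half-Cauchy noise scaled by `outlier_scale` — heavy-tailed
#' corrupted samples that a squared loss chases and a per-sample L2,1 loss
#' downweights. Fully deterministic given `params$seed`.
#'
#' @param params a [synth_params()].
#' @return `synthetic_dataset`: non-negative `X` (with gene/sample names),
#'   `true_labels`, `true_U`, `true_V`, logical `outlier_mask`, `params`.
#' @export
generate_dataset <- function(params = synth_params()) {
  assert_that(inherits(params, "synth_params"), "params must come from synth_params()")
  p <- params
  with_seed(p$seed, {
    labels <- sort(rep_len(seq_len(p$c), p$n))      # balanced to within 1
    V <- matrix(stats::runif(p$k * p$n, 0, 0.05), p$k, p$n)
    V[cbind(labels, seq_len(p$n))] <- V[cbind(labels, seq_len(p$n))] + 1
    U <- matrix(stats::runif(p$m * p$k, 0, 0.1), p$m, p$k)
    for (a in seq_len(p$c)) {
      rows <- ((a - 1) * p$planted_gene_count + 1):(a * p$planted_gene_count)
      U[rows, a] <- stats::runif(p$planted_gene_count, 0.8, 1.2)
    }
    X <- U %*% V + matrix(stats::rnorm(p$m * p$n, 0, p$noise_sd), p$m, p$n)
    X <- pmax(X, 0)
    n_out <- round(p$outlier_fraction * p$n)
    mask <- rep(FALSE, p$n)
    if (n_out > 0) {
      idx <- sample(p$n, n_out)
      mask[idx] <- TRUE
      X[, idx] <- p$outlier_scale *
        pmin(abs(stats::rcauchy(p$m * n_out)), 10)
    }
    dimnames(X) <- list(paste0("gene_", seq_len(p$m)),
                        paste0("sample_", seq_len(p$n)))
    structure(list(X = X, true_labels = labels, true_U = U, true_V = V,
                   outlier_mask = mask, params = p),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf("Synthetic dataset: %d genes x %d samples, %d classes (rank %d)\n",
              p$m, p$n, p$c, p$k))
  cat(sprintf("  noise sd %.3g, %d outlier columns\n",
              p$noise_sd, sum(x$outlier_mask)))
  invisible(x)
}

#' Concatenate synthetic views column-wise into a multi-view dataset
#'
#' Emulates multi-view construction from expression matrices sharing the
#' gene axis: columns are concatenated and each view becomes one class (the
#' view index), so a V-view concatenation carries V classes. Ground-truth
#' factors are dropped (they are not jointly defined across independently
#' generated views).
#'
#' @param datasets list of `synthetic_dataset` objects with equal gene
#'   counts.
#' @return a `synthetic_dataset` whose `true_labels` are view indices.
#' @export
multiview_concat <- function(datasets) {
  assert_that(is.list(datasets) && length(datasets) >= 1,
              "datasets must be a non-empty list")
  assert_that(all(vapply(datasets, inherits, TRUE, "synthetic_dataset")),
              "all elements must be synthetic_dataset objects")
  ms <- vapply(datasets, function(d) nrow(d$X), 1L)
  assert_that(length(unique(ms)) == 1, "gene dimensions differ across views")
  if (length(datasets) == 1) return(datasets[[1]])
  X <- do.call(cbind, lapply(datasets, `[[`, "X"))
  colnames(X) <- paste0("view", rep(seq_along(datasets),
                                    vapply(datasets, function(d) ncol(d$X), 1L)),
                        "_", colnames(X))
  labels <- rep(seq_along(datasets),
                vapply(datasets, function(d) ncol(d$X), 1L))
  mask <- unlist(lapply(datasets, `[[`, "outlier_mask"), use.names = FALSE)
  structure(list(X = X, true_labels = labels, true_U = NULL, true_V = NULL,
                 outlier_mask = mask,
                 params = lapply(datasets, `[[`, "params")),
            class = "synthetic_dataset")
}
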