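#' Rank genes by their basis-matrix loading mass
#'
#' Genes driving the factorization carry large loadings in the basis matrix
#' U; the row-sparsity induced by the L2,1 loss concentrates that mass on
#' informative genes. The default score is the row L1 mass `sum_k |u_ik|`
#' (equal to the row sum for non-negative U); `method = "l2"` uses the row
#' Euclidean norm instead. Ties keep the input gene order (stable sort).
#'
#' @param U non-negative m x k basis matrix; row names are gene ids (indices
#'   used when absent).
#' @param method `"l1"` (default) or `"l2"` row score.
#' @return `gene_ranking` object: `gene_ids` and `scores` sorted by
#'   non-increasing score, plus the permutation `order` into the input rows.
#' @export
score_genes <- function(U, method = c("l1", "l2")) {
  method <- match.arg(method)
  U <- as.matrix(U)
  check_nonnegative(U, "U")
  scores <- if (method == "l1") rowSums(abs(U)) else sqrt(rowSums(U^2))
  ids <- rownames(U)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(U)))
  ord <- order(-scores, seq_along(scores))   # stable: ties by gene index
  structure(list(gene_ids = ids[ord], scores = unname(scores[ord]),
                 order = ord, method = method),
            class = "gene_ranking")
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat(sprintf("Gene ranking (%s score) over %d genes; top 5:\n",
              x$method, length(x$gene_ids)))
  print(utils::head(data.frame(gene_id = x$gene_ids, score = x$scores), 5))
  invisible(x)
}

#' Select the top-scoring genes
#'
#' The first `n` gene ids of a [score_genes()] ranking; `n = 100` is the
#' conventional candidate-list size for downstream database lookup.
#'
#' @param ranking a `gene_ranking`.
#' @param n how many genes (1..m).
#' @return character vector of `n` gene ids, best first.
#' @export
select_top <- function(ranking, n = 100) {
  assert_that(inherits(ranking, "gene_ranking"), "ranking must come from score_genes()")
  m <- length(ranking$gene_ids)
  assert_that(n >= 1 && n <= m, sprintf("n must be in 1..%d", m))
  ranking$gene_ids[seq_len(n)]
}

#' Intersect gene selections from several methods
#'
#' The genes picked simultaneously by every supplied selection (the "common
#' across methods" set), ordered as in the first list.
#'
#' @param lists list of >= 2 character vectors of gene ids.
#' @return character vector, possibly empty.
#' @export
intersect_selections <- function(lists) {
  assert_that(is.list(lists) && length(lists) >= 2, "need at least 2 selections")
  common <- Reduce(intersect, lists[-1], init = lists[[1]])
  lists[[1]][lists[[1]] %in% common]
}
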