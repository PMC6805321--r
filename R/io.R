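open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a delimited expression matrix
#'
#' Expects genes in rows and samples in columns: first column gene ids,
#' header row sample ids. TSV by default; the separator is inferred from a
#' `.csv` extension or can be forced. Gzipped files are decompressed
#' transparently. Negative or missing entries are rejected with the
#' offending cell named.
#'
#' @param path file path (optionally `.gz`).
#' @param sep field separator; `NULL` (default) infers `","` for `.csv`
#'   files and `"\t"` otherwise.
#' @return numeric matrix with gene row names and sample column names.
#' @export
read_expression_matrix <- function(path, sep = NULL) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  if (is.null(sep)) sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  con <- open_text(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df)
  if (!is.numeric(X)) stop_invalid(sprintf("non-numeric entries in %s", path))
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop_invalid(sprintf("missing/NaN value at gene '%s', sample '%s'",
                         rownames(X)[bad[1]], colnames(X)[bad[2]]))
  }
  if (any(X < 0)) {
    bad <- which(X < 0, arr.ind = TRUE)[1, ]
    stop_invalid(sprintf("negative value at gene '%s', sample '%s'",
                         rownames(X)[bad[1]], colnames(X)[bad[2]]))
  }
  X
}

#' Write a matrix with identifiers
#'
#' Inverse of [read_expression_matrix()]: first column holds row ids under
#' the `id` header, remaining columns carry the column ids.
#'
#' @param X matrix with dimnames (defaults generated when absent).
#' @param path output path.
#' @param sep field separator (default tab).
#' @param id_header header of the identifier column.
#' @return invisibly, `path`.
#' @export
write_matrix <- function(X, path, sep = "\t", id_header = "gene_id") {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- as.character(seq_len(ncol(X)))
  df <- data.frame(rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_header
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a one-label-per-line file
#'
#' @param path file path.
#' @return character vector of labels.
#' @export
read_labels <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  con <- open_text(path)
  on.exit(close(con))
  labs <- readLines(con)
  labs <- labs[nzchar(labs)]
  assert_that(length(labs) >= 1, sprintf("no labels in %s", path))
  labs
}

#' @rdname read_labels
#' @param labels vector of labels, one per sample.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}

#' Run the full pipeline: data, fit, cluster, evaluate, select genes
#'
#' Composes the package end to end: load an expression matrix (or generate a
#' synthetic one), factorize it, k-means-cluster the coefficient matrix,
#' score the clustering against ground truth when labels are available, and
#' rank genes from the basis matrix. All outputs plus a JSON manifest
#' sufficient to reproduce the run land in `out_dir`.
#'
#' @param fit_cfg a [fit_config()].
#' @param out_dir output directory (created if needed).
#' @param input path to an expression matrix, or `NULL` to simulate.
#' @param labels path to a ground-truth label file, or `NULL` to skip
#'   evaluation (synthetic runs use the generated truth).
#' @param sim a [synth_params()] used when `input` is `NULL`.
#' @param n_clusters clusters for k-means (default: number of true classes
#'   when known, else `fit_cfg$k`).
#' @param n_genes size of the reported top-gene list (default 100, capped at
#'   the gene count).
#' @return invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(fit_cfg, out_dir, input = NULL, labels = NULL,
                         sim = synth_params(seed = fit_cfg$seed),
                         n_clusters = NULL, n_genes = 100) {
  assert_that(inherits(fit_cfg, "fit_config"), "fit_cfg must come from fit_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  truth <- NULL
  if (is.null(input)) {
    ds <- generate_dataset(sim)
    X <- ds$X
    truth <- as.character(ds$true_labels)
    write_matrix(X, file.path(out_dir, "X.tsv"))
    write_labels(truth, file.path(out_dir, "labels.txt"))
  } else {
    X <- read_expression_matrix(input)
  }
  if (!is.null(labels)) {
    truth <- read_labels(labels)
    assert_that(length(truth) == ncol(X), "label count must match sample count")
  }

  fit <- rhnmf_fit(X, fit_cfg)
  rownames(fit$U) <- rownames(X)
  colnames(fit$U) <- paste0("factor_", seq_len(ncol(fit$U)))
  rownames(fit$V) <- paste0("factor_", seq_len(nrow(fit$V)))
  colnames(fit$V) <- colnames(X)
  write_matrix(fit$U, file.path(out_dir, "U.tsv"))
  write_matrix(fit$V, file.path(out_dir, "V.tsv"), id_header = "factor_id")
  utils::write.table(
    data.frame(iteration = seq_along(fit$objective_trajectory),
               objective = fit$objective_trajectory),
    file.path(out_dir, "objective.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  kc <- if (!is.null(n_clusters)) n_clusters
        else if (!is.null(truth)) length(unique(truth)) else fit_cfg$k
  pred <- cluster_coefficients(fit$V, kc, seed = fit_cfg$seed)
  write_labels(pred, file.path(out_dir, "labels_pred.txt"))

  eval_res <- NULL
  if (!is.null(truth)) {
    eval_res <- list(ac = accuracy(pred, truth), nmi = nmi(pred, truth))
  } else {
    message("no ground-truth labels: evaluation skipped")
  }

  ranking <- score_genes(fit$U)
  top <- select_top(ranking, min(n_genes, nrow(X)))
  writeLines(top, file.path(out_dir, sprintf("genes_top%d.txt", length(top))))
  utils::write.table(
    data.frame(gene_id = ranking$gene_ids, score = ranking$scores),
    file.path(out_dir, "gene_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("rhnmf")),
    config = unclass(fit_cfg),
    seed = fit_cfg$seed,
    input = if (is.null(input)) "synthetic" else input,
    sim_params = if (is.null(input)) unclass(sim) else NULL,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    iterations = fit$iterations_run,
    converged = fit$converged,
    final_objective = fit$objective_trajectory[fit$iterations_run],
    evaluation = eval_res,
    outputs = as.list(file.path(out_dir, c(
      "U.tsv", "V.tsv", "objective.tsv", "labels_pred.txt",
      "gene_scores.tsv", sprintf("genes_top%d.txt", length(top)))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
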