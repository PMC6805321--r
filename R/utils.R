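#' @keywords internal
"_PACKAGE"

# Invalid-argument errors carry a dedicated condition class so the CLI can
# map them to exit code 1 (user error) rather than 2 (internal error).
stop_invalid <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("rhnmf_invalid_argument", "error")))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_invalid(msg)
  invisible(TRUE)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_matrix <- function(X, name = "X") {
  assert_that(is.matrix(X) && is.numeric(X),
              sprintf("%s must be a numeric matrix", name))
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop_invalid(sprintf("%s contains NA/NaN (first at row %d, column %d)",
                         name, bad[1], bad[2]))
  }
  assert_that(all(is.finite(X)), sprintf("%s contains non-finite values", name))
  invisible(TRUE)
}

check_nonnegative <- function(X, name = "X") {
  check_matrix(X, name)
  if (any(X < 0)) {
    bad <- which(X < 0, arr.ind = TRUE)[1, ]
    stop_invalid(sprintf("%s must be non-negative (negative at row %d, column %d)",
                         name, bad[1], bad[2]))
  }
  invisible(TRUE)
}
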