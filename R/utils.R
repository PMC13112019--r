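# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so library functions do not silently consume the
#' global stream. A `NULL` seed evaluates `expr` against the current state.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Draw `k` independent sub-seeds from a master seed (kept under 2^31).
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, k)))
}

#' Nearest positive semi-definite correlation matrix
#'
#' Projects a symmetric matrix onto the set of valid correlation matrices
#' by eigenvalue clipping (Higham-style alternating projection): negative
#' eigenvalues are raised to `tol`, the matrix is rebuilt and rescaled to
#' unit diagonal, and the step repeats until the smallest eigenvalue is
#' above `-tol`.
#'
#' @param m symmetric numeric matrix with unit diagonal.
#' @param tol eigenvalue tolerance (default `1e-8`).
#' @param maxit maximum projection iterations.
#' @return A symmetric positive semi-definite correlation matrix.
#' @export
nearest_psd <- function(m, tol = 1e-8, maxit = 50L) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m <- (m + t(m)) / 2
  for (it in seq_len(maxit)) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) >= -tol) break
    vals <- pmax(e$values, tol)
    m <- e$vectors %*% (vals * t(e$vectors))
    m <- stats::cov2cor(m)
    m <- (m + t(m)) / 2
  }
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -tol) {
    stop("nearest_psd() did not converge to a positive semi-definite matrix")
  }
  m
}

# Column standard deviations without the apply() overhead.
col_sds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt(pmax(colSums(x * x) - n * mu * mu, 0) / (n - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
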