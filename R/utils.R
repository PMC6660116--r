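# Internal helpers shared across modules.

ffgf_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ffgf_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

contract_error <- function(msg, ...) ffgf_error("ffgf_contract_error", msg, ...)
input_error    <- function(msg, ...) ffgf_error("ffgf_input_error", msg, ...)
format_error   <- function(msg, ...) ffgf_error("ffgf_format_error", msg, ...)

#' @noRd
assert_labels <- function(t) {
  if (!is.numeric(t) || anyNA(t) || !all(t %in% c(-1, 1)))
    contract_error("targets must be numeric and contain only +1/-1")
  invisible(as.numeric(t))
}

# Runs `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded fits never perturb the global stream.
# seed = NULL consumes the current stream instead (used inside seeded CV).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    contract_error("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Moore-Penrose pseudoinverse via SVD; tolerance follows the usual
# max(dim) * eps * max(singular value) rule.
pinv <- function(A, tol = NULL) {
  A <- as.matrix(A)
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Least-squares solution min ||A x - b|| through the pseudoinverse.
lstsq <- function(A, b) pinv(A) %*% as.matrix(b)
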