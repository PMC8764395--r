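#' @importFrom rlang %||% abort warn inform
#' @importFrom stats var cor cov sd rnorm runif rbinom rpois setNames qnorm
#'   pnorm qchisq median phyper p.adjust model.matrix complete.cases quantile
#' @importFrom methods as is
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulation functions are pure in (inputs, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lo, hi))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

is_symmetric_mat <- function(x, tol = 1e-8) {
  is.matrix(x) && nrow(x) == ncol(x) && max(abs(x - t(x))) <= tol * (1 + max(abs(x)))
}

# inverse with a tiny ridge fallback for near-singular symmetric matrices
robust_inv <- function(M) {
  tryCatch(solve(M), error = function(e) {
    solve(M + diag(1e-8 * (mean(abs(diag(M))) + 1), nrow(M)))
  })
}
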