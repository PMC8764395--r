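# Build the fixed-effects design matrix from a phenotype tibble.
# Factors are coded with an intercept and treatment contrasts, i.e. the first
# level of every factor after the implicit intercept is dropped, which fixes
# identifiability; empty levels are dropped with a message.
build_design <- function(pheno, fixed) {
  dat <- pheno[!is.na(pheno$y), , drop = FALSE]
  for (f in fixed) {
    if (!f %in% names(dat)) abort(sprintf("Fixed factor `%s` not in phenotypes.", f))
    dat[[f]] <- droplevels(factor(dat[[f]]))
  }
  form <- if (length(fixed)) {
    stats::as.formula(paste("~", paste(fixed, collapse = " + ")))
  } else ~1
  X <- model.matrix(form, dat)
  # guard against aliased columns (e.g. a factor collinear with another)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    warn(sprintf("%d aliased fixed-effect column(s) dropped.", ncol(X) - length(keep)))
    X <- X[, keep, drop = FALSE]
  }
  list(X = X, data = dat)
}

#' Assemble the single-step mixed-model equations
#'
#' Builds Henderson's coefficient matrix and right-hand side for the animal
#' model `y = Xb + Za + e` with `a ~ N(0, K sigma_a^2)` expressed through the
#' supplied relationship inverse (`H^-1` for single-step, `A^-1` for pedigree
#' BLUP): `LHS = [X'X, X'Z; Z'X, Z'Z + Kinv * sigma_e^2/sigma_a^2]`,
#' `RHS = [X'y; Z'y]`.
#'
#' @param pheno Tibble with a numeric `y` column, an `id` column and the
#'   fixed-effect factors; rows with missing `y` are dropped.
#' @param fixed Character vector of fixed-factor column names.
#' @param kinv Relationship inverse over all animals (dimnames = ids).
#' @param sigma_a2,sigma_e2 Variance components.
#' @return List with `LHS` (dense), `rhs`, `X`, `Z`, `ids` (animal order),
#'   `records` (data used), `p` (number of fixed columns).
#' @export
build_mme <- function(pheno, fixed, kinv, sigma_a2, sigma_e2) {
  if (sigma_a2 <= 0 || sigma_e2 <= 0) abort("Variance components must be positive.")
  dz <- build_design(pheno, fixed)
  X <- dz$X
  dat <- dz$data
  ids <- rownames(kinv)
  if (is.null(ids)) abort("`kinv` needs animal ids as dimnames.")
  ai <- match(as.character(dat$id), ids)
  if (anyNA(ai)) abort("Phenotyped animals missing from the relationship matrix.")
  n <- nrow(dat); q <- length(ids)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = ai, x = 1, dims = c(n, q))
  lam <- sigma_e2 / sigma_a2
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  LHS <- rbind(
    cbind(Matrix::crossprod(Xs), Matrix::crossprod(Xs, Z)),
    cbind(Matrix::crossprod(Z, Xs),
          Matrix::crossprod(Z) + Matrix::Matrix(kinv, sparse = TRUE) * lam)
  )
  rhs <- c(as.vector(Matrix::crossprod(Xs, dat$y)),
           as.vector(Matrix::crossprod(Z, dat$y)))
  list(LHS = as.matrix(LHS), rhs = rhs, X = X, Z = Z, ids = ids,
       records = dat, p = ncol(X))
}

#' Solve the single-step mixed-model equations
#'
#' Direct dense solve of the system from [build_mme()]. When `c22_ids` is
#' given, the block of the inverse coefficient matrix belonging to those
#' animals is extracted and scaled by `sigma_e2`, so that the returned `C22`
#' is the prediction-error (co)variance of their breeding values:
#' `PEV(a_hat_22) = C22` and `Var(a_hat_22) = G sigma_a^2 - C22`.
#'
#' @inheritParams build_mme
#' @param c22_ids Optional character ids (typically the genotyped animals)
#'   whose inverse-coefficient block is required.
#' @return Object of class `mme_solution`: list with `b` (tibble of fixed
#'   solutions), `a` (tibble id/ebv for all animals), `C22` (or NULL),
#'   `sigma_a2`, `sigma_e2`, `fixed`, `ids`.
#' @export
solve_mme <- function(pheno, fixed, kinv, sigma_a2, sigma_e2, c22_ids = NULL) {
  mme <- build_mme(pheno, fixed, kinv, sigma_a2, sigma_e2)
  need_inv <- !is.null(c22_ids)
  sol <- if (need_inv) {
    Cinv <- tryCatch(solve(mme$LHS), error = function(e) {
      abort("Singular mixed-model equations (after identifiability fix).")
    })
    drop(Cinv %*% mme$rhs)
  } else {
    tryCatch(drop(solve(mme$LHS, mme$rhs)), error = function(e) {
      abort("Singular mixed-model equations (after identifiability fix).")
    })
  }
  p <- mme$p
  b <- tibble::tibble(term = colnames(mme$X), estimate = unname(sol[seq_len(p)]))
  a <- tibble::tibble(id = mme$ids, ebv = unname(sol[-seq_len(p)]))
  C22 <- NULL
  if (need_inv) {
    idx <- p + match(c22_ids, mme$ids)
    if (anyNA(idx)) abort("`c22_ids` must be pedigree animals.")
    C22 <- Cinv[idx, idx, drop = FALSE] * sigma_e2
    dimnames(C22) <- list(c22_ids, c22_ids)
  }
  structure(list(b = b, a = a, C22 = C22, sigma_a2 = sigma_a2,
                 sigma_e2 = sigma_e2, fixed = fixed, ids = mme$ids),
            class = "mme_solution")
}

#' @export
print.mme_solution <- function(x, ...) {
  cat(sprintf("<mme_solution> %d fixed-effect solutions, %d breeding values\n",
              nrow(x$b), nrow(x$a)))
  cat(sprintf("  sigma_a2 = %.4g, sigma_e2 = %.4g\n", x$sigma_a2, x$sigma_e2))
  invisible(x)
}

#' @method tidy mme_solution
#' @export
tidy.mme_solution <- function(x, effects = c("random", "fixed"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") x$b else x$a
}
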