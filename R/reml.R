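# ---- generic dense AI-REML engine -----------------------------------------
# Variance structures linear in the parameters: V(theta) = sum_k theta_k V_k.
# Used for the general bivariate path (unequal record sets); the univariate
# and shared-record bivariate models go through the much faster
# eigen-rotated paths below.
reml_ai_dense <- function(y, X, Vlist, start, max_iter = 200, tol = 1e-8,
                          valid = function(th) all(th[attr(th, "var_idx") %||%
                                                       seq_along(th)] > 0)) {
  n <- length(y)
  k <- length(Vlist)
  th <- start
  floor_v <- 1e-8 * var(y)
  trace <- matrix(NA_real_, 0, k)
  AI <- NULL
  for (iter in seq_len(max_iter)) {
    V <- Reduce(`+`, purrr::map2(th, Vlist, `*`))
    Vi_chol <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(Vi_chol)) abort("Non-positive-definite V during REML; check starts.")
    Vinv <- chol2inv(Vi_chol)
    W <- Vinv %*% X
    XtVX <- crossprod(X, W)
    XtVXi <- robust_inv(XtVX)
    P <- Vinv - W %*% XtVXi %*% t(W)
    Py <- drop(P %*% y)
    score <- numeric(k)
    u <- vector("list", k)
    for (j in seq_len(k)) {
      u[[j]] <- drop(Vlist[[j]] %*% Py)
      trPV <- sum(P * Vlist[[j]])   # tr(P Vj), both symmetric
      score[j] <- -0.5 * (trPV - sum(Py * u[[j]]))
    }
    AI <- matrix(0, k, k)
    Pu <- purrr::map(u, ~ drop(P %*% .x))
    for (a in seq_len(k)) for (b in a:k) {
      AI[a, b] <- AI[b, a] <- 0.5 * sum(u[[a]] * Pu[[b]])
    }
    step <- tryCatch(solve(AI, score), error = function(e) score / (diag(AI) + 1e-12))
    th_new <- th + step
    sh <- 1
    while (!valid(structure(th_new, var_idx = attr(start, "var_idx"))) && sh < 30) {
      sh <- sh + 1
      th_new <- th + step / 2^(sh - 1)
    }
    if (!valid(structure(th_new, var_idx = attr(start, "var_idx")))) th_new <- th
    th_new <- pmax_keep(th_new, attr(start, "var_idx"), floor_v)
    trace <- rbind(trace, th_new)
    delta <- max(abs(th_new - th)) / max(sum(abs(th)), 1e-12)
    th <- th_new
    if (delta < tol) {
      return(list(theta = th, AI = AI, converged = TRUE, iter = iter,
                  trace = trace))
    }
  }
  list(theta = th, AI = AI, converged = FALSE, iter = max_iter, trace = trace)
}

# floor only the entries that are variances (not covariances)
pmax_keep <- function(th, var_idx, floor_v) {
  idx <- var_idx %||% seq_along(th)
  th[idx] <- pmax(th[idx], floor_v)
  th
}

# ---- univariate AI-REML (eigen-rotated) ------------------------------------

#' Univariate AI-REML variance components for the animal model
#'
#' Estimates additive and residual variances for `y = Xb + a + e`,
#' `a ~ N(0, K sigma_a^2)`, `e ~ N(0, I sigma_e^2)` by restricted maximum
#' likelihood with Average-Information updates and an EM-style fallback when
#' an AI step proposes a non-positive variance. Internally the relationship
#' matrix among recorded animals is eigendecomposed once, which makes every
#' iteration linear in the number of records.
#'
#' @param pheno Tibble with `id`, numeric `y` (NA rows dropped) and the fixed
#'   factors.
#' @param fixed Character vector of fixed-factor columns.
#' @param K Relationship matrix (A, G or H) with ids as dimnames; only the
#'   block of recorded animals is used.
#' @param start Optional `c(sigma_a2, sigma_e2)` start (default: half the
#'   phenotypic variance each).
#' @param max_iter,tol Iteration cap and relative-change convergence
#'   tolerance.
#' @return Object of class `varcomp`: variance components, heritability,
#'   average-information matrix and its inverse, convergence trace, REML
#'   log-likelihood.
#' @export
ai_reml <- function(pheno, fixed, K, start = NULL, max_iter = 200L,
                    tol = 1e-8) {
  dz <- build_design(pheno, fixed)
  dat <- dz$data
  X <- dz$X
  y <- dat$y
  n <- length(y)
  if (n <= ncol(X)) abort("More fixed-effect levels than records.")
  ids <- as.character(dat$id)
  K <- as.matrix(K)
  if (!all(ids %in% rownames(K))) abort("Recorded animals missing from K.")
  Krec <- K[ids, ids]
  es <- eigen((Krec + t(Krec)) / 2, symmetric = TRUE)
  d <- pmax(es$values, 0)
  U <- es$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  th <- start %||% c(var(y) / 2, var(y) / 2)
  floor_v <- 1e-10 * var(y)
  trace <- matrix(NA_real_, 0, 2,
                  dimnames = list(NULL, c("sigma_a2", "sigma_e2")))
  AI <- NULL
  converged <- FALSE
  iter_used <- max_iter
  for (iter in seq_len(max_iter)) {
    v <- d * th[1] + th[2]
    if (any(v <= 0)) v <- pmax(v, floor_v)
    W <- Xs / v
    XtVX <- crossprod(Xs, W)
    XtVXi <- robust_inv(XtVX)
    Pfun <- function(u) u / v - W %*% (XtVXi %*% crossprod(W, u))
    Py <- drop(Pfun(ys))
    ua <- d * Py
    ue <- Py
    trPVa <- sum(d / v) - sum(XtVXi * crossprod(W, d * W))
    trPVe <- sum(1 / v) - sum(XtVXi * crossprod(W, W))
    yPVaPy <- sum(ua * Py)
    yPVePy <- sum(ue * Py)
    score <- -0.5 * c(trPVa - yPVaPy, trPVe - yPVePy)
    Pua <- drop(Pfun(ua)); Pue <- drop(Pfun(ue))
    AI <- 0.5 * matrix(c(sum(ua * Pua), sum(ua * Pue),
                         sum(ua * Pue), sum(ue * Pue)), 2, 2)
    th_new <- th + tryCatch(solve(AI, score),
                            error = function(e) score / (diag(AI) + 1e-12))
    if (any(th_new <= 0)) {
      # EM-style multiplicative fallback: fixed point of the REML score
      ra <- if (trPVa > 0) yPVaPy / trPVa else 1
      re <- if (trPVe > 0) yPVePy / trPVe else 1
      th_new <- pmax(th * c(ra, re), floor_v)
    }
    # snap a vanishing component to the boundary so the iteration can close
    bound <- th_new < 1e-6 * sum(th_new)
    th_new[bound] <- 1e-6 * sum(th_new)
    trace <- rbind(trace, th_new)
    delta <- max(abs(th_new - th)) / max(sum(th), 1e-12)
    th <- th_new
    if (delta < tol) {
      converged <- TRUE
      iter_used <- iter
      break
    }
  }
  if (!converged) {
    abort(paste0("AI-REML did not converge in ", max_iter, " iterations; ",
                 "last (sigma_a2, sigma_e2) = (",
                 paste(signif(th, 6), collapse = ", "), ")."))
  }
  v <- d * th[1] + th[2]
  W <- Xs / v
  XtVX <- crossprod(Xs, W)
  Py <- drop(ys / v - W %*% (robust_inv(XtVX) %*% crossprod(W, ys)))
  logLik <- -0.5 * (sum(log(v)) + determinant(XtVX, logarithm = TRUE)$modulus +
                    sum(ys * Py))
  dimnames(AI) <- list(c("sigma_a2", "sigma_e2"), c("sigma_a2", "sigma_e2"))
  structure(list(
    type = "univariate",
    sigma_a2 = th[1], sigma_e2 = th[2],
    h2 = th[1] / sum(th),
    ai = AI, ai_inv = robust_inv(AI),
    trace = tibble::as_tibble(trace) |>
      dplyr::mutate(iter = dplyr::row_number(), .before = 1),
    converged = converged, n_iter = iter_used,
    logLik = as.numeric(logLik), n_records = n
  ), class = "varcomp")
}

# ---- bivariate AI-REML ------------------------------------------------------

#' Bivariate AI-REML with genetic and residual covariances
#'
#' Two-trait animal model sharing one relationship matrix: additive effects
#' follow `N(0, G0 (x) K)` with `G0` the 2x2 genetic (co)variance matrix, and
#' residuals `N(0, R0 (x) I)` with residual covariance only for animals
#' recorded in both traits. When both traits are recorded on the same animals
#' the likelihood is evaluated through one eigendecomposition of K (fast);
#' otherwise a dense general path is used. Non-positive-definite updates are
#' bent to the nearest positive-definite matrix.
#'
#' @param pheno Tibble with `id`, the two trait columns (NA = not recorded)
#'   and the fixed factors.
#' @param traits Character vector of the two trait column names.
#' @param fixed Character vector of fixed-factor columns (shared).
#' @param K Relationship matrix with ids as dimnames.
#' @param start Optional length-6 start
#'   `c(ga11, ga12, ga22, re11, re12, re22)`.
#' @param max_iter,tol Iteration controls.
#' @return Object of class `varcomp` (type `"bivariate"`) with `G_cov`,
#'   `R_cov`, genetic/residual/phenotypic correlations, per-trait
#'   heritabilities, the 6x6 AI matrix and its inverse, and the trace.
#' @export
ai_reml_bivariate <- function(pheno, traits, fixed, K, start = NULL,
                              max_iter = 200L, tol = 1e-8) {
  stopifnot(length(traits) == 2L)
  y1_all <- pheno[[traits[1]]]
  y2_all <- pheno[[traits[2]]]
  obs1 <- !is.na(y1_all); obs2 <- !is.na(y2_all)
  same_set <- identical(which(obs1), which(obs2))
  K <- as.matrix(K)
  if (same_set) {
    fit <- biv_reml_rotated(pheno, traits, fixed, K, start, max_iter, tol)
  } else {
    fit <- biv_reml_dense(pheno, traits, fixed, K, start, max_iter, tol)
  }
  th <- fit$theta
  G0 <- matrix(th[c(1, 2, 2, 3)], 2, 2, dimnames = list(traits, traits))
  R0 <- matrix(th[c(4, 5, 5, 6)], 2, 2, dimnames = list(traits, traits))
  P0 <- G0 + R0
  nm <- c("ga11", "ga12", "ga22", "re11", "re12", "re22")
  AI <- fit$AI
  dimnames(AI) <- list(nm, nm)
  structure(list(
    type = "bivariate", traits = traits,
    G_cov = G0, R_cov = R0, P_cov = P0,
    sigma_a2 = diag(G0), sigma_e2 = diag(R0),
    h2 = diag(G0) / diag(P0),
    r_genetic = G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2]),
    r_residual = R0[1, 2] / sqrt(R0[1, 1] * R0[2, 2]),
    r_phenotypic = P0[1, 2] / sqrt(P0[1, 1] * P0[2, 2]),
    ai = AI, ai_inv = robust_inv(AI),
    trace = tibble::as_tibble(fit$trace, .name_repair = ~nm) |>
      dplyr::mutate(iter = dplyr::row_number(), .before = 1),
    converged = fit$converged, n_iter = fit$iter
  ), class = "varcomp")
}

# positive-definiteness of both 2x2 blocks
biv_valid <- function(th) {
  th[1] > 0 && th[3] > 0 && th[4] > 0 && th[6] > 0 &&
    th[1] * th[3] - th[2]^2 > 0 && th[4] * th[6] - th[5]^2 > 0
}

biv_start <- function(y1, y2, start) {
  if (!is.null(start)) return(start)
  shared <- stats::complete.cases(y1, y2)
  cv <- if (any(shared)) cov(y1[shared], y2[shared]) else 0
  c(var(y1, na.rm = TRUE) / 2, cv / 2, var(y2, na.rm = TRUE) / 2,
    var(y1, na.rm = TRUE) / 2, cv / 2, var(y2, na.rm = TRUE) / 2)
}

# Shared-record fast path: observations ordered trait-major; after rotating
# by the eigenvectors of K[rec, rec], V is block-diagonal over eigen-indices
# with 2x2 blocks G0 * d_i + R0.
biv_reml_rotated <- function(pheno, traits, fixed, K, start, max_iter, tol) {
  rec <- which(!is.na(pheno[[traits[1]]]))
  dat <- pheno[rec, , drop = FALSE]
  dat$y <- dat[[traits[1]]]
  dz <- build_design(dat, fixed)
  X <- dz$X
  ids <- as.character(dz$data$id)
  y1 <- dz$data[[traits[1]]]
  y2 <- dz$data[[traits[2]]]
  n <- length(y1)
  es <- eigen((K[ids, ids] + t(K[ids, ids])) / 2, symmetric = TRUE)
  d <- pmax(es$values, 0)
  U <- es$vectors
  y1s <- drop(crossprod(U, y1)); y2s <- drop(crossprod(U, y2))
  Xs <- crossprod(U, X)
  p <- ncol(Xs)
  Xfull <- rbind(cbind(Xs, matrix(0, n, p)), cbind(matrix(0, n, p), Xs))
  ys <- c(y1s, y2s)
  th <- biv_start(y1, y2, start)
  floor_v <- 1e-10 * (var(y1) + var(y2))
  wt <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))  # which block each ga hits
  trace <- matrix(NA_real_, 0, 6)
  AI <- NULL
  converged <- FALSE
  iter_used <- max_iter
  for (iter in seq_len(max_iter)) {
    tries <- 0
    repeat {
      v11 <- d * th[1] + th[4]; v12 <- d * th[2] + th[5]; v22 <- d * th[3] + th[6]
      dt <- v11 * v22 - v12^2
      if (all(dt > 0) && all(v11 > 0)) break
      tries <- tries + 1
      if (tries > 20) abort("Non-positive-definite V in bivariate REML; adjust starts.")
      # shrink the correlations slightly towards zero until V is PD
      th <- bend_biv(th * c(1, 0.95, 1, 1, 0.95, 1), floor_v * 10^tries)
    }
    i11 <- v22 / dt; i12 <- -v12 / dt; i22 <- v11 / dt
    vinv_mat <- function(M) {
      a <- M[1:n, , drop = FALSE]; b <- M[(n + 1):(2 * n), , drop = FALSE]
      rbind(i11 * a + i12 * b, i12 * a + i22 * b)
    }
    # derivative matrices: weights (w11, w12, w22) times d (genetic) or 1
    vi_mult <- function(u, w, scale) {
      a <- u[1:n]; b <- u[(n + 1):(2 * n)]
      c(scale * (w[1] * a + w[2] * b), scale * (w[2] * a + w[3] * b))
    }
    W <- vinv_mat(Xfull)
    XtVX <- crossprod(Xfull, W)
    XtVXi <- robust_inv(XtVX)
    Pfun <- function(u) drop(vinv_mat(cbind(u)) - W %*% (XtVXi %*% crossprod(W, u)))
    Py <- Pfun(ys)
    scales <- list(d, d, d, 1, 1, 1)
    ws <- c(wt, wt)
    u <- purrr::map2(ws, scales, ~ vi_mult(Py, .x, .y))
    trv <- c(sum(i11 * d), 2 * sum(i12 * d), sum(i22 * d),
             sum(i11), 2 * sum(i12), sum(i22))
    score <- numeric(6)
    for (j in 1:6) {
      ViW <- apply(W, 2L, vi_mult, w = ws[[j]], scale = scales[[j]])
      trPV <- trv[j] - sum(XtVXi * crossprod(W, ViW))
      score[j] <- -0.5 * (trPV - sum(Py * u[[j]]))
    }
    Pu <- purrr::map(u, Pfun)
    AI <- matrix(0, 6, 6)
    for (a in 1:6) for (b in a:6) {
      AI[a, b] <- AI[b, a] <- 0.5 * sum(u[[a]] * Pu[[b]])
    }
    step <- tryCatch(solve(AI, score), error = function(e) score / (diag(AI) + 1e-12))
    th_new <- th + step
    sh <- 0
    while (!biv_valid(th_new) && sh < 30) {
      sh <- sh + 1
      th_new <- th + step / 2^sh
    }
    if (!biv_valid(th_new)) th_new <- bend_biv(th_new, floor_v)
    trace <- rbind(trace, th_new)
    delta <- max(abs(th_new - th)) / max(sum(abs(th)), 1e-12)
    th <- th_new
    if (delta < tol) {
      converged <- TRUE
      iter_used <- iter
      break
    }
  }
  if (!converged) {
    abort(paste0("Bivariate AI-REML did not converge in ", max_iter,
                 " iterations."))
  }
  list(theta = th, AI = AI, converged = converged, iter = iter_used,
       trace = trace)
}

# bend a non-PD 2x2 pair to the nearest PD matrices (eigenvalue clipping)
bend_biv <- function(th, eps) {
  fix <- function(m) {
    es <- eigen(m, symmetric = TRUE)
    lam <- pmax(es$values, eps)
    es$vectors %*% diag(lam) %*% t(es$vectors)
  }
  G0 <- fix(matrix(th[c(1, 2, 2, 3)], 2, 2))
  R0 <- fix(matrix(th[c(4, 5, 5, 6)], 2, 2))
  inform("Non-positive-definite REML update bent to nearest PD matrices.")
  c(G0[1, 1], G0[1, 2], G0[2, 2], R0[1, 1], R0[1, 2], R0[2, 2])
}

# General path for unequal record sets: builds the dense V components once
# and hands them to the generic AI engine.
biv_reml_dense <- function(pheno, traits, fixed, K, start, max_iter, tol) {
  mk <- function(tr) {
    dat <- pheno[!is.na(pheno[[tr]]), , drop = FALSE]
    dat$y <- dat[[tr]]
    dz <- build_design(dat, fixed)
    list(y = dz$data$y, X = dz$X, ids = as.character(dz$data$id))
  }
  t1 <- mk(traits[1]); t2 <- mk(traits[2])
  n1 <- length(t1$y); n2 <- length(t2$y)
  K11 <- K[t1$ids, t1$ids]; K22 <- K[t2$ids, t2$ids]; K12 <- K[t1$ids, t2$ids]
  S <- outer(t1$ids, t2$ids, "==") * 1
  zero <- function(a, b) matrix(0, a, b)
  Vlist <- list(
    rbind(cbind(K11, zero(n1, n2)), cbind(zero(n2, n1), zero(n2, n2))),
    rbind(cbind(zero(n1, n1), K12), cbind(t(K12), zero(n2, n2))),
    rbind(cbind(zero(n1, n1), zero(n1, n2)), cbind(zero(n2, n1), K22)),
    rbind(cbind(diag(n1), zero(n1, n2)), cbind(zero(n2, n1), zero(n2, n2))),
    rbind(cbind(zero(n1, n1), S), cbind(t(S), zero(n2, n2))),
    rbind(cbind(zero(n1, n1), zero(n1, n2)), cbind(zero(n2, n1), diag(n2)))
  )
  X <- rbind(cbind(t1$X, zero(n1, ncol(t2$X))),
             cbind(zero(n2, ncol(t1$X)), t2$X))
  y <- c(t1$y, t2$y)
  st <- structure(biv_start(pheno[[traits[1]]], pheno[[traits[2]]], start),
                  var_idx = c(1L, 3L, 4L, 6L))
  fit <- reml_ai_dense(y, X, Vlist, st, max_iter, tol,
                       valid = function(th) biv_valid(th))
  if (!fit$converged) {
    abort("Bivariate AI-REML (general path) did not converge.")
  }
  fit
}

# ---- derived quantities -----------------------------------------------------

#' Heritability from variance components
#'
#' `h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)`, per trait.
#'
#' @param vc A `varcomp` object, or a numeric `sigma_a2` with `sigma_e2`.
#' @param sigma_e2 Residual variance when `vc` is numeric.
#' @return Numeric heritability (per trait for bivariate fits).
#' @export
heritability <- function(vc, sigma_e2 = NULL) {
  if (inherits(vc, "varcomp")) {
    tot <- vc$sigma_a2 + vc$sigma_e2
    if (any(tot <= 0)) abort("Zero total variance; heritability undefined.")
    return(vc$sigma_a2 / tot)
  }
  tot <- vc + sigma_e2
  if (any(tot <= 0)) abort("Zero total variance; heritability undefined.")
  vc / tot
}

#' Monte-Carlo standard errors and HPD intervals for derived parameters
#'
#' Samples parameter vectors from a multivariate normal centred at the REML
#' estimates with covariance equal to the inverse average-information matrix,
#' recomputes heritabilities and correlations for each draw, and reports
#' their standard deviation and shortest 95% highest-density interval.
#' Draws with non-positive variances (or non-positive-definite covariance
#' blocks, bivariate case) are rejected and counted. A correlation is flagged
#' significant when its HPD interval excludes zero.
#'
#' @param vc A `varcomp` object from [ai_reml()] or [ai_reml_bivariate()].
#' @param n_samples Number of Monte-Carlo draws.
#' @param seed Integer seed.
#' @param prob Interval coverage (default 0.95).
#' @return Tibble: `parameter`, `estimate`, `sd`, `hpd_lo`, `hpd_hi`,
#'   `significant` (correlations only), plus attribute `"n_rejected"`.
#' @export
mc_standard_errors <- function(vc, n_samples = 10000L, seed = 1L,
                               prob = 0.95) {
  stopifnot(inherits(vc, "varcomp"))
  Sig <- (vc$ai_inv + t(vc$ai_inv)) / 2
  mu <- if (vc$type == "univariate") {
    c(vc$sigma_a2, vc$sigma_e2)
  } else {
    c(vc$G_cov[1, 1], vc$G_cov[1, 2], vc$G_cov[2, 2],
      vc$R_cov[1, 1], vc$R_cov[1, 2], vc$R_cov[2, 2])
  }
  with_seed(seed, {
    es <- eigen(Sig, symmetric = TRUE)
    L <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), nrow(Sig))
    Zm <- matrix(rnorm(n_samples * length(mu)), length(mu), n_samples)
    draws <- t(mu + L %*% Zm)
    ok <- if (vc$type == "univariate") {
      draws[, 1] > 0 & draws[, 2] > 0
    } else {
      draws[, 1] > 0 & draws[, 3] > 0 & draws[, 4] > 0 & draws[, 6] > 0 &
        (draws[, 1] * draws[, 3] - draws[, 2]^2) > 0 &
        (draws[, 4] * draws[, 6] - draws[, 5]^2) > 0
    }
    n_rej <- sum(!ok)
    if (n_rej > n_samples / 2) {
      abort("More than half the Monte-Carlo draws invalid; estimates too close to a boundary.")
    }
    dr <- draws[ok, , drop = FALSE]
    derived <- if (vc$type == "univariate") {
      tibble::tibble(parameter = "h2",
                     estimate = vc$h2,
                     values = list(dr[, 1] / (dr[, 1] + dr[, 2])))
    } else {
      tibble::tibble(
        parameter = c("h2_1", "h2_2", "r_genetic", "r_phenotypic"),
        estimate = c(vc$h2, vc$r_genetic, vc$r_phenotypic),
        values = list(
          dr[, 1] / (dr[, 1] + dr[, 4]),
          dr[, 3] / (dr[, 3] + dr[, 6]),
          dr[, 2] / sqrt(dr[, 1] * dr[, 3]),
          (dr[, 2] + dr[, 5]) /
            sqrt((dr[, 1] + dr[, 4]) * (dr[, 3] + dr[, 6]))
        )
      )
    }
    out <- dplyr::mutate(
      derived,
      sd = purrr::map_dbl(.data$values, sd),
      hpd = purrr::map(.data$values, hpd_interval, prob = prob),
      hpd_lo = purrr::map_dbl(.data$hpd, 1),
      hpd_hi = purrr::map_dbl(.data$hpd, 2),
      significant = ifelse(grepl("^r_", .data$parameter),
                           .data$hpd_lo > 0 | .data$hpd_hi < 0, NA)
    ) |>
      dplyr::select("parameter", "estimate", "sd", "hpd_lo", "hpd_hi",
                    "significant")
    attr(out, "n_rejected") <- n_rej
    out
  })
}

# shortest interval containing `prob` of the draws
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) return(c(NA_real_, NA_real_))
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1L], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

# ---- methods ----------------------------------------------------------------

#' @export
print.varcomp <- function(x, ...) {
  if (x$type == "univariate") {
    cat(sprintf("<varcomp> univariate AI-REML (%d iters%s)\n", x$n_iter,
                if (x$converged) "" else ", NOT converged"))
    cat(sprintf("  sigma_a2 = %.5g  sigma_e2 = %.5g  h2 = %.4f\n",
                x$sigma_a2, x$sigma_e2, x$h2))
  } else {
    cat(sprintf("<varcomp> bivariate AI-REML (%d iters%s)\n", x$n_iter,
                if (x$converged) "" else ", NOT converged"))
    cat(sprintf("  h2 = (%.3f, %.3f)  r_g = %.3f  r_p = %.3f\n",
                x$h2[1], x$h2[2], x$r_genetic, x$r_phenotypic))
  }
  invisible(x)
}

#' Tidy variance-component estimates
#'
#' @param x A `varcomp` object.
#' @param ... Unused.
#' @return A tibble with one row per (co)variance parameter.
#' @method tidy varcomp
#' @export
tidy.varcomp <- function(x, ...) {
  if (x$type == "univariate") {
    tibble::tibble(term = c("sigma_a2", "sigma_e2"),
                   estimate = c(x$sigma_a2, x$sigma_e2),
                   std_error = sqrt(pmax(diag(x$ai_inv), 0)))
  } else {
    tibble::tibble(term = rownames(x$ai),
                   estimate = c(x$G_cov[1, 1], x$G_cov[1, 2], x$G_cov[2, 2],
                                x$R_cov[1, 1], x$R_cov[1, 2], x$R_cov[2, 2]),
                   std_error = sqrt(pmax(diag(x$ai_inv), 0)))
  }
}

#' One-row model summary for a variance-component fit
#'
#' @param x A `varcomp` object.
#' @param ... Unused.
#' @return A one-row tibble with heritabilities, correlations (bivariate),
#'   convergence status and iteration count.
#' @method glance varcomp
#' @export
glance.varcomp <- function(x, ...) {
  if (x$type == "univariate") {
    tibble::tibble(h2 = x$h2, sigma_a2 = x$sigma_a2, sigma_e2 = x$sigma_e2,
                   logLik = x$logLik, converged = x$converged,
                   n_iter = x$n_iter, n_records = x$n_records)
  } else {
    tibble::tibble(h2_1 = x$h2[1], h2_2 = x$h2[2], r_genetic = x$r_genetic,
                   r_phenotypic = x$r_phenotypic, converged = x$converged,
                   n_iter = x$n_iter)
  }
}
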