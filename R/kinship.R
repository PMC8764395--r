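#' Pedigree numerator relationship matrix (A)
#'
#' Tabular (recursive) method: the relationship of animal i with an older
#' animal j is the average of j's relationships with i's parents, and the
#' diagonal is 1 plus half the relationship between the parents (1 + F_i).
#'
#' @param ped Pedigree tibble (`id`, `sire`, `dam`; 0 = unknown),
#'   topologically ordered (parents before offspring).
#' @return Dense symmetric matrix with animal ids as dimnames; the diagonal
#'   minus 1 gives inbreeding coefficients.
#' @export
build_a <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  if (any(si >= seq_len(n), na.rm = TRUE) || any(di >= seq_len(n), na.rm = TRUE)) {
    abort("Pedigree must be ordered with parents before offspring.")
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      rel <- numeric(i - 1L)
      if (!is.na(s)) rel <- rel + 0.5 * A[s, prev]
      if (!is.na(d)) rel <- rel + 0.5 * A[d, prev]
      A[i, prev] <- rel
      A[prev, i] <- rel
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(as.character(ped$id), as.character(ped$id))
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' 1/d_i to its own diagonal, -1/(2 d_i) to animal-parent cells and
#' 1/(4 d_i) between parents, where d_i is the Mendelian sampling variance
#' computed from parental inbreeding coefficients (taken from [build_a()]).
#'
#' @param ped Ordered pedigree tibble.
#' @return Sparse symmetric `dgCMatrix` with animal ids as dimnames.
#' @export
build_a_inverse <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  Fcoef <- diag(build_a(ped)) - 1
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii[[length(ii) + 1L]] <<- i; jj[[length(jj) + 1L]] <<- j
    xx[[length(xx) + 1L]] <<- v
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dval <- if (!is.na(s) && !is.na(d)) {
      0.5 - 0.25 * (Fcoef[s] + Fcoef[d])
    } else if (!is.na(s)) {
      0.75 - 0.25 * Fcoef[s]
    } else if (!is.na(d)) {
      0.75 - 0.25 * Fcoef[d]
    } else 1
    al <- 1 / dval
    add(i, i, al)
    for (p in c(s, d)) {
      if (!is.na(p)) {
        add(i, p, -al / 2); add(p, i, -al / 2)
        for (p2 in c(s, d)) if (!is.na(p2)) add(p, p2, al / 4)
      }
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(as.character(ped$id),
                                               as.character(ped$id)))
  methods::as(Matrix::forceSymmetric(Ainv), "generalMatrix")
}

#' Raw genomic relationship matrix (VanRaden method 1)
#'
#' `G0 = M M' / (2 * sum(p_i (1 - p_i)))` where `M` is the genotype matrix
#' centred by twice the allele frequencies. By default the frequencies of the
#' current genotyped set are used for centring; monomorphic SNPs (p of 0 or 1)
#' are excluded from the scaling denominator with a warning.
#'
#' @param geno A complete [geno_data] for the genotyped animals.
#' @param p_freqs Optional named vector of alternate-allele frequencies; the
#'   default uses the observed frequencies of `geno`.
#' @return An object of class `g_matrix`: list with `G` (matrix), `M`
#'   (centred genotypes), `p` (frequencies used), `denom`
#'   (2 * sum p(1-p) over polymorphic SNPs) and `ids`.
#' @export
build_g <- function(geno, p_freqs = NULL) {
  g <- geno_matrix(geno)
  if (anyNA(g)) abort("Genotypes must be complete (impute before build_g).")
  p <- p_freqs %||% allele_freq(g)
  p <- p[colnames(g)]
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warn(sprintf("%d monomorphic SNP(s) excluded from the G scaling.", sum(mono)))
  }
  denom <- 2 * sum(p[!mono] * (1 - p[!mono]))
  if (denom <= 0) abort("All SNPs monomorphic; G undefined.")
  M <- sweep(g, 2L, 2 * p, "-")
  G <- tcrossprod(M) / denom
  structure(list(G = G, M = M, p = p, denom = denom, ids = rownames(g)),
            class = "g_matrix")
}

#' Blend a genomic relationship matrix with the identity
#'
#' `G = lam * G0 + beta * I`, the standard guard against singularity.
#'
#' @param G0 Symmetric matrix (or a `g_matrix`).
#' @param lam,beta Blending weights (defaults 0.99 and 0.01).
#' @return Matrix of the same dimension.
#' @export
blend_g <- function(G0, lam = 0.99, beta = 0.01) {
  if (inherits(G0, "g_matrix")) G0 <- G0$G
  if (!is_symmetric_mat(G0, tol = 1e-6)) abort("`G0` must be symmetric.")
  if (lam + beta <= 0 || lam + beta > 1.5) {
    warn("Non-standard blending: lam + beta outside (0, 1.5].")
  }
  lam * G0 + beta * diag(nrow(G0))
}

#' Tune G to the pedigree relationships of the genotyped animals
#'
#' Returns both (a) the mean-matching adjustment `G_adj = alpha + gamma * G`
#' with `alpha`, `gamma` chosen so that the mean diagonal and mean
#' off-diagonal of `G_adj` equal those of `A22` (the different genetic bases
#' of the pedigree and genomic matrices), and (b) the scalar
#' `delta = 1 - (0.5/n^2) * (sum(A22) - sum(G))`, retained for the SNP-effect
#' back-solve scaling. For a single animal the off-diagonal constraint is
#' dropped and only the diagonal is matched.
#'
#' @param G Blended genomic matrix (same animal ordering as `A22`).
#' @param A22 Pedigree relationship matrix restricted to genotyped animals.
#' @return List with `G_adj`, `alpha`, `gamma`, `delta`.
#' @export
tune_g_to_a22 <- function(G, A22) {
  if (!all(dim(G) == dim(A22))) abort("`G` and `A22` must have equal dimension.")
  n <- nrow(G)
  delta <- 1 - (0.5 / n^2) * (sum(A22) - sum(G))
  if (n == 1L) {
    alpha <- mean(diag(A22)) - mean(diag(G))
    gamma <- 1
  } else {
    md_g <- mean(diag(G)); mo_g <- (sum(G) - sum(diag(G))) / (n^2 - n)
    md_a <- mean(diag(A22)); mo_a <- (sum(A22) - sum(diag(A22))) / (n^2 - n)
    if (abs(md_g - mo_g) < 1e-12) {
      abort("Degenerate G (constant matrix): mean-matching system singular.")
    }
    gamma <- (md_a - mo_a) / (md_g - mo_g)
    alpha <- md_a - gamma * md_g
  }
  list(G_adj = alpha + gamma * G, alpha = alpha, gamma = gamma, delta = delta)
}

#' Inverse of the combined pedigree--genomic relationship matrix
#'
#' `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]` over the genotyped block; outside
#' that block H^-1 equals A^-1.
#'
#' @param Ainv Sparse or dense inverse of A for all pedigree animals
#'   (dimnames = animal ids).
#' @param A22 Pedigree relationship matrix of the genotyped animals.
#' @param G_adj Blended/tuned genomic matrix (same ordering as `A22`).
#' @param geno_ids Character ids of the genotyped animals (defaults to
#'   `rownames(G_adj)`, else `rownames(A22)`).
#' @return Sparse symmetric `H^-1` over all pedigree animals, with the
#'   genotyped ids in attribute `"geno_ids"`.
#' @export
build_h_inverse <- function(Ainv, A22, G_adj, geno_ids = NULL) {
  geno_ids <- geno_ids %||% rownames(G_adj) %||% rownames(A22)
  H <- methods::as(Matrix::Matrix(Ainv, sparse = TRUE), "generalMatrix")
  if (length(geno_ids)) {
    if (!all(geno_ids %in% rownames(H))) {
      abort("Genotyped ids must be a subset of the pedigree ids.")
    }
    Ginv <- tryCatch(solve(G_adj), error = function(e) {
      abort("`G_adj` is singular; blend with the identity (blend_g) first.")
    })
    A22inv <- solve(A22)
    idx <- match(geno_ids, rownames(H))
    H[idx, idx] <- H[idx, idx] + (Ginv - A22inv)
  }
  H <- (H + Matrix::t(H)) / 2
  attr(H, "geno_ids") <- geno_ids
  H
}
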