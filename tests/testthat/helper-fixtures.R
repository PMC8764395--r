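# Shared small fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# a small herd: 240 animals, 3 chromosomes x 60 SNPs, polygenic-ish trait
small_herd <- function() {
  if (is.null(fixture_env$herd)) {
    cfg <- sim_config(n_founders = 60, n_generations = 3, n_chromosomes = 3,
                      snps_per_chromosome = 60, n_qtl = 60, h2_true = 0.3,
                      seed = 101)
    fixture_env$herd <- c(simulate_herd(cfg), list(cfg = cfg))
  }
  fixture_env$herd
}

# a larger herd (~1000 animals) for statistical property checks
medium_herd <- function() {
  if (is.null(fixture_env$herd_m)) {
    cfg <- sim_config(n_founders = 250, n_generations = 3, n_chromosomes = 5,
                      snps_per_chromosome = 80, n_qtl = 400, h2_true = 0.3,
                      seed = 202)
    fixture_env$herd_m <- c(simulate_herd(cfg), list(cfg = cfg))
  }
  fixture_env$herd_m
}

fixed_factors <- c("contemporary_group", "parity_class", "birth_month")

# hand-made geno_data from a plain matrix (one chromosome, 1 Mb spacing)
toy_geno <- function(g, chrom = NULL, pos = NULL) {
  if (is.null(rownames(g))) rownames(g) <- as.character(seq_len(nrow(g)))
  if (is.null(colnames(g))) colnames(g) <- paste0("s", seq_len(ncol(g)))
  map <- tibble::tibble(
    snp = colnames(g),
    chrom = chrom %||% rep(1L, ncol(g)),
    pos_bp = pos %||% seq_len(ncol(g)) * 1e6
  )
  geno_data(g, map)
}

`%||%` <- rlang::`%||%`

# path-counting coefficient-of-relationship oracle (exhaustive recursion),
# independent of the tabular method in build_a()
kinship_oracle <- function(ped) {
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  n <- nrow(ped)
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i == j) {
      return(0.5 * (1 + f(si[i], di[i])))
    }
    if (i < j) {
      return(0.5 * (f(i, si[j]) + f(i, di[j])))
    }
    0.5 * (f(j, si[i]) + f(j, di[i]))
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) A[i, j] <- 2 * f(i, j)
  dimnames(A) <- list(as.character(ped$id), as.character(ped$id))
  A
}

# generalized-least-squares mixed-model oracle via direct covariance
# inversion: V = Z K Z' sa + I se
gls_oracle <- function(y, X, K_rec, K_cross, sa, se) {
  V <- K_rec * sa + diag(se, length(y))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  a <- sa * K_cross %*% Vi %*% (y - X %*% b)
  list(b = drop(b), a = drop(a))
}
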