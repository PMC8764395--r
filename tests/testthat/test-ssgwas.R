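test_that("back-solved SNP effects equal the SNP-BLUP solution", {
  set.seed(42)
  n <- 30; m <- 80
  g <- matrix(rbinom(n * m, 2, 0.4), n, m,
              dimnames = list(as.character(1:n), paste0("s", 1:m)))
  gd <- toy_geno(g)
  pfix <- stats::setNames(rep(0.45, m), colnames(g))
  gm <- build_g(gd, p_freqs = pfix)
  y <- rnorm(n, 10, 2)
  sa <- 1; se <- 2
  Ginv <- solve(gm$G)
  dimnames(Ginv) <- list(rownames(g), rownames(g))
  ph <- tibble::tibble(id = as.integer(rownames(g)), y = y)
  sol <- solve_mme(ph, character(0), Ginv, sa, se, c22_ids = rownames(g))
  a22 <- sol$a$ebv
  ghat <- backsolve_snp_effects(gm$M, gm$denom, gm$G, a22, lam = 1, delta = 1)
  # oracle: joint (mean, SNP effects) ridge MME
  M <- gm$M; kk <- se / (sa / gm$denom)
  X <- matrix(1, n, 1)
  LHS <- rbind(cbind(crossprod(X), crossprod(X, M)),
               cbind(crossprod(M, X), crossprod(M) + diag(kk, m)))
  snp_blup <- solve(LHS, c(crossprod(X, y), crossprod(M, y)))[-1]
  expect_lt(max(abs(ghat - snp_blup)), 1e-6)
  # M g correlates with the breeding values it was solved from
  expect_gt(cor(drop(M %*% ghat), a22), 0.99)
  # linearity in lambda, zero input -> zero output
  expect_equal(backsolve_snp_effects(gm$M, gm$denom, gm$G, a22, lam = 2),
               2 * backsolve_snp_effects(gm$M, gm$denom, gm$G, a22, lam = 1))
  expect_equal(unname(backsolve_snp_effects(gm$M, gm$denom, gm$G,
                                            rep(0, n))), rep(0, m))
})

test_that("SNP-effect PEV matches a Monte-Carlo sampling oracle", {
  set.seed(7)
  n <- 25; m <- 60
  g <- matrix(rbinom(n * m, 2, 0.35), n, m,
              dimnames = list(as.character(1:n), paste0("s", 1:m)))
  gm <- build_g(toy_geno(g), p_freqs = stats::setNames(rep(0.4, m), colnames(g)))
  G <- blend_g(gm$G, 0.95, 0.05)
  sa <- 0.8
  # a synthetic, PSD C22 strictly inside [0, G sa]
  C22 <- 0.4 * sa * G + diag(0.01, n)
  sdg <- snp_effect_pev(gm$M, gm$denom, G, C22, sa, lam = 1, delta = 1)
  W <- G * sa - C22
  L <- t(chol(W))
  draws <- L %*% matrix(rnorm(n * 20000), n, 20000)
  ghat_draws <- (1 / gm$denom) * crossprod(gm$M, solve(G, draws))
  mc_var <- apply(ghat_draws, 1L, var)
  expect_lt(max(abs(mc_var / sdg^2 - 1)), 0.05)
  # no information: C22 = G sa -> all zero
  expect_equal(unname(snp_effect_pev(gm$M, gm$denom, G, G * sa, sa)),
               rep(0, m), tolerance = 1e-10)
  # perfect knowledge: C22 = 0 -> hand formula M' G^-1 M sa scaled
  sd0 <- snp_effect_pev(gm$M, gm$denom, G, matrix(0, n, n), sa,
                        lam = 1, delta = 1)
  hand <- sqrt(diag(t(gm$M) %*% solve(G) %*% gm$M) * sa) / gm$denom
  expect_equal(unname(sd0), unname(hand), tolerance = 1e-10)
  # scale mismatch triggers an error
  expect_error(snp_effect_pev(gm$M, gm$denom, G, G * sa * 2, sa),
               "scale")
})

test_that("p-values follow the two-sided normal formula", {
  p <- snp_pvalues(c(1.96, 0, 3), c(1, 1, 1))
  expect_equal(p[1], 0.05, tolerance = 0.0005)
  expect_equal(p[2], 1)
  expect_equal(p[3], 0.0027, tolerance = 1e-4)
  expect_message(pz <- snp_pvalues(c(1, 2), c(1, 0)), "zero PEV")
  expect_true(is.na(pz[2]))
  # |g|/sd and -log10(p) are co-monotone
  set.seed(1)
  gh <- rnorm(50); sdg <- runif(50, 0.5, 2)
  pv <- snp_pvalues(gh, sdg)
  expect_equal(order(abs(gh / sdg)), order(-log10(pv)))
})

test_that("variance explained is the genic share of additive variance", {
  expect_equal(variance_explained(0, 0.3, 1), 0)
  expect_equal(variance_explained(1, 0.5, 1), 50)
  expect_error(variance_explained(1, 0.5, 0), "positive")
  # sums to ~100% for a fully genic trait on ~independent SNPs
  cfg <- sim_config(n_founders = 300, n_generations = 0, n_chromosomes = 4,
                    snps_per_chromosome = 50, n_qtl = 200, h2_true = 1,
                    ld_decay_bp = 1, sex_limited = FALSE, seed = 19)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(ped, geno, cfg)
  q <- ph$truth$qtl
  p <- allele_freq <- colMeans(geno_matrix(geno))[q$snp] / 2
  tot <- sum(variance_explained(q$effect, p, var(ph$truth$breeding_values$tbv)))
  expect_equal(tot, 100, tolerance = 12)
})

test_that("effective tests decompose correlation eigenvalues", {
  # identity correlation -> m_eff = n
  expect_equal(as.numeric(effective_tests(diag(8))), 8)
  # perfectly correlated block -> 1
  expect_equal(as.numeric(effective_tests(matrix(1, 5, 5))), 1)
  # random matrix vs the direct eigenvalue-formula oracle
  set.seed(2)
  Z <- matrix(rnorm(200 * 50), 200, 50)
  cm <- cor(Z)
  lam <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  oracle <- sum(ifelse(lam >= 1, 1, 0) + (lam - floor(lam)))
  expect_equal(as.numeric(effective_tests(cm)), oracle, tolerance = 1e-8)
  # geno_data interface sums per-chromosome blocks, bounded by n_snps
  herd <- small_herd()
  meff <- effective_tests(herd$geno)
  m <- ncol(geno_matrix(herd$geno))
  expect_true(meff >= 1 && meff <= m)
  blocks <- attr(meff, "blocks")
  expect_equal(sum(blocks$m_eff), as.numeric(meff))
  # block splitting changes the estimate only modestly
  meff_b <- effective_tests(herd$geno, block_size = 20)
  expect_equal(as.numeric(meff_b), as.numeric(meff), tolerance = 0.2 * m)
})

test_that("thresholds reproduce the effective-test arithmetic", {
  th <- gwas_thresholds(17766, 0.05)
  expect_equal(round(th$significant_logp, 2), 5.55)
  expect_equal(signif(th$suggestive_p, 4), 5.629e-5)
  th1 <- gwas_thresholds(1, 0.05)
  expect_equal(th1$significant_logp, -log10(0.05), tolerance = 1e-10)
  expect_equal(round(th1$significant_logp, 3), 1.301)
  expect_error(gwas_thresholds(0.5), "m_eff")
})

test_that("inflation factor calibrates on null and scaled chi-squares", {
  set.seed(4)
  p <- runif(1e5)
  expect_equal(inflation_factor(p), 1, tolerance = 0.02)
  expect_equal(inflation_factor(rep(0.5, 200)), 1, tolerance = 1e-12)
  # doubling the chi-square statistics doubles lambda
  x <- stats::rchisq(5e4, 1)
  p2 <- stats::pchisq(2 * x, 1, lower.tail = FALSE)
  expect_equal(inflation_factor(p2), 2, tolerance = 0.05)
  expect_error(inflation_factor(c(0.5, 0)), "0, 1")
  expect_warning(inflation_factor(runif(10)), "Fewer than 100")
})

test_that("GWAS tables classify hits with inclusive boundaries", {
  th <- gwas_thresholds(100, 0.05)  # sig p = 5e-4, suggestive p = 0.01
  res <- tibble::tibble(snp = paste0("s", 1:4), chrom = 1L,
                        pos_bp = 1:4 * 1e5,
                        p = c(5e-4, 0.01, 0.5, NA))
  tabs <- gwas_tables(res, th)
  expect_equal(tabs$manhattan$class,
               c("significant", "suggestive", "none", "none"))
  expect_equal(nrow(tabs$hits), 2L)
  expect_equal(tabs$hits$snp[1], "s1")
  expect_equal(nrow(tabs$qq), 3L)
  expect_true(all(diff(tabs$qq$observed_logp) <= 0 |
                    diff(tabs$qq$expected_logp) <= 0))
  # no hits -> empty hit list, complete table
  tabs0 <- gwas_tables(dplyr::mutate(res, p = c(0.5, 0.6, 0.7, 0.8)), th)
  expect_equal(nrow(tabs0$hits), 0L)
  expect_equal(nrow(tabs0$manhattan), 4L)
})

test_that("plot builders return ggplot objects", {
  th <- gwas_thresholds(100)
  res <- tibble::tibble(snp = paste0("s", 1:20), chrom = rep(1:2, each = 10),
                        pos_bp = rep(1:10 * 1e6, 2), p = runif(20),
                        minus_log10_p = -log10(runif(20)))
  expect_s3_class(plot_manhattan(res, th), "ggplot")
  tabs <- gwas_tables(res[, -5], th)
  expect_s3_class(plot_qq(tabs$qq, inflation = 1), "ggplot")
  herd <- small_herd()
  expect_s3_class(plot_ld_decay(compute_ld(herd$geno, seed = 1)), "ggplot")
})
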