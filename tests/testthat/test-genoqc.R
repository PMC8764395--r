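test_that("MAF filter counts alleles over non-missing calls", {
  g <- toy_geno(rbind(c(0, 0, 2), c(0, 0, 1), c(0, 0, 1), c(1, 0, 0)))
  # SNP1: p = 1/8 = 0.125 kept at 0.05; SNP2 monomorphic removed; SNP3 kept
  f <- filter_maf(g, 0.05)
  expect_setequal(f$removed$snp, "s2")
  expect_equal(f$removed$maf, 0)
  expect_equal(colnames(geno_matrix(f$geno)), c("s1", "s3"))
  # threshold 0 removes nothing
  expect_equal(ncol(geno_matrix(filter_maf(g, 0)$geno)), 3L)
  # all-missing SNP treated as MAF 0 with warning
  gm <- geno_matrix(g); gm[, 1] <- NA
  expect_warning(f2 <- filter_maf(toy_geno(gm), 0.05), "all calls missing")
  expect_true("s1" %in% f2$removed$snp)
  # idempotence
  f3 <- filter_maf(f$geno, 0.05)
  expect_identical(geno_matrix(f3$geno), geno_matrix(f$geno))
})

test_that("HWE filter measures the heterozygosity deviation from 2pq", {
  g <- toy_geno(rbind(c(0, 1), c(1, 1), c(1, 1), c(2, 1)))
  # SNP1: p = 0.5, obs het 0.5, dev 0 -> kept
  # SNP2: all het, p = 0.5, dev 0.5 -> removed
  f <- filter_hwe(g, 0.15)
  expect_equal(f$removed$snp, "s2")
  expect_equal(f$removed$dev, 0.5)
  expect_equal(colnames(geno_matrix(f$geno)), "s1")
  expect_equal(nrow(filter_hwe(g, 1)$removed), 0L)
})

test_that("call-rate filter matches a brute-force application", {
  set.seed(42)
  gm <- matrix(rbinom(25, 2, 0.4), 5, 5)
  gm[cbind(c(1, 1, 2, 3, 5, 5, 4), c(1, 2, 1, 3, 1, 4, 1))] <- NA
  g <- toy_geno(gm)
  f <- filter_callrate(g, 0.9, 0.8)
  # oracle: snp filter first, then animals on surviving snps
  keep_snp <- colMeans(!is.na(gm)) >= 0.9
  keep_an <- rowMeans(!is.na(gm[, keep_snp, drop = FALSE])) >= 0.8
  expect_equal(nrow(f$removed_snps), sum(!keep_snp))
  expect_equal(nrow(f$removed_animals), sum(!keep_an))
  expect_equal(dim(geno_matrix(f$geno)), c(sum(keep_an), sum(keep_snp)))
  # complete matrix unchanged
  g2 <- toy_geno(matrix(1, 3, 3))
  expect_equal(dim(geno_matrix(filter_callrate(g2, 0.9, 0.95)$geno)), c(3L, 3L))
  # conservation: removed + kept = input
  expect_equal(nrow(f$removed_snps) + ncol(geno_matrix(f$geno)), 5L)
  expect_equal(nrow(f$removed_animals) + nrow(geno_matrix(f$geno)), 5L)
})

test_that("Mendelian conflicts follow opposite-homozygote and trio rules", {
  gm <- rbind(`1` = c(0, 1, 0), `2` = c(0, 2, 0), `3` = c(2, 1, 1))
  colnames(gm) <- paste0("s", 1:3)
  g <- toy_geno(gm)
  ped <- tibble::tibble(id = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L))
  conf <- detect_mendelian_conflicts(g, ped)
  # s1: sire 0 offspring 2 -> opposite homozygote conflict
  # s2: sire het -> no conflict from sire; dam 2, off 1 ok
  # s3: sire 0, dam 0, offspring 1 -> trio conflict
  expect_setequal(conf$snp, c("s1", "s3"))
  expect_true(all(conf$id == "3"))
  g2 <- resolve_mendelian_conflicts(g, conf)
  expect_true(all(is.na(geno_matrix(g2)["3", c("s1", "s3")])))
  expect_equal(geno_matrix(g2)["3", "s2"], 1)
})

test_that("MAF summary matches hand allele counts", {
  g <- toy_geno(rbind(c(0, 0, 2), c(1, 0, 2), c(2, 2, 2)))
  ms <- maf_summary(g)
  expect_equal(ms$snp$maf, c(0.5, 1 / 3, 0))
  expect_true(all(ms$snp$maf >= 0 & ms$snp$maf <= 0.5))
})

test_that("LD r2 is the squared Pearson correlation of allele counts", {
  x <- c(0, 1, 2, 1)
  gm <- cbind(x, 2 - x, c(0, 1, 1, 2))
  colnames(gm) <- NULL
  g <- toy_geno(gm)
  ld <- compute_ld(g)
  pick <- function(i, j) ld$r2[ld$snp_i == i & ld$snp_j == j]
  expect_equal(pick("s1", "s2"), 1)          # complement: sign squared away
  expect_equal(pick("s1", "s3"), 0.25)       # hand: cov 1/3, vars 2/3 each
  gdup <- cbind(x, x); colnames(gdup) <- NULL
  dup <- toy_geno(gdup)
  expect_equal(compute_ld(dup)$r2, 1)
  expect_true(all(ld$r2 >= 0 & ld$r2 <= 1))
})

test_that("PCA of G matches an independent eigensolve", {
  G <- matrix(c(2, 1, 0.5, 1, 3, 0.2, 0.5, 0.2, 1.5), 3, 3)
  G <- (G + t(G)) / 2
  p <- pca_of_g(G, k = 3)
  ev <- eigen(G, symmetric = TRUE)
  expect_equal(p$eigenvalues, ev$values)
  expect_equal(abs(as.matrix(p$scores[, -1])),
               abs(sweep(ev$vectors, 2, sqrt(ev$values), "*")),
               ignore_attr = TRUE, tolerance = 1e-10)
  # identity -> flat spectrum; rank-1 -> single nonzero eigenvalue
  expect_equal(pca_of_g(diag(4))$eigenvalues, rep(1, 4))
  v <- c(1, 2, 3)
  ev1 <- pca_of_g(tcrossprod(v))$eigenvalues
  expect_equal(sum(ev1 > 1e-10), 1L)
  expect_error(pca_of_g(matrix(1:4, 2, 2)), "symmetric")
})

test_that("imputation cross-validation scores imputers against truth", {
  herd <- small_herd()
  sp <- split_panels(herd$geno, 0.5, 0.6, seed = 3)
  oracle <- function(geno, ped) geno_matrix(herd$geno)[rownames(geno_matrix(geno)), ]
  cv <- imputation_cv(herd$geno, sp$mask, n_rounds = 3,
                      n_animals_per_round = 5, imputer = oracle, seed = 1)
  expect_equal(cv$rounds$accuracy, rep(1, 3))
  expect_equal(cv$mean_accuracy, 1)

  # parent-average beats the plain per-SNP mean on pedigree data
  cv_pa <- imputation_cv(herd$geno, sp$mask, n_rounds = 4,
                         n_animals_per_round = 10,
                         imputer = impute_parent_average,
                         ped = herd$pedigree, seed = 7)
  cv_mean <- imputation_cv(herd$geno, sp$mask, n_rounds = 4,
                           n_animals_per_round = 10,
                           imputer = impute_snp_mean,
                           ped = herd$pedigree, seed = 7)
  expect_gt(cv_pa$mean_accuracy, cv_mean$mean_accuracy)

  # constant-frequency panel: per-SNP mean imputer has ~no information
  cfgc <- sim_config(n_founders = 80, n_generations = 1, n_chromosomes = 2,
                     snps_per_chromosome = 40, founder_maf_low = 0.3,
                     founder_maf_high = 0.3, ld_decay_bp = 1, seed = 12)
  pedc <- simulate_pedigree(cfgc)
  genoc <- simulate_genotypes(pedc, cfgc)
  spc <- split_panels(genoc, 0.5, 0.5, seed = 2)
  cvc <- imputation_cv(genoc, spc$mask, n_rounds = 3,
                       n_animals_per_round = 10, imputer = impute_snp_mean,
                       seed = 5)
  expect_lt(abs(cvc$mean_accuracy), 0.3)
})

test_that("ADG derivation reproduces hand OLS and the R2 filter", {
  w <- tibble::tibble(id = rep(1:2, each = 3),
                      age_days = rep(c(30, 60, 90), 2),
                      weight_kg = c(70, 100, 130, 80, 80, 80))
  adg <- derive_adg(w)
  expect_equal(adg$adg$adg_g_d, c(1000, 0))
  expect_equal(adg$adg$r2, c(1, 1))
  # hand OLS: slope 0.9 kg/d, R2 = 1 - 1750/11875 < 0.9 -> removed
  w2 <- tibble::tibble(id = 9, age_days = c(0, 50, 100, 150),
                       weight_kg = c(50, 100, 100, 200))
  adg2 <- derive_adg(w2, r2_min = 0.9)
  expect_equal(nrow(adg2$adg), 0L)
  expect_equal(adg2$removed$r2, 1 - 1750 / 11875)
  adg2b <- derive_adg(w2, r2_min = 0.8)
  expect_equal(adg2b$adg$adg_g_d, 900)
  # sub-period slopes around a split age
  adg3 <- derive_adg(w2, r2_min = 0, split_age = 75)
  expect_equal(adg3$adg$adg_first_g_d, 1000)   # (0,50),(50,100)
  expect_equal(adg3$adg$adg_second_g_d, 2000)  # (100,100),(150,200)
  # identical ages -> error
  wbad <- tibble::tibble(id = 1, age_days = c(30, 30), weight_kg = c(1, 2))
  expect_error(derive_adg(wbad), "identical ages")
})

test_that("parity classes collapse as first/second/3-7/8+", {
  expect_equal(parity_class(c(1, 2, 3, 5, 7, 8, 9, 12)),
               c(1L, 2L, 3L, 3L, 3L, 4L, 4L, 4L))
  expect_error(parity_class(0), ">= 1")
})

test_that("the staged QC pipeline conserves counts", {
  herd <- small_herd()
  g <- geno_matrix(herd$geno)
  set.seed(3)
  # inject missingness and one bad SNP
  g[sample(length(g), round(0.02 * length(g)))] <- NA
  g[, 5] <- ifelse(is.na(g[, 5]), NA, 1)  # all-het SNP -> HWE removal
  qc <- suppressWarnings(suppressMessages(
    run_geno_qc(geno_data(g, snp_map(herd$geno)), herd$pedigree)))
  expect_false(anyNA(geno_matrix(qc$geno)))
  expect_true(snp_map(herd$geno)$snp[5] %in%
                setdiff(colnames(g), colnames(geno_matrix(qc$geno))))
  rep <- qc$report
  expect_equal(ncol(g) - sum(rep$snps_removed), ncol(geno_matrix(qc$geno)))
  expect_equal(nrow(g) - sum(rep$animals_removed), nrow(geno_matrix(qc$geno)))
})
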