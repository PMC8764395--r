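test_that("pedigree simulation respects structure and determinism", {
  cfg <- sim_config(n_founders = 2, n_generations = 1, n_per_generation = 1,
                    seed = 5)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 3L)
  expect_setequal(ped$sire[3] |> c(ped$dam[3]), c(1L, 2L))
  expect_true(all(ped$sire[1:2] == 0L) && all(ped$dam[1:2] == 0L))

  cfg0 <- sim_config(n_founders = 10, n_generations = 0, seed = 2)
  ped0 <- simulate_pedigree(cfg0)
  expect_equal(nrow(ped0), 10L)
  expect_true(all(ped0$sire == 0L))

  cfg2 <- sim_config(n_founders = 30, n_generations = 2, seed = 9)
  expect_identical(simulate_pedigree(cfg2), simulate_pedigree(cfg2))
  # parents precede offspring
  ped2 <- simulate_pedigree(cfg2)
  idx <- seq_len(nrow(ped2))
  expect_true(all(match(ped2$sire, ped2$id, nomatch = 0L) < idx))
  expect_true(all(c("M", "F") %in% ped2$sex))
})

test_that("gene dropping copies parental haplotypes without recombination", {
  cfg <- sim_config(n_founders = 2, n_generations = 1, n_per_generation = 5,
                    n_chromosomes = 1, snps_per_chromosome = 40,
                    recomb_rate = 0, seed = 3)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  hap <- attr(geno, "haplotypes")
  sire_row <- match(ped$sire[3], ped$id)
  for (i in 3:7) {
    si <- match(ped$sire[i], ped$id)
    di <- match(ped$dam[i], ped$id)
    gam1 <- hap$H1[i, ]
    gam2 <- hap$H2[i, ]
    expect_true(identical(gam1, hap$H1[si, ]) || identical(gam1, hap$H2[si, ]))
    expect_true(identical(gam2, hap$H1[di, ]) || identical(gam2, hap$H2[di, ]))
  }
  expect_identical(geno_matrix(simulate_genotypes(ped, cfg)),
                   geno_matrix(geno))
})

test_that("LD decays with distance in the simulated panel", {
  herd <- small_herd()
  ld <- compute_ld(herd$geno, seed = 1)
  near <- mean(ld$r2[ld$dist_bp < 1e6])
  far <- mean(ld$r2[ld$dist_bp > 1e6])
  expect_gt(near, far)
  expect_gt(near, 0.05)
  expect_lt(far, 0.1)
})

test_that("gene-dropping offspring mean equals the mid-parent mean", {
  cfg <- sim_config(n_founders = 2, n_generations = 1,
                    n_per_generation = 1000, n_chromosomes = 2,
                    snps_per_chromosome = 50, seed = 17)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  g <- geno_matrix(geno)
  midparent <- (g[1, ] + g[2, ]) / 2
  offmean <- colMeans(g[-(1:2), , drop = FALSE])
  expect_lt(mean(abs(offmean - midparent)), 0.06)
})

test_that("phenotype model hits the requested genetic architecture", {
  herd <- small_herd()
  cfg <- herd$cfg
  founders <- herd$pedigree$sire == 0L
  expect_equal(var(herd$truth$breeding_values$tbv[founders]),
               herd$truth$sigma_a2_true, tolerance = 1e-10)
  # slope of phenotype on true breeding value ~ 1 (checked on a larger herd)
  hm <- medium_herd()
  ph <- hm$phenotypes[!is.na(hm$phenotypes$y), ]
  slope <- cov(ph$y, ph$tbv) / var(ph$tbv)
  expect_equal(slope, 1, tolerance = 0.15)
  # sex-limited recording
  expect_true(all(is.na(herd$phenotypes$y[herd$phenotypes$sex == "F"])))

  cfg0 <- sim_config(n_founders = 50, n_generations = 1, n_chromosomes = 1,
                     snps_per_chromosome = 30, h2_true = 0, seed = 4)
  ped0 <- simulate_pedigree(cfg0)
  g0 <- simulate_genotypes(ped0, cfg0)
  ph0 <- simulate_phenotypes(ped0, g0, cfg0)
  expect_true(all(ph0$truth$qtl$effect == 0))
  expect_equal(var(ph0$phenotypes$y, na.rm = TRUE),
               ph0$truth$sigma_e2_true + 0.25 * cfg0$fixed_effect_sd^2 * 3,
               tolerance = 0.5)

  cfg1 <- sim_config(n_founders = 50, n_generations = 1, n_chromosomes = 1,
                     snps_per_chromosome = 30, h2_true = 1, mu = 0,
                     sex_limited = FALSE,
                     fixed_effect_levels = c(1, 1, 1), seed = 4)
  ped1 <- simulate_pedigree(cfg1)
  g1 <- simulate_genotypes(ped1, cfg1)
  ph1 <- simulate_phenotypes(ped1, g1, cfg1)
  expect_equal(ph1$phenotypes$y, ph1$phenotypes$tbv)
})

test_that("bivariate traits realise the requested genetic correlation", {
  cfg <- sim_config(n_founders = 120, n_generations = 2, n_chromosomes = 3,
                    snps_per_chromosome = 60, n_qtl = 120, seed = 21)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  bi <- simulate_phenotypes_bivariate(ped, geno, cfg, r_genetic = 0.6)
  expect_equal(bi$truth$r_genetic_realised, 0.6, tolerance = 1e-8)
  founders <- ped$sire == 0L
  expect_equal(var(bi$phenotypes$tbv2[founders]), cfg$h2_true * cfg$sigma_p2,
               tolerance = 1e-8)
})

test_that("weight series follow the linear growth model", {
  cfg <- sim_config(n_founders = 30, n_generations = 0, ws_noise_sd = 0,
                    ws_high_noise_fraction = 0, ws_slope_mean = 1,
                    ws_slope_sd = 0, seed = 6)
  ped <- simulate_pedigree(cfg)
  w <- simulate_weight_series(ped, cfg)
  adg <- derive_adg(w)
  expect_equal(nrow(adg$removed), 0L)
  expect_equal(adg$adg$adg_g_d, rep(1000, 30), tolerance = 1e-8)
  expect_equal(adg$adg$r2, rep(1, 30))

  # high-noise animals produce sub-0.9 R-squared series
  cfg2 <- sim_config(n_founders = 100, n_generations = 0,
                     ws_high_noise_fraction = 0.3, seed = 8)
  ped2 <- simulate_pedigree(cfg2)
  w2 <- simulate_weight_series(ped2, cfg2)
  adg2 <- derive_adg(w2)
  expect_gt(nrow(adg2$removed), 0L)
  flagged <- unique(w2$id[w2$high_noise])
  expect_true(all(adg2$removed$id %in% flagged))
})

test_that("panel splitting masks exactly the non-overlap SNPs", {
  herd <- small_herd()
  sp <- split_panels(herd$geno, hd_fraction = 0.5,
                     ld_overlap_fraction = 0.6, seed = 2)
  g <- geno_matrix(sp$geno)
  ld_an <- sp$mask$ld_animals
  expect_equal(length(sp$mask$overlap_snps), round(0.6 * ncol(g)))
  expect_true(all(is.na(g[ld_an, sp$mask$masked_snps])))
  expect_true(!anyNA(g[sp$mask$hd_animals, ]))
  expect_identical(split_panels(herd$geno, 0.5, 0.6, seed = 2)$mask, sp$mask)

  sp_all <- split_panels(herd$geno, 1, 0.6, seed = 1)
  expect_true(!anyNA(geno_matrix(sp_all$geno)))
  expect_error(split_panels(herd$geno, 0, 0.5, seed = 1), "fractions")
})
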