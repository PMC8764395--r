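#' Configuration for the synthetic herd simulator
#'
#' Bundles every knob of the simulator: pedigree shape, genome layout, the
#' linkage-disequilibrium (LD) model for founder haplotypes, the genetic
#' architecture of the trait, the fixed-effect structure of the phenotype
#' model, and the weight--age recording scheme. Defaults emulate a small
#' performance-tested dual-purpose herd: a few hundred founders, several
#' discrete generations of random mating, tens-of-megabase chromosomes with
#' LD decaying over roughly a megabase, an intermediate minor-allele-frequency
#' spectrum, a polygenic trait recorded on males only, and partial genotyping.
#'
#' @param n_founders Number of founder animals (generation 0).
#' @param n_generations Number of discrete non-founder generations.
#' @param n_per_generation Offspring produced per generation
#'   (default `n_founders`).
#' @param n_chromosomes,snps_per_chromosome,chromosome_length_bp Genome layout;
#'   positions are 1-based bp.
#' @param recomb_rate Expected crossovers per chromosome per meiosis
#'   (Poisson mean).
#' @param founder_maf_low,founder_maf_high Bounds of the uniform distribution
#'   founder allele frequencies are drawn from.
#' @param ld_decay_bp Distance scale (bp) of the first-order Markov decay of
#'   adjacent-marker correlation in founder haplotypes; larger values give
#'   longer-range LD.
#' @param n_qtl Number of SNPs carrying causal effects; the default is
#'   300 capped at the panel size (a polygenic architecture).
#' @param h2_true Narrow-sense heritability of the simulated trait, in [0, 1].
#' @param sigma_p2 Total phenotypic variance (additive + residual).
#' @param mu Overall phenotypic mean.
#' @param fixed_effect_sd Standard deviation of the level effects drawn for
#'   each fixed factor (a factor with a single level contributes 0).
#' @param sex_limited If `TRUE`, only males receive phenotypes.
#' @param prop_genotyped Fraction of animals carrying genotypes downstream
#'   (used by [split_panels()] and the pipeline driver).
#' @param fixed_effect_levels Named integer vector with the number of levels of
#'   `contemporary_group`, `parity_class` and `birth_month`.
#' @param ws_n_points,ws_age_start,ws_age_end Number and age range (days) of
#'   weight recordings per animal.
#' @param ws_intercept_mean,ws_intercept_sd,ws_slope_mean,ws_slope_sd
#'   Per-animal linear growth model: birth-ish weight (kg) and gain (kg/day).
#' @param ws_noise_sd Measurement noise (kg) of ordinary weight series.
#' @param ws_high_noise_fraction,ws_high_noise_sd Fraction of animals with
#'   erratic series and their noise level, used to exercise the R-squared
#'   data-cleaning filter.
#' @param seed Integer seed; every simulator function is a pure function of
#'   its inputs and this seed.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_founders = 20, n_generations = 2, seed = 1)
#' ped <- simulate_pedigree(cfg)
sim_config <- function(n_founders = 200L,
                       n_generations = 4L,
                       n_per_generation = n_founders,
                       n_chromosomes = 10L,
                       snps_per_chromosome = 200L,
                       chromosome_length_bp = 1e8,
                       recomb_rate = 1,
                       founder_maf_low = 0.1,
                       founder_maf_high = 0.5,
                       ld_decay_bp = 1e6,
                       n_qtl = NULL,
                       h2_true = 0.3,
                       sigma_p2 = 1,
                       mu = 0,
                       fixed_effect_sd = 0.5,
                       sex_limited = TRUE,
                       prop_genotyped = 0.5,
                       fixed_effect_levels = c(contemporary_group = 12L,
                                               parity_class = 4L,
                                               birth_month = 12L),
                       ws_n_points = 4L,
                       ws_age_start = 30,
                       ws_age_end = 330,
                       ws_intercept_mean = 45,
                       ws_intercept_sd = 6,
                       ws_slope_mean = 1.0,
                       ws_slope_sd = 0.15,
                       ws_noise_sd = 4,
                       ws_high_noise_fraction = 0.1,
                       ws_high_noise_sd = 60,
                       seed = 1L) {
  cfg <- list(
    n_founders = assert_count(n_founders, "n_founders", 1L),
    n_generations = assert_count(n_generations, "n_generations", 0L),
    n_per_generation = assert_count(n_per_generation, "n_per_generation", 1L),
    n_chromosomes = assert_count(n_chromosomes, "n_chromosomes", 1L),
    snps_per_chromosome = assert_count(snps_per_chromosome, "snps_per_chromosome", 1L),
    chromosome_length_bp = assert_scalar_number(chromosome_length_bp, "chromosome_length_bp", 1),
    recomb_rate = assert_scalar_number(recomb_rate, "recomb_rate", 0),
    founder_maf_low = assert_scalar_number(founder_maf_low, "founder_maf_low", 0, 0.5),
    founder_maf_high = assert_scalar_number(founder_maf_high, "founder_maf_high", 0, 0.5),
    ld_decay_bp = assert_scalar_number(ld_decay_bp, "ld_decay_bp", 0),
    n_qtl = assert_count(n_qtl %||% min(300L, n_chromosomes * snps_per_chromosome),
                         "n_qtl", 0L),
    h2_true = assert_scalar_number(h2_true, "h2_true", 0, 1),
    sigma_p2 = assert_scalar_number(sigma_p2, "sigma_p2", 0),
    mu = assert_scalar_number(mu, "mu"),
    fixed_effect_sd = assert_scalar_number(fixed_effect_sd, "fixed_effect_sd", 0),
    sex_limited = isTRUE(sex_limited),
    prop_genotyped = assert_scalar_number(prop_genotyped, "prop_genotyped", 0, 1),
    fixed_effect_levels = fixed_effect_levels,
    ws_n_points = assert_count(ws_n_points, "ws_n_points", 2L),
    ws_age_start = assert_scalar_number(ws_age_start, "ws_age_start", 0),
    ws_age_end = assert_scalar_number(ws_age_end, "ws_age_end", 0),
    ws_intercept_mean = ws_intercept_mean,
    ws_intercept_sd = assert_scalar_number(ws_intercept_sd, "ws_intercept_sd", 0),
    ws_slope_mean = ws_slope_mean,
    ws_slope_sd = assert_scalar_number(ws_slope_sd, "ws_slope_sd", 0),
    ws_noise_sd = assert_scalar_number(ws_noise_sd, "ws_noise_sd", 0),
    ws_high_noise_fraction = assert_scalar_number(ws_high_noise_fraction, "ws_high_noise_fraction", 0, 1),
    ws_high_noise_sd = assert_scalar_number(ws_high_noise_sd, "ws_high_noise_sd", 0),
    seed = assert_count(seed, "seed", 0L)
  )
  if (cfg$founder_maf_low > cfg$founder_maf_high) {
    abort("`founder_maf_low` must not exceed `founder_maf_high`.")
  }
  if (cfg$n_qtl > cfg$n_chromosomes * cfg$snps_per_chromosome) {
    abort("`n_qtl` cannot exceed the total number of SNPs.")
  }
  if (length(cfg$fixed_effect_levels) != 3L || any(cfg$fixed_effect_levels < 1L)) {
    abort("`fixed_effect_levels` must give 3 positive level counts.")
  }
  names(cfg$fixed_effect_levels) <- c("contemporary_group", "parity_class", "birth_month")
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-generation random-mating pedigree
#'
#' Founders (generation 0) have unknown parents; each later generation is
#' produced by sampling a sire among the previous generation's males and a dam
#' among its females. Sexes are assigned alternately and then shuffled within
#' generation, so both sexes are present even in tiny pedigrees. The returned
#' table is topologically ordered: every animal's parents precede it.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `id`, `sire`, `dam` (0 = unknown), `sex`
#'   ("M"/"F"), `generation`, `birth_month`, `dam_parity`.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    sexes_for <- function(n) {
      s <- rep(c("M", "F"), length.out = n)
      if (n > 1L) sample(s) else s
    }
    months <- function(n) sample.int(cfg$fixed_effect_levels[["birth_month"]], n, replace = TRUE)
    gens <- vector("list", cfg$n_generations + 1L)
    gens[[1L]] <- tibble::tibble(
      id = seq_len(cfg$n_founders),
      sire = 0L, dam = 0L,
      sex = sexes_for(cfg$n_founders),
      generation = 0L,
      birth_month = months(cfg$n_founders),
      dam_parity = sample.int(10L, cfg$n_founders, replace = TRUE)
    )
    next_id <- cfg$n_founders + 1L
    if (cfg$n_generations > 0L) {
      for (g in seq_len(cfg$n_generations)) {
        prev <- gens[[g]]
        sires <- prev$id[prev$sex == "M"]
        dams <- prev$id[prev$sex == "F"]
        if (length(sires) == 0L || length(dams) == 0L) {
          abort("Impossible mating structure: a generation lacks one sex.")
        }
        n <- cfg$n_per_generation
        pick <- function(pool, n) pool[sample.int(length(pool), n, replace = TRUE)]
        gens[[g + 1L]] <- tibble::tibble(
          id = seq.int(next_id, length.out = n),
          sire = pick(sires, n),
          dam = pick(dams, n),
          sex = sexes_for(n),
          generation = g,
          birth_month = months(n),
          dam_parity = sample.int(10L, n, replace = TRUE)
        )
        next_id <- next_id + n
      }
    }
    dplyr::bind_rows(gens)
  })
}

# Recombine two parental haplotypes over one chromosome: Poisson number of
# crossovers at uniform positions, random starting strand.
recombine_gamete <- function(hap1, hap2, pos, chrom_len, recomb_rate) {
  n_x <- rpois(1L, recomb_rate)
  start <- rbinom(1L, 1L, 0.5)
  if (n_x == 0L) {
    if (start == 0L) hap1 else hap2
  } else {
    xo <- sort(runif(n_x, 0, chrom_len))
    seg <- findInterval(pos, xo)
    ifelse((seg + start) %% 2L == 0L, hap1, hap2)
  }
}

#' Simulate LD-structured genotypes by gene dropping
#'
#' Founder haplotypes are drawn from a first-order Markov model: a latent
#' AR(1) Gaussian process along each chromosome (correlation
#' `exp(-distance / ld_decay_bp)`) is thresholded at each SNP's allele
#' frequency, so adjacent-marker allele correlation decays with distance.
#' Descendant haplotypes are produced by gene dropping with
#' Poisson(`recomb_rate`) crossovers per chromosome at uniform positions.
#' The genotype is the sum of the two haplotype alleles (0/1/2 alt-allele
#' dosage).
#'
#' @param ped Pedigree from [simulate_pedigree()] (topologically ordered).
#' @param cfg The [sim_config()] used to build `ped`.
#' @return A [geno_data] object for all pedigree animals, with the haplotype
#'   pair retained in attribute `"haplotypes"`.
#' @export
simulate_genotypes <- function(ped, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(ped$sire > ped$id | ped$dam > ped$id)) {
    abort("Pedigree is not topologically ordered; parents must precede offspring.")
  }
  m_per <- cfg$snps_per_chromosome
  n_chr <- cfg$n_chromosomes
  n <- nrow(ped)
  with_seed(cfg$seed + 1L, {
    map <- purrr::map_dfr(seq_len(n_chr), function(cc) {
      pos <- sort(sample.int(cfg$chromosome_length_bp, m_per))
      tibble::tibble(
        snp = sprintf("SNP%d_%d", cc, seq_len(m_per)),
        chrom = cc, pos_bp = pos,
        allele_ref = "A", allele_alt = "B",
        freq = runif(m_per, cfg$founder_maf_low, cfg$founder_maf_high)
      )
    })
    m <- nrow(map)
    H1 <- matrix(0L, n, m)
    H2 <- matrix(0L, n, m)
    founder_idx <- which(ped$sire == 0L & ped$dam == 0L)
    # founder haplotypes: latent AR(1) Gaussian, thresholded per SNP
    for (cc in seq_len(n_chr)) {
      cols <- which(map$chrom == cc)
      pos <- map$pos_bp[cols]
      p <- map$freq[cols]
      rho <- if (length(cols) > 1L) {
        exp(-diff(pos) / max(cfg$ld_decay_bp, 1))
      } else numeric(0)
      n_hap <- 2L * length(founder_idx)
      z <- matrix(0, n_hap, length(cols))
      z[, 1L] <- rnorm(n_hap)
      if (length(cols) > 1L) {
        for (j in 2L:length(cols)) {
          z[, j] <- rho[j - 1L] * z[, j - 1L] +
            sqrt(1 - rho[j - 1L]^2) * rnorm(n_hap)
        }
      }
      alle <- sweep(z, 2L, qnorm(p), "<") * 1L
      H1[founder_idx, cols] <- alle[seq_along(founder_idx), , drop = FALSE]
      H2[founder_idx, cols] <- alle[length(founder_idx) + seq_along(founder_idx), , drop = FALSE]
    }
    chr_cols <- split(seq_len(m), map$chrom)
    chr_pos <- split(map$pos_bp, map$chrom)
    for (i in setdiff(seq_len(n), founder_idx)) {
      si <- match(ped$sire[i], ped$id)
      di <- match(ped$dam[i], ped$id)
      if (is.na(si) || is.na(di)) {
        abort("Pedigree/config mismatch: non-founder with unknown parent row.")
      }
      for (cc in seq_len(n_chr)) {
        cols <- chr_cols[[cc]]
        pos <- chr_pos[[cc]]
        H1[i, cols] <- recombine_gamete(H1[si, cols], H2[si, cols], pos,
                                        cfg$chromosome_length_bp, cfg$recomb_rate)
        H2[i, cols] <- recombine_gamete(H1[di, cols], H2[di, cols], pos,
                                        cfg$chromosome_length_bp, cfg$recomb_rate)
      }
    }
    g <- H1 + H2
    rownames(g) <- as.character(ped$id)
    colnames(g) <- map$snp
    out <- geno_data(g, dplyr::select(map, -"freq"))
    attr(out, "haplotypes") <- list(H1 = H1, H2 = H2)
    out
  })
}

#' Simulate polygenic + QTL phenotypes with known truth
#'
#' The trait follows `y = mu + Xb + Mq + e`: `M` is the column-centred
#' genotype matrix, `q` a sparse vector of Gaussian QTL allele-substitution
#' effects rescaled exactly so that the realised additive variance equals
#' `h2_true * sigma_p2`, `Xb` collects contemporary-group, dam-parity-class
#' and birth-month effects, and `e` is Gaussian residual. If `sex_limited`,
#' phenotypes are assigned to males only (females get `NA`).
#'
#' @param ped Pedigree tibble.
#' @param geno Complete [geno_data] for all pedigree animals.
#' @param cfg The [sim_config()].
#' @return A list with `phenotypes` (tibble: id, sex, generation,
#'   contemporary_group, dam_parity, parity_class, birth_month, tbv, y) and
#'   `truth` (list: qtl tibble, breeding_values tibble, sigma_a2_true,
#'   sigma_e2_true).
#' @export
simulate_phenotypes <- function(ped, geno, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(geno, "geno_data"))
  g <- geno_matrix(geno)
  if (anyNA(g) || nrow(g) != nrow(ped)) {
    abort("Genotypes must be complete for all pedigree animals.")
  }
  with_seed(cfg$seed + 2L, {
    n <- nrow(ped)
    m <- ncol(g)
    p <- colMeans(g) / 2
    sigma_a2 <- cfg$h2_true * cfg$sigma_p2
    sigma_e2 <- (1 - cfg$h2_true) * cfg$sigma_p2
    qtl_idx <- if (cfg$n_qtl > 0L) sort(sample.int(m, cfg$n_qtl)) else integer(0)
    q <- rep(0, length(qtl_idx))
    tbv <- rep(0, n)
    if (cfg$h2_true > 0 && length(qtl_idx) > 0L) {
      q <- rnorm(length(qtl_idx))
      Mq <- sweep(g[, qtl_idx, drop = FALSE], 2L, 2 * p[qtl_idx], "-")
      raw <- drop(Mq %*% q)
      # the base population defining sigma_a2 is the founder generation
      founders <- ped$sire == 0L & ped$dam == 0L
      v <- if (sum(founders) >= 2L) var(raw[founders]) else var(raw)
      if (is.na(v) || v <= 0) v <- var(raw)
      if (v <= 0) abort("Degenerate QTL genotypes: zero additive variance.")
      q <- q * sqrt(sigma_a2 / v)
      tbv <- raw * sqrt(sigma_a2 / v)
    }
    lv <- cfg$fixed_effect_levels
    eff <- function(k) if (k <= 1L) rep(0, max(k, 1L)) else rnorm(k, 0, cfg$fixed_effect_sd)
    cg_eff <- eff(lv[["contemporary_group"]])
    pc_eff <- eff(lv[["parity_class"]])
    bm_eff <- eff(lv[["birth_month"]])
    cg <- sample.int(lv[["contemporary_group"]], n, replace = TRUE)
    pc <- pmin(parity_class(ped$dam_parity), lv[["parity_class"]])
    bm <- pmin(ped$birth_month, lv[["birth_month"]])
    xb <- cg_eff[cg] + pc_eff[pc] + bm_eff[bm]
    e <- if (sigma_e2 > 0) rnorm(n, 0, sqrt(sigma_e2)) else rep(0, n)
    y <- cfg$mu + xb + tbv + e
    if (cfg$sex_limited) y[ped$sex != "M"] <- NA_real_
    list(
      phenotypes = tibble::tibble(
        id = ped$id, sex = ped$sex, generation = ped$generation,
        contemporary_group = cg, dam_parity = ped$dam_parity,
        parity_class = pc, birth_month = bm, tbv = tbv, y = y
      ),
      truth = list(
        qtl = tibble::tibble(snp = colnames(g)[qtl_idx], effect = q),
        breeding_values = tibble::tibble(id = ped$id, tbv = tbv),
        sigma_a2_true = sigma_a2,
        sigma_e2_true = sigma_e2
      )
    )
  })
}

#' Simulate per-animal weight--age series
#'
#' Each animal grows linearly (per-animal intercept and slope) with Gaussian
#' measurement noise; a configurable fraction of animals receives high-noise
#' series so that the downstream R-squared cleaning filter has something to
#' remove.
#'
#' @param ped Pedigree tibble.
#' @param cfg The [sim_config()]; `ws_*` fields control the series.
#' @return Tibble with columns `id`, `age_days`, `weight_kg`, plus per-animal
#'   `true_slope_kg_d` and `high_noise` for truth-based checks.
#' @export
simulate_weight_series <- function(ped, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$ws_n_points < 2L) abort("At least 2 weight points per animal are required.")
  with_seed(cfg$seed + 3L, {
    n <- nrow(ped)
    ages <- seq(cfg$ws_age_start, cfg$ws_age_end, length.out = cfg$ws_n_points)
    slope <- rnorm(n, cfg$ws_slope_mean, cfg$ws_slope_sd)
    intercept <- rnorm(n, cfg$ws_intercept_mean, cfg$ws_intercept_sd)
    high <- runif(n) < cfg$ws_high_noise_fraction
    sds <- ifelse(high, cfg$ws_high_noise_sd, cfg$ws_noise_sd)
    purrr::map_dfr(seq_len(n), function(i) {
      tibble::tibble(
        id = ped$id[i],
        age_days = ages,
        weight_kg = intercept[i] + slope[i] * ages +
          rnorm(length(ages), 0, sds[i]),
        true_slope_kg_d = slope[i],
        high_noise = high[i]
      )
    })
  })
}

#' Split a genotype panel into high- and low-density subsets
#'
#' Marks a random subset of animals as high-density (HD); the remaining
#' animals keep only the overlap SNP subset shared between the two platforms,
#' all other calls being set missing. The returned mask records exactly what
#' was hidden so imputation accuracy can be scored against truth.
#'
#' @param geno A [geno_data] object.
#' @param hd_fraction Fraction of animals on the HD panel, in (0, 1].
#' @param ld_overlap_fraction Fraction of SNPs shared by the low-density
#'   panel, in (0, 1].
#' @param seed Integer seed.
#' @return List with `geno` (masked panel) and `mask` (list: `hd_animals`,
#'   `ld_animals`, `overlap_snps`, `masked_snps`).
#' @export
split_panels <- function(geno, hd_fraction, ld_overlap_fraction, seed = 1L) {
  stopifnot(inherits(geno, "geno_data"))
  assert_scalar_number(hd_fraction, "hd_fraction", 0, 1)
  assert_scalar_number(ld_overlap_fraction, "ld_overlap_fraction", 0, 1)
  if (hd_fraction <= 0 || ld_overlap_fraction <= 0) {
    abort("Panel fractions must be in (0, 1].")
  }
  g <- geno_matrix(geno)
  ids <- rownames(g)
  snps <- colnames(g)
  with_seed(seed, {
    n_hd <- max(1L, round(hd_fraction * length(ids)))
    hd <- sort(sample(ids, n_hd))
    ld <- setdiff(ids, hd)
    n_ov <- max(1L, round(ld_overlap_fraction * length(snps)))
    overlap <- sort(sample(snps, n_ov))
    masked <- setdiff(snps, overlap)
    if (length(ld) > 0L && length(masked) > 0L) {
      g[ld, masked] <- NA_integer_
    }
    list(
      geno = geno_data(g, snp_map(geno)),
      mask = list(hd_animals = hd, ld_animals = ld,
                  overlap_snps = overlap, masked_snps = masked)
    )
  })
}

#' Simulate two genetically correlated traits
#'
#' Builds two genomic traits on the same QTL set with a target genetic
#' correlation: the second trait's QTL effect vector is a linear combination
#' of the first's and an independent draw, chosen so the founder-generation
#' breeding values have exactly the requested correlation and variances.
#' Residuals are drawn with correlation `r_residual` for animals recorded in
#' both traits. Both traits share the fixed-effect structure (independent
#' level effects) and the sex-limited recording rule.
#'
#' @param ped Pedigree tibble.
#' @param geno Complete [geno_data] for all pedigree animals.
#' @param cfg The [sim_config()]; `h2_true` applies to trait 1.
#' @param r_genetic Target genetic correlation between the traits.
#' @param h2_2 Heritability of trait 2 (default: same as trait 1).
#' @param r_residual Residual correlation (default 0).
#' @return List with `phenotypes` (tibble incl. `y1`, `y2`, `tbv1`, `tbv2`)
#'   and `truth` (per-trait variances and the realised founder genetic
#'   correlation).
#' @export
simulate_phenotypes_bivariate <- function(ped, geno, cfg, r_genetic,
                                          h2_2 = cfg$h2_true,
                                          r_residual = 0) {
  stopifnot(inherits(cfg, "sim_config"), inherits(geno, "geno_data"))
  assert_scalar_number(r_genetic, "r_genetic", -1, 1)
  assert_scalar_number(h2_2, "h2_2", 0, 1)
  g <- geno_matrix(geno)
  if (anyNA(g) || nrow(g) != nrow(ped)) {
    abort("Genotypes must be complete for all pedigree animals.")
  }
  if (cfg$h2_true <= 0 || h2_2 <= 0 || cfg$n_qtl < 2L) {
    abort("Bivariate simulation needs positive heritabilities and >= 2 QTL.")
  }
  with_seed(cfg$seed + 4L, {
    n <- nrow(ped)
    m <- ncol(g)
    p <- colMeans(g) / 2
    founders <- ped$sire == 0L & ped$dam == 0L
    base <- if (sum(founders) >= 2L) founders else rep(TRUE, n)
    v1 <- cfg$h2_true * cfg$sigma_p2
    v2 <- h2_2 * cfg$sigma_p2
    qtl_idx <- sort(sample.int(m, cfg$n_qtl))
    Mq <- sweep(g[, qtl_idx, drop = FALSE], 2L, 2 * p[qtl_idx], "-")
    scale_to <- function(x, v) x * sqrt(v / var(x[base]))
    t1 <- scale_to(drop(Mq %*% rnorm(cfg$n_qtl)), v1)
    u <- drop(Mq %*% rnorm(cfg$n_qtl))
    # founder-moment orthogonalisation, still linear in genotypes
    w <- u - (cov(t1[base], u[base]) / v1) * t1
    t2 <- r_genetic * sqrt(v2 / v1) * t1 +
      sqrt(max(1 - r_genetic^2, 0)) * scale_to(w, v2)
    e1v <- (1 - cfg$h2_true) * cfg$sigma_p2
    e2v <- (1 - h2_2) * cfg$sigma_p2
    z1 <- rnorm(n); z2 <- rnorm(n)
    e1 <- sqrt(e1v) * z1
    e2 <- sqrt(e2v) * (r_residual * z1 + sqrt(1 - r_residual^2) * z2)
    lv <- cfg$fixed_effect_levels
    eff <- function(k) if (k <= 1L) rep(0, max(k, 1L)) else rnorm(k, 0, cfg$fixed_effect_sd)
    cg <- sample.int(lv[["contemporary_group"]], n, replace = TRUE)
    pc <- pmin(parity_class(ped$dam_parity), lv[["parity_class"]])
    bm <- pmin(ped$birth_month, lv[["birth_month"]])
    xb1 <- eff(lv[["contemporary_group"]])[cg] + eff(lv[["parity_class"]])[pc] +
      eff(lv[["birth_month"]])[bm]
    xb2 <- eff(lv[["contemporary_group"]])[cg] + eff(lv[["parity_class"]])[pc] +
      eff(lv[["birth_month"]])[bm]
    y1 <- cfg$mu + xb1 + t1 + e1
    y2 <- cfg$mu + xb2 + t2 + e2
    if (cfg$sex_limited) {
      y1[ped$sex != "M"] <- NA_real_
      y2[ped$sex != "M"] <- NA_real_
    }
    list(
      phenotypes = tibble::tibble(
        id = ped$id, sex = ped$sex, generation = ped$generation,
        contemporary_group = cg, parity_class = pc, birth_month = bm,
        tbv1 = t1, tbv2 = t2, y1 = y1, y2 = y2
      ),
      truth = list(
        sigma_a2 = c(v1, v2),
        sigma_e2 = c(e1v, e2v),
        r_genetic = r_genetic,
        r_genetic_realised = cor(t1[base], t2[base]),
        qtl = tibble::tibble(snp = colnames(g)[qtl_idx])
      )
    )
  })
}

#' One-call synthetic herd
#'
#' Convenience wrapper chaining [simulate_pedigree()], [simulate_genotypes()],
#' [simulate_phenotypes()] and [simulate_weight_series()].
#'
#' @param cfg A [sim_config()].
#' @return List with `pedigree`, `geno`, `phenotypes`, `truth`, `weights`.
#' @export
simulate_herd <- function(cfg = sim_config()) {
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(ped, geno, cfg)
  w <- simulate_weight_series(ped, cfg)
  list(pedigree = ped, geno = geno, phenotypes = ph$phenotypes,
       truth = ph$truth, weights = w)
}
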