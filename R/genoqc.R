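#' Quality-control thresholds
#'
#' The default values reproduce a two-stage genotype cleaning protocol:
#' a pre-imputation pass (MAF < 0.01, SNP call rate < 0.90) and a
#' post-imputation pass (MAF < 0.05, heterozygosity deviating from the
#' Hardy--Weinberg expectation 2pq by more than 0.15, SNP call rate < 0.90,
#' animal call rate < 0.95), plus the growth-curve cleaning rule that drops
#' animals whose weight-on-age regression has R-squared below 0.9.
#'
#' @param maf_pre,callrate_snp_pre Pre-imputation SNP filters.
#' @param maf_post,hwe_het_dev,callrate_snp_post,callrate_animal
#'   Post-imputation filters.
#' @param adg_r2_min Minimum R-squared of the weight-on-age regression.
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_pre = 0.01, callrate_snp_pre = 0.90,
                          maf_post = 0.05, hwe_het_dev = 0.15,
                          callrate_snp_post = 0.90, callrate_animal = 0.95,
                          adg_r2_min = 0.90) {
  th <- list(maf_pre = maf_pre, callrate_snp_pre = callrate_snp_pre,
             maf_post = maf_post, hwe_het_dev = hwe_het_dev,
             callrate_snp_post = callrate_snp_post,
             callrate_animal = callrate_animal, adg_r2_min = adg_r2_min)
  for (nm in names(th)) assert_scalar_number(th[[nm]], nm, 0, 1)
  structure(th, class = "qc_thresholds")
}

#' Remove SNPs with low minor allele frequency
#'
#' MAF is computed on non-missing calls. SNPs with every call missing are
#' treated as MAF 0 and removed with a warning.
#'
#' @param geno A [geno_data] object.
#' @param threshold SNPs with MAF strictly below this are removed.
#' @return List with `geno` (filtered) and `removed` (tibble: snp, maf).
#' @export
filter_maf <- function(geno, threshold = 0.05) {
  g <- geno_matrix(geno)
  p <- allele_freq(g)
  maf <- pmin(p, 1 - p)
  all_missing <- is.nan(p) | is.na(p)
  if (any(all_missing)) {
    warn(sprintf("%d SNP(s) with all calls missing treated as MAF 0 and removed.",
                 sum(all_missing)))
    maf[all_missing] <- 0
  }
  drop <- maf < threshold
  list(
    geno = subset_geno(geno, snps = colnames(g)[!drop]),
    removed = tibble::tibble(snp = colnames(g)[drop], maf = unname(maf[drop]))
  )
}

#' Remove SNPs deviating from Hardy--Weinberg heterozygosity
#'
#' A SNP is removed when the absolute deviation of its observed heterozygote
#' proportion from the expected 2p(1-p) exceeds `dev_threshold`. Proportions
#' are computed over non-missing calls.
#'
#' @param geno A [geno_data] object.
#' @param dev_threshold Maximum tolerated |observed het - 2pq|.
#' @return List with `geno` and `removed` (tibble: snp, het_obs, het_exp, dev).
#' @export
filter_hwe <- function(geno, dev_threshold = 0.15) {
  g <- geno_matrix(geno)
  p <- allele_freq(g)
  het_obs <- colMeans(g == 1, na.rm = TRUE)
  het_exp <- 2 * p * (1 - p)
  dev <- abs(het_obs - het_exp)
  dev[is.na(dev)] <- 0
  drop <- dev > dev_threshold
  list(
    geno = subset_geno(geno, snps = colnames(g)[!drop]),
    removed = tibble::tibble(snp = colnames(g)[drop],
                             het_obs = unname(het_obs[drop]),
                             het_exp = unname(het_exp[drop]),
                             dev = unname(dev[drop]))
  )
}

#' Remove SNPs and animals with low call rate
#'
#' The SNP filter is applied first; animal call rates are then computed on the
#' surviving SNPs.
#'
#' @param geno A [geno_data] object.
#' @param snp_thr SNPs with call rate strictly below this are removed.
#' @param animal_thr Animals with call rate strictly below this are removed.
#' @return List with `geno`, `removed_snps`, `removed_animals`.
#' @export
filter_callrate <- function(geno, snp_thr = 0.90, animal_thr = 0.95) {
  g <- geno_matrix(geno)
  cr_snp <- colMeans(!is.na(g))
  keep_snp <- cr_snp >= snp_thr
  if (!any(keep_snp)) abort("Call-rate filter removed every SNP.")
  g2 <- g[, keep_snp, drop = FALSE]
  cr_an <- rowMeans(!is.na(g2))
  keep_an <- cr_an >= animal_thr
  if (!any(keep_an)) abort("Call-rate filter removed every animal.")
  list(
    geno = subset_geno(geno, animals = rownames(g)[keep_an],
                       snps = colnames(g)[keep_snp]),
    removed_snps = tibble::tibble(snp = colnames(g)[!keep_snp],
                                  call_rate = unname(cr_snp[!keep_snp])),
    removed_animals = tibble::tibble(id = rownames(g)[!keep_an],
                                     call_rate = unname(cr_an[!keep_an]))
  )
}

#' Detect Mendelian conflicts between parents and offspring
#'
#' A conflict is flagged when parent and offspring are opposite homozygotes at
#' a SNP, or when both parents are the same homozygote and the offspring is
#' heterozygous (it cannot have received the absent allele from either side).
#' Only animals present in the genotype data are considered.
#'
#' @param geno A [geno_data] object.
#' @param ped Pedigree tibble (`id`, `sire`, `dam`; 0 = unknown).
#' @return Tibble with one row per conflicting (offspring, snp): columns
#'   `id`, `snp`, `off_geno`, `sire_geno`, `dam_geno`.
#' @export
detect_mendelian_conflicts <- function(geno, ped) {
  g <- geno_matrix(geno)
  ids <- rownames(g)
  res <- vector("list", nrow(ped))
  for (i in seq_len(nrow(ped))) {
    off <- as.character(ped$id[i])
    if (!off %in% ids) next
    s <- as.character(ped$sire[i]); d <- as.character(ped$dam[i])
    gs <- if (ped$sire[i] != 0L && s %in% ids) g[s, ] else rep(NA_real_, ncol(g))
    gd <- if (ped$dam[i] != 0L && d %in% ids) g[d, ] else rep(NA_real_, ncol(g))
    go <- g[off, ]
    opp <- (!is.na(go) & !is.na(gs) & abs(go - gs) == 2) |
           (!is.na(go) & !is.na(gd) & abs(go - gd) == 2)
    both_hom_het <- !is.na(go) & go == 1 & !is.na(gs) & !is.na(gd) &
      gs == gd & (gs == 0 | gs == 2)
    conf <- which(opp | both_hom_het)
    if (length(conf)) {
      res[[i]] <- tibble::tibble(
        id = off, snp = colnames(g)[conf],
        off_geno = unname(go[conf]),
        sire_geno = unname(gs[conf]),
        dam_geno = unname(gd[conf])
      )
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(id = character(), snp = character(),
                          off_geno = double(), sire_geno = double(),
                          dam_geno = double())
  }
  out
}

#' Resolve Mendelian conflicts by blanking the offspring call
#'
#' @param geno A [geno_data] object.
#' @param conflicts Output of [detect_mendelian_conflicts()].
#' @return A `geno_data` with the offending offspring calls set missing.
#' @export
resolve_mendelian_conflicts <- function(geno, conflicts) {
  g <- geno_matrix(geno)
  if (nrow(conflicts)) {
    g[cbind(conflicts$id, conflicts$snp)] <- NA
  }
  geno_data(g, snp_map(geno))
}

#' Minor-allele-frequency summary
#'
#' @param geno A [geno_data] object.
#' @return List with `snp` (tibble: snp, chrom, maf), `chromosome` (tibble:
#'   chrom, n_snps, mean_maf, sd_maf) and `overall` (tibble: mean_maf, sd_maf).
#' @export
maf_summary <- function(geno) {
  p <- allele_freq(geno)
  maf <- pmin(p, 1 - p)
  per_snp <- dplyr::mutate(
    dplyr::select(snp_map(geno), "snp", "chrom"), maf = unname(maf))
  per_chrom <- dplyr::summarise(
    dplyr::group_by(per_snp, .data$chrom),
    n_snps = dplyr::n(),
    mean_maf = mean(.data$maf, na.rm = TRUE),
    sd_maf = sd(.data$maf, na.rm = TRUE), .groups = "drop")
  list(snp = per_snp, chromosome = per_chrom,
       overall = tibble::tibble(mean_maf = mean(per_snp$maf, na.rm = TRUE),
                                sd_maf = sd(per_snp$maf, na.rm = TRUE)))
}

#' Within-chromosome linkage disequilibrium (r-squared)
#'
#' r2 is the squared Pearson correlation of 0/1/2 allele counts over animals
#' non-missing at both SNPs, for within-chromosome pairs only. When a
#' chromosome carries more pairs than `max_pairs_per_chrom`, a seeded random
#' subsample of pairs is returned. Pairs involving a zero-variance SNP are
#' skipped.
#'
#' @param geno A [geno_data] object.
#' @param max_pairs_per_chrom Cap on reported pairs per chromosome.
#' @param seed Seed for pair subsampling.
#' @return Tibble with columns `chrom`, `snp_i`, `snp_j`, `dist_bp`, `r2`.
#' @export
compute_ld <- function(geno, max_pairs_per_chrom = 200000L, seed = 1L) {
  g <- geno_matrix(geno)
  map <- snp_map(geno)
  with_seed(seed, {
    purrr::map_dfr(split(seq_len(nrow(map)), map$chrom), function(cols) {
      m <- length(cols)
      if (m < 2L) return(NULL)
      keep <- which(apply(g[, cols, drop = FALSE], 2L, function(x) {
        sd(x, na.rm = TRUE) > 0
      }))
      if (length(keep) < 2L) return(NULL)
      cols <- cols[keep]
      cm <- suppressWarnings(cor(g[, cols, drop = FALSE],
                                 use = "pairwise.complete.obs"))
      ut <- which(upper.tri(cm), arr.ind = TRUE)
      if (nrow(ut) > max_pairs_per_chrom) {
        ut <- ut[sample.int(nrow(ut), max_pairs_per_chrom), , drop = FALSE]
      }
      r <- cm[ut]
      ok <- !is.na(r)
      tibble::tibble(
        chrom = map$chrom[cols[1L]],
        snp_i = map$snp[cols[ut[ok, 1L]]],
        snp_j = map$snp[cols[ut[ok, 2L]]],
        dist_bp = abs(map$pos_bp[cols[ut[ok, 2L]]] - map$pos_bp[cols[ut[ok, 1L]]]),
        r2 = r[ok]^2
      )
    })
  })
}

#' Summarise LD decay in distance bins
#'
#' @param ld Output of [compute_ld()].
#' @param bin_bp Bin width in bp (default 1 Mb).
#' @return Tibble with `bin_start_bp`, `bin_end_bp`, `n_pairs`, `mean_r2`,
#'   `sd_r2`.
#' @export
ld_decay_summary <- function(ld, bin_bp = 1e6) {
  dplyr::summarise(
    dplyr::group_by(ld, bin = floor(.data$dist_bp / bin_bp)),
    n_pairs = dplyr::n(),
    mean_r2 = mean(.data$r2),
    sd_r2 = sd(.data$r2), .groups = "drop") |>
    dplyr::transmute(bin_start_bp = .data$bin * bin_bp,
                     bin_end_bp = (.data$bin + 1) * bin_bp,
                     n_pairs = .data$n_pairs, mean_r2 = .data$mean_r2,
                     sd_r2 = .data$sd_r2)
}

#' Principal components of a genomic relationship matrix
#'
#' Eigendecomposition of a symmetric relationship matrix; principal-component
#' coordinates are eigenvector times the square root of the eigenvalue,
#' ordered by decreasing eigenvalue.
#'
#' @param G Symmetric matrix (e.g. from [build_g()]), with animal dimnames.
#' @param k Number of components to return.
#' @return List with `eigenvalues` (full vector) and `scores` (tibble: id,
#'   PC1..PCk).
#' @export
pca_of_g <- function(G, k = 10L) {
  if (!is_symmetric_mat(G, tol = 1e-6)) abort("`G` must be symmetric.")
  es <- eigen((G + t(G)) / 2, symmetric = TRUE)
  k <- min(k, ncol(G))
  lam <- pmax(es$values[seq_len(k)], 0)
  scores <- sweep(es$vectors[, seq_len(k), drop = FALSE], 2L, sqrt(lam), "*")
  colnames(scores) <- paste0("PC", seq_len(k))
  ids <- rownames(G) %||% as.character(seq_len(nrow(G)))
  list(eigenvalues = es$values,
       scores = dplyr::bind_cols(tibble::tibble(id = ids),
                                 tibble::as_tibble(scores)))
}

#' Baseline imputers
#'
#' `impute_snp_mean()` replaces each missing call with the per-SNP mean of
#' observed dosages. `impute_parent_average()` uses the average of available
#' parental genotypes at the SNP when at least one parent is genotyped and
#' non-missing there, falling back to the per-SNP mean.
#'
#' @param geno A [geno_data] with missing calls.
#' @param ped Pedigree tibble (only used by the parent-average imputer).
#' @return A numeric animals-by-SNPs matrix of imputed dosages (possibly
#'   fractional), `NA`-free wherever imputation was possible.
#' @export
impute_snp_mean <- function(geno, ped = NULL) {
  g <- geno_matrix(geno)
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx)) g[idx] <- mu[idx[, 2L]]
  g
}

#' @rdname impute_snp_mean
#' @export
impute_parent_average <- function(geno, ped) {
  g0 <- geno_matrix(geno)
  g <- g0
  mu <- colMeans(g0, na.rm = TRUE)
  ids <- rownames(g0)
  miss_an <- which(rowSums(is.na(g0)) > 0L)
  for (i in miss_an) {
    id <- ids[i]
    row <- match(as.numeric(id), ped$id)
    pg <- NULL
    if (!is.na(row)) {
      par <- c(ped$sire[row], ped$dam[row])
      par <- as.character(par[par != 0L])
      par <- par[par %in% ids]
      if (length(par)) {
        pg <- colMeans(g0[par, , drop = FALSE], na.rm = TRUE)
      }
    }
    nas <- is.na(g0[i, ])
    fill <- if (!is.null(pg)) ifelse(is.nan(pg), mu, pg) else mu
    g[i, nas] <- fill[nas]
  }
  g
}

#' Masking cross-validation of imputation accuracy
#'
#' In each round, the overlap SNPs are hidden in a random subset of candidate
#' animals, the pluggable imputer fills the panel back in, and accuracy is the
#' Pearson correlation between true and imputed dosages over the masked cells.
#' Cells the imputer leaves missing are counted as failures and excluded from
#' the correlation.
#'
#' @param geno_full A complete [geno_data] (truth).
#' @param mask Mask description, e.g. `split_panels()$mask`; `overlap_snps`
#'   are hidden and `hd_animals` (if present) are the candidate animals.
#' @param n_rounds Number of cross-validation rounds.
#' @param n_animals_per_round Animals masked per round.
#' @param imputer Function `(geno_masked, ped) -> matrix` of imputed dosages.
#' @param ped Pedigree passed through to the imputer.
#' @param seed Integer seed.
#' @return List with `rounds` (tibble: round, n_masked, n_failed, accuracy)
#'   and `mean_accuracy`.
#' @export
imputation_cv <- function(geno_full, mask, n_rounds = 10L,
                          n_animals_per_round = 10L,
                          imputer = impute_parent_average, ped = NULL,
                          seed = 1L) {
  g_true <- geno_matrix(geno_full)
  if (anyNA(g_true[, mask$overlap_snps])) {
    abort("`geno_full` must be complete at the masked positions.")
  }
  candidates <- mask$hd_animals %||% rownames(g_true)
  snps <- mask$overlap_snps
  with_seed(seed, {
    rounds <- purrr::map_dfr(seq_len(n_rounds), function(r) {
      an <- sample(candidates, min(n_animals_per_round, length(candidates)))
      g_masked <- g_true
      g_masked[an, snps] <- NA
      gm <- geno_data(g_masked, snp_map(geno_full))
      imp <- imputer(gm, ped)
      truth <- as.vector(g_true[an, snps, drop = FALSE])
      pred <- as.vector(imp[an, snps, drop = FALSE])
      failed <- is.na(pred)
      if (any(failed)) {
        inform(sprintf("Round %d: %d cell(s) left missing by the imputer.",
                       r, sum(failed)))
      }
      acc <- if (sd(truth[!failed]) > 0 && sd(pred[!failed]) > 0) {
        cor(truth[!failed], pred[!failed])
      } else NA_real_
      tibble::tibble(round = r, n_masked = length(truth),
                     n_failed = sum(failed), accuracy = acc)
    })
    list(rounds = rounds, mean_accuracy = mean(rounds$accuracy, na.rm = TRUE))
  })
}

#' Average daily gain from weight--age series
#'
#' Per animal, the ordinary-least-squares slope of weight (kg) on age (days)
#' converted to g/day, with the regression R-squared. Animals with R-squared
#' below `r2_min` are excluded and listed. An exactly constant series has
#' slope 0 and is treated as a perfect fit (R-squared 1). If `split_age` is
#' given, sub-period slopes are also returned: ages `<= split_age` (first),
#' ages `>= split_age` (second); a sub-period with fewer than 2 distinct ages
#' yields `NA`.
#'
#' @param weights Tibble with columns `id`, `age_days`, `weight_kg`.
#' @param r2_min Minimum R-squared to keep an animal.
#' @param split_age Optional age (days) splitting the test period.
#' @return List with `adg` (tibble: id, n_points, adg_g_d, r2, and if split,
#'   adg_first_g_d, adg_second_g_d) and `removed` (tibble: id, r2).
#' @export
derive_adg <- function(weights, r2_min = 0.90, split_age = NULL) {
  ols_slope <- function(a, w) {
    if (length(unique(a)) < 2L) return(c(NA_real_, NA_real_))
    b <- cov(a, w) / var(a)
    fit <- mean(w) + b * (a - mean(a))
    sst <- sum((w - mean(w))^2)
    r2 <- if (sst == 0) 1 else 1 - sum((w - fit)^2) / sst
    c(b, r2)
  }
  res <- dplyr::group_by(weights, .data$id) |>
    dplyr::group_modify(function(df, key) {
      if (length(unique(df$age_days)) < 2L) {
        abort(sprintf("Animal %s: all weights recorded at identical ages.",
                      as.character(key$id)))
      }
      full <- ols_slope(df$age_days, df$weight_kg)
      out <- tibble::tibble(n_points = nrow(df),
                            adg_g_d = full[1L] * 1000, r2 = full[2L])
      if (!is.null(split_age)) {
        d1 <- df[df$age_days <= split_age, ]
        d2 <- df[df$age_days >= split_age, ]
        out$adg_first_g_d <- ols_slope(d1$age_days, d1$weight_kg)[1L] * 1000
        out$adg_second_g_d <- ols_slope(d2$age_days, d2$weight_kg)[1L] * 1000
      }
      out
    }) |>
    dplyr::ungroup()
  kept <- res[res$r2 >= r2_min, ]
  removed <- res[res$r2 < r2_min, c("id", "r2")]
  list(adg = kept, removed = removed)
}

#' Dam parity class
#'
#' Collapses parity order into four classes: first parity, second parity,
#' third to seventh parity, and eighth or later.
#'
#' @param parity Integer vector of parity orders (>= 1).
#' @return Integer vector of classes in \{1, 2, 3, 4\}.
#' @export
#' @examples
#' parity_class(c(1, 2, 5, 9))
parity_class <- function(parity) {
  if (any(is.na(parity)) || any(parity < 1) || any(parity != round(parity))) {
    abort("`parity` must be integers >= 1.")
  }
  ifelse(parity == 1, 1L, ifelse(parity == 2, 2L, ifelse(parity <= 7, 3L, 4L)))
}

#' Full genotype quality-control pipeline
#'
#' Applies, in order: pre-imputation MAF filter, pre-imputation SNP call-rate
#' filter, Mendelian-conflict blanking (if a pedigree is given), imputation of
#' remaining missing calls with the supplied imputer, then the post-imputation
#' MAF, Hardy--Weinberg, SNP call-rate and animal call-rate filters.
#'
#' @param geno A [geno_data] object.
#' @param ped Optional pedigree for conflict detection and imputation.
#' @param thresholds A [qc_thresholds()].
#' @param imputer Imputation function, or `NULL` to skip imputation.
#' @return List with `geno` (clean, complete if imputed), `report` (tibble of
#'   per-step removals) and `conflicts`.
#' @export
run_geno_qc <- function(geno, ped = NULL, thresholds = qc_thresholds(),
                        imputer = impute_parent_average) {
  steps <- list()
  note <- function(step, n_snps_removed, n_animals_removed, g) {
    steps[[length(steps) + 1L]] <<- tibble::tibble(
      step = step, snps_removed = n_snps_removed,
      animals_removed = n_animals_removed,
      snps_left = ncol(geno_matrix(g)), animals_left = nrow(geno_matrix(g)))
  }
  f1 <- filter_maf(geno, thresholds$maf_pre)
  note("maf_pre", nrow(f1$removed), 0L, f1$geno)
  f2 <- filter_callrate(f1$geno, thresholds$callrate_snp_pre, 0)
  note("callrate_snp_pre", nrow(f2$removed_snps), nrow(f2$removed_animals), f2$geno)
  g <- f2$geno
  conflicts <- NULL
  if (!is.null(ped)) {
    conflicts <- detect_mendelian_conflicts(g, ped)
    g <- resolve_mendelian_conflicts(g, conflicts)
    note("mendelian_conflicts", 0L, 0L, g)
  }
  if (!is.null(imputer) && anyNA(geno_matrix(g))) {
    gi <- imputer(g, ped)
    # imputed dosages are rounded back to 0/1/2 calls for downstream filters
    gi <- pmin(pmax(round(gi), 0), 2)
    g <- geno_data(gi, snp_map(g))
    note("imputation", 0L, 0L, g)
  }
  f3 <- filter_maf(g, thresholds$maf_post)
  note("maf_post", nrow(f3$removed), 0L, f3$geno)
  f4 <- filter_hwe(f3$geno, thresholds$hwe_het_dev)
  note("hwe", nrow(f4$removed), 0L, f4$geno)
  f5 <- filter_callrate(f4$geno, thresholds$callrate_snp_post,
                        thresholds$callrate_animal)
  note("callrate_post", nrow(f5$removed_snps), nrow(f5$removed_animals), f5$geno)
  list(geno = f5$geno, report = dplyr::bind_rows(steps), conflicts = conflicts)
}
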