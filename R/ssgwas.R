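#' Back-solve breeding values into SNP allele-substitution effects
#'
#' Linear transformation of the genomic breeding values of the genotyped
#' animals into per-SNP effects:
#' `g_hat = lam * delta * (1 / (2 * sum(p q))) * M' G^-1 a22_hat`,
#' where `M` is the genotype matrix centred by twice the allele frequencies
#' and `G` the (blended, tuned) genomic relationship matrix.
#'
#' @param M Centred genotype matrix (animals x SNPs), e.g. `build_g()$M`.
#' @param denom The scaling constant `2 * sum(p_i (1 - p_i))`, e.g.
#'   `build_g()$denom`.
#' @param G Genomic relationship matrix used in the evaluation (same animal
#'   order as `M`).
#' @param a22_hat Breeding values of the genotyped animals (same order).
#' @param lam,delta Blending weight and tuning scalar entering the transform.
#' @return Named numeric vector of allele-substitution effects.
#' @export
backsolve_snp_effects <- function(M, denom, G, a22_hat, lam = 0.99,
                                  delta = 1) {
  Ginv_a <- tryCatch(solve(G, a22_hat), error = function(e) {
    abort("Singular G; blend with the identity before back-solving.")
  })
  drop(lam * delta / denom * crossprod(M, Ginv_a))
}

#' Prediction-error standard deviations of SNP effects
#'
#' Sampling standard deviation of each back-solved SNP effect:
#' `Var(g_hat) = (lam * delta / (2 sum pq))^2 * M' G^-1 (G sigma_a^2 - C22)
#' G^-1 M`, whose diagonal is returned as standard deviations. `C22` must be
#' the prediction-error (co)variance block of the genotyped animals on the
#' observation scale (as produced by [solve_mme()]), so that
#' `G sigma_a^2 - C22` is the (co)variance of the estimated breeding values.
#'
#' @inheritParams backsolve_snp_effects
#' @param C22 Inverse-coefficient-matrix block of the genotyped animals,
#'   scaled by the residual variance.
#' @param sigma_a2 Additive genetic variance.
#' @return Named numeric vector `sd(g_hat)`; tiny negative variances (above
#'   -1e-10 relative) are clipped to zero, larger ones raise an error.
#' @export
snp_effect_pev <- function(M, denom, G, C22, sigma_a2, lam = 0.99,
                           delta = 1) {
  W <- G * sigma_a2 - C22
  B <- solve(G, M)                # G^-1 M, animals x SNPs
  v <- colSums(B * (W %*% B)) * (lam * delta / denom)^2
  scale_ref <- max(abs(v), 1)
  if (any(v < -1e-10 * scale_ref)) {
    abort("Negative SNP-effect variance: C22 scale does not match G * sigma_a2.")
  }
  if (any(v < 0)) {
    inform(sprintf("%d tiny negative SNP-effect variance(s) clipped to 0.",
                   sum(v < 0)))
  }
  sqrt(pmax(v, 0))
}

#' Two-sided normal p-values for SNP effects
#'
#' `p_i = 2 * (1 - Phi(|g_hat_i / sd(g_hat_i)|))`. SNPs with zero standard
#' deviation are reported as `NA` (excluded from testing) with a message.
#'
#' @param g_hat,sd_g Effect estimates and their standard deviations.
#' @return Numeric vector of p-values in (0, 1], `NA` where `sd_g == 0`.
#' @export
snp_pvalues <- function(g_hat, sd_g) {
  if (length(g_hat) != length(sd_g)) abort("Lengths of g_hat and sd_g differ.")
  if (any(sd_g < 0)) abort("Negative standard deviations.")
  zero <- sd_g == 0
  if (any(zero)) {
    inform(sprintf("%d SNP(s) with zero PEV variance excluded from testing.",
                   sum(zero)))
  }
  p <- 2 * pnorm(abs(g_hat / sd_g), lower.tail = FALSE)
  p[zero] <- NA_real_
  p
}

#' Percentage of additive variance explained per SNP
#'
#' The genic-variance share `100 * 2 p_i (1 - p_i) g_hat_i^2 / sigma_a^2`.
#'
#' @param g_hat SNP allele-substitution effects.
#' @param p_freqs Allele frequencies (same order).
#' @param sigma_a2 Additive genetic variance (> 0).
#' @return Numeric vector of percentages.
#' @export
variance_explained <- function(g_hat, p_freqs, sigma_a2) {
  if (sigma_a2 <= 0) abort("`sigma_a2` must be positive.")
  100 * 2 * p_freqs * (1 - p_freqs) * g_hat^2 / sigma_a2
}

#' Effective number of independent tests
#'
#' Eigenvalue-based estimate from the SNP correlation matrix, computed per
#' chromosome (or per fixed-size block within chromosome) and summed:
#' each block contributes
#' `sum_i [ 1(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`, i.e. the
#' integral part of each eigenvalue counts one full test when at least 1 and
#' the non-integral part is added fractionally. Negative eigenvalues from a
#' non-positive-semidefinite correlation estimate are clipped at 0.
#'
#' @param x A [geno_data] object, or a SNP correlation matrix.
#' @param block_size Optional cap on the number of SNPs per eigendecomposed
#'   block within a chromosome.
#' @return Scalar `m_eff` with per-block detail in attribute `"blocks"`.
#' @export
effective_tests <- function(x, block_size = NULL) {
  meff_block <- function(cm) {
    lam <- eigen((cm + t(cm)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (any(lam < -1e-8)) {
      inform("Negative correlation eigenvalues clipped at 0.")
    }
    lam <- pmax(lam, 0)
    sum((lam >= 1) + (lam - floor(lam)))
  }
  if (is.matrix(x)) {
    m <- meff_block(x)
    attr(m, "blocks") <- tibble::tibble(chrom = NA_integer_, block = 1L,
                                        n_snps = ncol(x), m_eff = as.numeric(m))
    return(m)
  }
  g <- geno_matrix(x)
  map <- snp_map(x)
  blocks <- purrr::map_dfr(split(seq_len(nrow(map)), map$chrom), function(cols) {
    ok <- cols[apply(g[, cols, drop = FALSE], 2L,
                     function(z) sd(z, na.rm = TRUE) > 0)]
    if (!length(ok)) return(NULL)
    parts <- if (is.null(block_size)) list(ok) else {
      split(ok, ceiling(seq_along(ok) / block_size))
    }
    purrr::imap_dfr(parts, function(cc, bi) {
      cm <- suppressWarnings(cor(g[, cc, drop = FALSE],
                                 use = "pairwise.complete.obs"))
      cm[is.na(cm)] <- 0
      diag(cm) <- 1
      tibble::tibble(chrom = map$chrom[cc[1L]], block = as.integer(bi),
                     n_snps = length(cc), m_eff = meff_block(cm))
    })
  })
  out <- sum(blocks$m_eff)
  attr(out, "blocks") <- blocks
  out
}

#' Genome-wide significance thresholds from the effective test number
#'
#' The genome-wide threshold is the Bonferroni correction at the effective
#' number of independent tests, `-log10(alpha / m_eff)`; the suggestive
#' threshold is `1 / m_eff` (one expected false positive per genome scan).
#'
#' @param m_eff Effective number of independent tests (>= 1).
#' @param alpha Genome-wide type-I error rate.
#' @return List of class `gwas_thresholds`: `m_eff`, `alpha`,
#'   `significant_p`, `significant_logp`, `suggestive_p`, `suggestive_logp`.
#' @export
#' @examples
#' gwas_thresholds(17766)  # -log10(p) = 5.55, suggestive p = 5.629e-5
gwas_thresholds <- function(m_eff, alpha = 0.05) {
  if (m_eff < 1) abort("`m_eff` must be >= 1.")
  sig_p <- alpha / m_eff
  sug_p <- 1 / m_eff
  structure(list(m_eff = as.numeric(m_eff), alpha = alpha,
                 significant_p = sig_p, significant_logp = -log10(sig_p),
                 suggestive_p = sug_p, suggestive_logp = -log10(sug_p)),
            class = "gwas_thresholds")
}

#' @export
print.gwas_thresholds <- function(x, ...) {
  cat(sprintf("<gwas_thresholds> m_eff = %.1f, alpha = %g\n", x$m_eff, x$alpha))
  cat(sprintf("  significant: p <= %.4g (-log10 = %.2f)\n",
              x$significant_p, x$significant_logp))
  cat(sprintf("  suggestive:  p <= %.4g (-log10 = %.2f)\n",
              x$suggestive_p, x$suggestive_logp))
  invisible(x)
}

#' Genomic inflation factor (lambda_GC)
#'
#' Median-based inflation: each two-sided p-value is converted to a 1-df
#' chi-square quantile and the median is divided by the null median 0.45494.
#' Values near 1 indicate adequate control of population structure.
#'
#' @param p_values Vector of p-values in (0, 1]; `NA` dropped.
#' @return Scalar inflation factor.
#' @export
inflation_factor <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1].")
  if (length(p) < 100L) warn("Fewer than 100 p-values; inflation estimate unstable.")
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

#' Manhattan, QQ and hit tables for GWAS results
#'
#' Classifies every SNP against the thresholds (boundary values count as
#' hits), and builds the observed-vs-expected quantile table.
#'
#' @param results Tibble with columns `snp`, `chrom`, `pos_bp`, `p` (NA
#'   allowed for untested SNPs).
#' @param thresholds A [gwas_thresholds()].
#' @return List with `manhattan` (per-SNP tibble incl. `minus_log10_p` and
#'   `class` in significant/suggestive/none), `qq` (tibble observed vs
#'   expected -log10 p) and `hits` (classified SNPs sorted by p).
#' @export
gwas_tables <- function(results, thresholds) {
  man <- dplyr::mutate(
    results,
    minus_log10_p = -log10(.data$p),
    class = dplyr::case_when(
      is.na(.data$p) ~ "none",
      .data$p <= thresholds$significant_p ~ "significant",
      .data$p <= thresholds$suggestive_p ~ "suggestive",
      TRUE ~ "none"
    )
  )
  pobs <- sort(man$p[!is.na(man$p)])
  qq <- tibble::tibble(
    expected_logp = -log10((seq_along(pobs) - 0.5) / length(pobs)),
    observed_logp = -log10(pobs)
  )
  hits <- dplyr::arrange(dplyr::filter(man, .data$class != "none"), .data$p)
  list(manhattan = man, qq = qq, hits = hits)
}

#' Single-step GWAS from a solved model
#'
#' Chains the back-solve, prediction-error variances, p-values and variance
#' explained into one per-SNP results table.
#'
#' @param gmat A `g_matrix` from [build_g()] (provides `M`, `p`, `denom`).
#' @param G Genomic relationship matrix used in the evaluation (blended and
#'   tuned), same animal order as `gmat`.
#' @param solution An `mme_solution` from [solve_mme()] with `C22` for the
#'   genotyped animals.
#' @param map SNP map tibble (`snp`, `chrom`, `pos_bp`).
#' @param lam,delta Transform scalars (see [backsolve_snp_effects()]).
#' @return Tibble of class `ssgwas_result` with per-SNP effect, sd, p,
#'   -log10 p and percent variance explained.
#' @export
run_ssgwas <- function(gmat, G, solution, map, lam = 0.99, delta = 1) {
  stopifnot(inherits(gmat, "g_matrix"), inherits(solution, "mme_solution"))
  if (is.null(solution$C22)) abort("`solution` must carry C22 (pass c22_ids to solve_mme).")
  ids <- gmat$ids
  a22 <- solution$a$ebv[match(ids, solution$a$id)]
  g_hat <- backsolve_snp_effects(gmat$M, gmat$denom, G, a22, lam, delta)
  sd_g <- snp_effect_pev(gmat$M, gmat$denom, G, solution$C22[ids, ids],
                         solution$sigma_a2, lam, delta)
  p <- snp_pvalues(g_hat, sd_g)
  out <- dplyr::mutate(
    dplyr::select(map, "snp", "chrom", "pos_bp"),
    g_hat = unname(g_hat), sd_g = unname(sd_g), p = unname(p),
    minus_log10_p = -log10(.data$p),
    var_explained_pct = unname(
      variance_explained(g_hat, gmat$p, solution$sigma_a2))
  )
  class(out) <- c("ssgwas_result", class(out))
  out
}
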