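#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end driver: simulation
#' config, QC thresholds, model factors, blending/tuning settings, the
#' significance level, and stage toggles.
#'
#' @param sim A [sim_config()].
#' @param qc A [qc_thresholds()].
#' @param fixed Fixed-effect factor columns used in the model.
#' @param lam,beta Blending weights for [blend_g()].
#' @param tune Whether to tune G to A22 means before building H.
#' @param alpha Genome-wide significance level.
#' @param hd_fraction,ld_overlap_fraction Panel split used for the
#'   imputation cross-validation stage.
#' @param stages Character subset of
#'   `c("simulate", "qc", "kinship", "reml", "gwas")` to run.
#' @param out_dir Output directory (created; a seed-stamped subdirectory is
#'   used so outputs are never silently overwritten).
#' @param seed Master seed recorded in the manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), qc = qc_thresholds(),
                            fixed = c("contemporary_group", "parity_class",
                                      "birth_month"),
                            lam = 0.99, beta = 0.01, tune = TRUE,
                            alpha = 0.05,
                            hd_fraction = 0.5, ld_overlap_fraction = 0.6,
                            stages = c("simulate", "qc", "kinship", "reml",
                                       "gwas"),
                            out_dir = tempfile("ssgwas_run_"),
                            seed = sim$seed) {
  structure(list(sim = sim, qc = qc, fixed = fixed, lam = lam, beta = beta,
                 tune = tune, alpha = alpha, hd_fraction = hd_fraction,
                 ld_overlap_fraction = ld_overlap_fraction,
                 stages = stages, out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the end-to-end single-step GWAS pipeline
#'
#' Chains simulate -> QC -> kinship -> REML -> GWAS on synthetic herd data,
#' writing per-stage TSVs, a thresholds JSON and a run manifest (seed, config
#' hash) into a versioned output directory. Numeric columns are written at
#' fixed precision so identical configs reproduce byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  run_dir <- file.path(config$out_dir, paste0("run_seed", config$seed))
  if (dir.exists(run_dir)) {
    stamp <- format(Sys.time(), "%Y%m%d%H%M%S")
    run_dir <- paste0(run_dir, "_", stamp)
  }
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(out_dir = run_dir)
  wr <- function(x, name) {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], function(v) signif(v, 10))
    readr::write_tsv(x, file.path(run_dir, name))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }
  herd <- stage("simulate", simulate_herd(config$sim))
  res$herd <- herd
  if ("simulate" %in% config$stages) {
    wr(herd$pedigree, "pedigree.tsv")
    wr(herd$phenotypes, "phenotypes.tsv")
    wr(herd$truth$qtl, "truth_qtl.tsv")
  }
  geno <- herd$geno
  if ("qc" %in% config$stages) {
    qc <- stage("qc", run_geno_qc(geno, herd$pedigree, config$qc))
    wr(qc$report, "qc_report.tsv")
    geno <- qc$geno
    res$qc <- qc
    ms <- maf_summary(geno)
    wr(ms$chromosome, "maf_by_chromosome.tsv")
    ld <- compute_ld(geno, max_pairs_per_chrom = 50000L, seed = config$seed)
    wr(ld_decay_summary(ld), "ld_decay.tsv")
  }
  if (!any(c("kinship", "reml", "gwas") %in% config$stages)) {
    write_manifest(config, run_dir)
    return(invisible(res))
  }
  kin <- stage("kinship", {
    ped <- herd$pedigree
    geno_ids <- with_seed(config$seed + 11L, {
      sample(as.character(ped$id),
             max(2L, round(config$sim$prop_genotyped * nrow(ped))))
    })
    geno_ids <- sort(geno_ids)
    A <- build_a(ped)
    Ainv <- build_a_inverse(ped)
    A22 <- A[geno_ids, geno_ids]
    gm <- build_g(subset_geno(geno, animals = geno_ids))
    Gb <- blend_g(gm$G, config$lam, config$beta)
    tuned <- if (config$tune) tune_g_to_a22(Gb, A22) else
      list(G_adj = Gb, alpha = 0, gamma = 1, delta = 1)
    Hinv <- build_h_inverse(Ainv, A22, tuned$G_adj, geno_ids)
    list(A = A, Ainv = Ainv, A22 = A22, gmat = gm, G_adj = tuned$G_adj,
         delta = tuned$delta, Hinv = Hinv, geno_ids = geno_ids)
  })
  res$kinship <- kin
  if ("reml" %in% config$stages || "gwas" %in% config$stages) {
    H <- stage("kinship", solve(as.matrix(kin$Hinv)))
    dimnames(H) <- dimnames(kin$Hinv)
    vc <- stage("reml", ai_reml(herd$phenotypes, config$fixed, H))
    res$varcomp <- vc
    wr(tidy(vc), "varcomp.tsv")
    wr(glance(vc), "varcomp_summary.tsv")
    if ("gwas" %in% config$stages) {
      gw <- stage("gwas", {
        sol <- solve_mme(herd$phenotypes, config$fixed, kin$Hinv,
                         vc$sigma_a2, vc$sigma_e2, c22_ids = kin$geno_ids)
        run_ssgwas(kin$gmat, kin$G_adj, sol,
                   snp_map(subset_geno(geno,
                                       snps = intersect(snp_map(geno)$snp,
                                                        colnames(kin$gmat$M)))),
                   lam = config$lam, delta = kin$delta)
      })
      res$gwas <- gw
      meff <- effective_tests(subset_geno(geno, animals = kin$geno_ids))
      thr <- gwas_thresholds(as.numeric(meff), config$alpha)
      res$thresholds <- thr
      tabs <- gwas_tables(gw, thr)
      wr(tabs$manhattan, "gwas_manhattan.tsv")
      wr(tabs$qq, "gwas_qq.tsv")
      wr(tabs$hits, "gwas_hits.tsv")
      jsonlite::write_json(
        list(m_eff = as.numeric(meff), alpha = config$alpha,
             significant_logp = thr$significant_logp,
             suggestive_p = thr$suggestive_p,
             inflation = inflation_factor(gw$p)),
        file.path(run_dir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  write_manifest(config, run_dir)
  invisible(res)
}

write_manifest <- function(config, run_dir) {
  cfg_plain <- unclass(config)
  cfg_plain$sim <- unclass(cfg_plain$sim)
  cfg_plain$qc <- unclass(cfg_plain$qc)
  cfg_plain$out_dir <- NULL  # hash the analysis settings, not the destination
  jsonlite::write_json(
    list(seed = config$seed,
         config_hash = rlang::hash(cfg_plain),
         package_version = as.character(utils::packageVersion("ssgwasr")),
         stages = config$stages),
    file.path(run_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(NULL)
}
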