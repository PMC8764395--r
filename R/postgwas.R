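#' Map SNPs to genes within a window
#'
#' A SNP maps to every gene whose interval (1-based, inclusive) lies within
#' `window_bp` of its position; a SNP inside the interval has distance 0 and
#' is flagged `"within"`. All genes at the minimum distance are additionally
#' flagged as nearest (ties all reported).
#'
#' @param snps Tibble with `snp`, `chrom`, `pos_bp`.
#' @param annotation Tibble with `gene_id`, `chrom`, `start_bp`, `end_bp`
#'   (1-based inclusive; `strand` optional and informational).
#' @param window_bp Maximum gap between SNP and gene interval.
#' @return Tibble with `snp`, `chrom`, `pos_bp`, `gene_id`, `distance_bp`,
#'   `within`, `nearest`. SNPs on chromosomes absent from the annotation are
#'   skipped with a message.
#' @export
map_snps_to_genes <- function(snps, annotation, window_bp = 15000) {
  if (any(annotation$start_bp > annotation$end_bp)) {
    abort("Annotation has intervals with start > end.")
  }
  unknown <- setdiff(unique(snps$chrom), unique(annotation$chrom))
  if (length(unknown)) {
    inform(sprintf("SNPs on %d chromosome(s) absent from annotation skipped.",
                   length(unknown)))
  }
  ann_by_chrom <- split(annotation, annotation$chrom)
  res <- purrr::map_dfr(split(snps, snps$chrom), function(ss) {
    ann <- ann_by_chrom[[as.character(ss$chrom[1L])]]
    if (is.null(ann)) return(NULL)
    purrr::map_dfr(seq_len(nrow(ss)), function(i) {
      pos <- ss$pos_bp[i]
      gap <- ifelse(pos >= ann$start_bp & pos <= ann$end_bp, 0,
                    pmin(abs(pos - ann$start_bp), abs(pos - ann$end_bp)))
      keep <- which(gap <= window_bp)
      if (!length(keep)) return(NULL)
      tibble::tibble(snp = ss$snp[i], chrom = ss$chrom[i], pos_bp = pos,
                     gene_id = ann$gene_id[keep],
                     distance_bp = gap[keep],
                     within = gap[keep] == 0,
                     nearest = gap[keep] == min(gap[keep]))
    })
  })
  if (nrow(res) == 0L) {
    res <- tibble::tibble(snp = character(), chrom = integer(),
                          pos_bp = double(), gene_id = character(),
                          distance_bp = double(), within = logical(),
                          nearest = logical())
  }
  res
}

#' Select hit and background gene sets from GWAS results
#'
#' The background is every gene with at least one SNP within the mapping
#' window; the hits are genes with at least one SNP below the nominal
#' p-value, each gene counted once.
#'
#' @param gwas_results Tibble with `snp`, `chrom`, `pos_bp`, `p`.
#' @param annotation Gene annotation (see [map_snps_to_genes()]).
#' @param p_nominal Nominal p-value cut for hit SNPs.
#' @param window_bp SNP-to-gene mapping window.
#' @return List with `hit_genes`, `background_genes` (character vectors) and
#'   the full `mapping`.
#' @export
select_gene_hits <- function(gwas_results, annotation, p_nominal = 0.01,
                             window_bp = 15000) {
  mapping <- map_snps_to_genes(gwas_results, annotation, window_bp)
  if (nrow(mapping) == 0L) abort("Empty background: no SNP maps to any gene.")
  background <- sort(unique(mapping$gene_id))
  hit_snps <- gwas_results$snp[!is.na(gwas_results$p) &
                                 gwas_results$p < p_nominal]
  hits <- sort(unique(mapping$gene_id[mapping$snp %in% hit_snps]))
  list(hit_genes = hits, background_genes = background, mapping = mapping)
}

#' Benjamini--Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]).
#'
#' @param p_list Numeric p-values in [0, 1].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(p_list) {
  if (any(p_list < 0 | p_list > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_list, method = "BH")
}

#' Term enrichment of hit genes by hypergeometric test
#'
#' For each term, the one-sided hypergeometric tail probability of drawing at
#' least the observed overlap between hit genes and the term's background
#' members; Benjamini--Hochberg adjustment across tested terms. A term passes
#' the filters when adjusted p < `fdr`, overlap >= `min_genes`, and the
#' overlap covers at least `min_pct` percent of the term's genes present in
#' the background. Terms with no background member are skipped.
#'
#' @param hit_genes,background_genes Character vectors, hits a subset of the
#'   background.
#' @param terms Tibble with `term_id`, `gene_id` (long format; optional
#'   `term_name`).
#' @param fdr,min_genes,min_pct Filter thresholds.
#' @return Tibble: `term_id`, `n_background_in_term`, `n_hits_in_term`,
#'   `pct_of_term`, `raw_p`, `bh_fdr`, `passes_filters`, `overlap_genes`
#'   (list column).
#' @export
enrich <- function(hit_genes, background_genes, terms, fdr = 0.05,
                   min_genes = 3L, min_pct = 4.0) {
  if (!all(hit_genes %in% background_genes)) {
    abort("`hit_genes` must be a subset of `background_genes`.")
  }
  n_bg <- length(background_genes)
  n_hit <- length(hit_genes)
  by_term <- split(terms$gene_id, terms$term_id)
  res <- purrr::imap_dfr(by_term, function(genes, tid) {
    in_bg <- intersect(unique(genes), background_genes)
    if (!length(in_bg)) return(NULL)
    ov <- intersect(in_bg, hit_genes)
    k <- length(ov); K <- length(in_bg)
    raw_p <- phyper(k - 1, K, n_bg - K, n_hit, lower.tail = FALSE)
    tibble::tibble(term_id = tid, n_background_in_term = K,
                   n_hits_in_term = k,
                   pct_of_term = 100 * k / K,
                   raw_p = raw_p, overlap_genes = list(ov))
  })
  if (is.null(res) || nrow(res) == 0L) {
    inform("No term intersects the background; nothing tested.")
    return(tibble::tibble(term_id = character(),
                          n_background_in_term = integer(),
                          n_hits_in_term = integer(), pct_of_term = double(),
                          raw_p = double(), bh_fdr = double(),
                          passes_filters = logical(),
                          overlap_genes = list()))
  }
  res$bh_fdr <- bh_adjust(res$raw_p)
  res$passes_filters <- res$bh_fdr < fdr &
    res$n_hits_in_term >= min_genes &
    res$pct_of_term >= min_pct
  dplyr::relocate(dplyr::arrange(res, .data$raw_p), "overlap_genes",
                  .after = "passes_filters")
}

#' Overlap of candidate regions with QTL intervals
#'
#' A candidate region is the SNP position plus/minus `flank_bp`; an interval
#' overlaps when it shares at least one bp with the region (1-based inclusive
#' coordinates). Reports every overlap and the percentage share of each QTL
#' category among overlaps. Malformed intervals (start > end or missing
#' fields) are skipped with a message.
#'
#' @param candidate_snps Tibble with `snp`, `chrom`, `pos_bp`.
#' @param qtl_intervals Tibble with `chrom`, `start_bp`, `end_bp`, `category`
#'   (and optionally `qtl_id`).
#' @param flank_bp Half-width of the candidate region.
#' @return List with `overlaps` (one row per SNP x interval) and
#'   `category_share` (tibble: category, n, pct).
#' @export
region_qtl_overlap <- function(candidate_snps, qtl_intervals, flank_bp = 5e5) {
  bad <- is.na(qtl_intervals$start_bp) | is.na(qtl_intervals$end_bp) |
    qtl_intervals$start_bp > qtl_intervals$end_bp
  if (any(bad)) {
    inform(sprintf("%d malformed QTL interval(s) skipped.", sum(bad)))
    qtl_intervals <- qtl_intervals[!bad, , drop = FALSE]
  }
  ov <- purrr::map_dfr(seq_len(nrow(candidate_snps)), function(i) {
    lo <- candidate_snps$pos_bp[i] - flank_bp
    hi <- candidate_snps$pos_bp[i] + flank_bp
    q <- qtl_intervals[qtl_intervals$chrom == candidate_snps$chrom[i] &
                         qtl_intervals$end_bp >= lo &
                         qtl_intervals$start_bp <= hi, , drop = FALSE]
    if (!nrow(q)) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(snp = candidate_snps$snp[i],
                     region_start_bp = lo, region_end_bp = hi), q)
  })
  if (is.null(ov) || nrow(ov) == 0L) {
    return(list(overlaps = tibble::tibble(),
                category_share = tibble::tibble(category = character(),
                                                n = integer(), pct = double())))
  }
  share <- dplyr::count(ov, .data$category, name = "n") |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$pct))
  list(overlaps = ov, category_share = share)
}

#' Localized LD around a focal SNP
#'
#' r-squared between the focal SNP and every SNP within the window, with the
#' five-bin colour classification used for localized LD plots
#' (boundaries assigned to the lower class): `blue` < 0.2, `lightblue` < 0.4,
#' `green` < 0.6, `yellow` < 0.8, `red` > 0.8.
#'
#' @param geno A [geno_data] object.
#' @param focal_snp SNP id present in `geno`.
#' @param window_bp Half-width of the window (default 0.5 Mb).
#' @return Tibble: `snp`, `chrom`, `pos_bp`, `dist_bp`, `r2`, `ld_class`.
#'   Zero-variance SNPs are skipped.
#' @export
localized_ld <- function(geno, focal_snp, window_bp = 5e5) {
  g <- geno_matrix(geno)
  map <- snp_map(geno)
  fi <- match(focal_snp, map$snp)
  if (is.na(fi)) abort(sprintf("Focal SNP `%s` not found.", focal_snp))
  sel <- which(map$chrom == map$chrom[fi] &
                 abs(map$pos_bp - map$pos_bp[fi]) <= window_bp)
  x <- g[, fi]
  if (sd(x, na.rm = TRUE) == 0) abort("Focal SNP has zero variance.")
  keep <- sel[apply(g[, sel, drop = FALSE], 2L,
                    function(z) sd(z, na.rm = TRUE) > 0)]
  r2 <- vapply(keep, function(j) {
    suppressWarnings(cor(x, g[, j], use = "pairwise.complete.obs"))^2
  }, numeric(1))
  tibble::tibble(
    snp = map$snp[keep], chrom = map$chrom[keep], pos_bp = map$pos_bp[keep],
    dist_bp = abs(map$pos_bp[keep] - map$pos_bp[fi]),
    r2 = r2,
    ld_class = ld_class(r2)
  )
}

# five printed LD bins; boundary values fall in the lower class
ld_class <- function(r2) {
  cut(r2, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
      labels = c("blue", "lightblue", "green", "yellow", "red"),
      right = TRUE) |> as.character()
}
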