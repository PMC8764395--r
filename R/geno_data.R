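#' Genotype container
#'
#' A light container pairing an animals-by-SNPs dosage matrix (0/1/2 copies of
#' the alternate allele, `NA` for missing) with its SNP map (chromosome,
#' 1-based bp position, alleles). Row names of the matrix are animal ids,
#' column names the SNP ids, and the map rows follow the column order.
#'
#' @param geno Integer/numeric matrix, animals x SNPs, values in
#'   \{0, 1, 2, NA\}, with row and column names.
#' @param map Tibble with columns `snp`, `chrom`, `pos_bp` (and optionally
#'   `allele_ref`, `allele_alt`), one row per genotype column, same order.
#' @return An object of class `geno_data`.
#' @export
geno_data <- function(geno, map) {
  if (!is.matrix(geno) || is.null(rownames(geno)) || is.null(colnames(geno))) {
    abort("`geno` must be a matrix with animal row names and SNP column names.")
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0) || any(bad > 2))) {
    abort("Genotype dosages must be in {0, 1, 2} or NA.")
  }
  map <- tibble::as_tibble(map)
  req <- c("snp", "chrom", "pos_bp")
  if (!all(req %in% names(map))) {
    abort("`map` must have columns snp, chrom, pos_bp.")
  }
  if (nrow(map) != ncol(geno) || !identical(as.character(map$snp), colnames(geno))) {
    abort("`map` rows must match genotype columns (same SNPs, same order).")
  }
  structure(list(geno = geno, map = map), class = "geno_data")
}

#' @describeIn geno_data Extract the dosage matrix.
#' @param x A `geno_data` object.
#' @export
geno_matrix <- function(x) {
  stopifnot(inherits(x, "geno_data"))
  x$geno
}

#' @describeIn geno_data Extract the SNP map tibble.
#' @export
snp_map <- function(x) {
  stopifnot(inherits(x, "geno_data"))
  x$map
}

#' @describeIn geno_data Subset by animal ids and/or SNP ids.
#' @param animals,snps Character vectors of ids to keep (NULL = all).
#' @export
subset_geno <- function(x, animals = NULL, snps = NULL) {
  g <- geno_matrix(x)
  map <- snp_map(x)
  if (!is.null(animals)) g <- g[animals, , drop = FALSE]
  if (!is.null(snps)) {
    g <- g[, snps, drop = FALSE]
    map <- map[match(snps, map$snp), ]
  }
  geno_data(g, map)
}

#' @export
print.geno_data <- function(x, ...) {
  g <- geno_matrix(x)
  cat(sprintf("<geno_data> %d animals x %d SNPs on %d chromosome(s); %.2f%% missing\n",
              nrow(g), ncol(g), dplyr::n_distinct(snp_map(x)$chrom),
              100 * mean(is.na(g))))
  invisible(x)
}

# Per-SNP alternate-allele frequency over non-missing calls; all-missing -> NA.
allele_freq <- function(geno) {
  g <- if (inherits(geno, "geno_data")) geno_matrix(geno) else geno
  colMeans(g, na.rm = TRUE) / 2
}
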