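#' Read and write pedigree CSV
#'
#' The file has a header and columns `id,sire,dam,sex,birth_month,dam_parity`
#' (0 or blank = unknown parent). On reading, the pedigree is reordered
#' topologically if needed; a cyclic pedigree raises an error listing one
#' cycle.
#'
#' @param ped Pedigree tibble.
#' @param path File path.
#' @return `read_pedigree_csv()` returns the ordered pedigree tibble.
#' @export
write_pedigree_csv <- function(ped, path) {
  readr::write_csv(ped, path)
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  ped <- readr::read_csv(path, show_col_types = FALSE)
  ped$sire[is.na(ped$sire)] <- 0L
  ped$dam[is.na(ped$dam)] <- 0L
  order_pedigree(ped)
}

#' Topologically order a pedigree
#'
#' Kahn's algorithm; parents are placed before offspring. Cycles raise an
#' error naming the animals involved.
#'
#' @param ped Pedigree tibble with `id`, `sire`, `dam`.
#' @return The reordered tibble.
#' @export
order_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), as.character(ped$id))
  parent_of <- function(p) ifelse(p == 0L, NA_integer_, idx[as.character(p)])
  si <- parent_of(ped$sire); di <- parent_of(ped$dam)
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    cyc <- setdiff(seq_len(n), out)
    abort(paste0("Pedigree contains a cycle involving animals: ",
                 paste(ped$id[cyc], collapse = ", ")))
  }
  ped[out, , drop = FALSE]
}

#' Read and write phenotype CSV
#'
#' Rows whose fixed-effect factors are missing are excluded with a message.
#'
#' @param pheno Phenotype tibble.
#' @param path File path.
#' @param factors Factor columns checked for missingness on read.
#' @return `read_phenotypes_csv()` returns the phenotype tibble.
#' @export
write_phenotypes_csv <- function(pheno, path) {
  readr::write_csv(pheno, path)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path, factors = c("contemporary_group",
                                                  "parity_class",
                                                  "birth_month")) {
  ph <- readr::read_csv(path, show_col_types = FALSE)
  factors <- intersect(factors, names(ph))
  if (length(factors)) {
    bad <- !complete.cases(ph[, factors])
    if (any(bad)) {
      inform(sprintf("%d row(s) with missing factor levels excluded.", sum(bad)))
      ph <- ph[!bad, , drop = FALSE]
    }
  }
  ph
}

#' Write and read genotypes as PLINK-style .ped/.map text files
#'
#' The .map file has columns chromosome, SNP id, genetic distance (0) and
#' 1-based bp position. The .ped file has the six standard leading columns
#' (family, individual, sire, dam, sex, phenotype; unknown written as 0/-9)
#' followed by two allele characters per SNP; missing calls are written
#' `0 0`.
#'
#' @param geno A [geno_data] object.
#' @param prefix Path prefix; `.ped` and `.map` are appended.
#' @return `read_plink()` returns a `geno_data`; alleles are recoded to
#'   0/1/2 dosages of the alternate allele.
#' @export
write_plink <- function(geno, prefix) {
  g <- geno_matrix(geno)
  map <- snp_map(geno)
  readr::write_tsv(
    tibble::tibble(chrom = map$chrom, snp = map$snp, cm = 0,
                   pos_bp = map$pos_bp),
    paste0(prefix, ".map"), col_names = FALSE)
  ref <- if ("allele_ref" %in% names(map)) map$allele_ref else rep("A", nrow(map))
  alt <- if ("allele_alt" %in% names(map)) map$allele_alt else rep("B", nrow(map))
  lines <- vapply(seq_len(nrow(g)), function(i) {
    al <- character(2L * ncol(g))
    for (j in seq_len(ncol(g))) {
      v <- g[i, j]
      pair <- if (is.na(v)) c("0", "0")
      else if (v == 0) c(ref[j], ref[j])
      else if (v == 1) c(ref[j], alt[j])
      else c(alt[j], alt[j])
      al[c(2L * j - 1L, 2L * j)] <- pair
    }
    paste(c("0", rownames(g)[i], "0", "0", "0", "-9", al), collapse = " ")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  map_raw <- readr::read_tsv(paste0(prefix, ".map"), col_names = FALSE,
                             show_col_types = FALSE)
  map <- tibble::tibble(snp = as.character(map_raw[[2]]),
                        chrom = map_raw[[1]], pos_bp = map_raw[[4]])
  lines <- readLines(paste0(prefix, ".ped"))
  m <- nrow(map)
  rows <- lapply(seq_along(lines), function(li) {
    f <- strsplit(trimws(lines[li]), "\\s+")[[1]]
    if (length(f) != 6L + 2L * m) {
      abort(sprintf("Line %d of .ped has %d fields; expected %d.",
                    li, length(f), 6L + 2L * m))
    }
    f
  })
  ids <- vapply(rows, function(f) f[2L], character(1))
  alleles <- lapply(rows, function(f) f[-(1:6)])
  # alternate allele = second distinct non-missing allele per SNP (alphabetic)
  geno <- matrix(NA_integer_, length(rows), m,
                 dimnames = list(ids, map$snp))
  a1 <- do.call(rbind, lapply(alleles, function(a) a[seq(1L, 2L * m, 2L)]))
  a2 <- do.call(rbind, lapply(alleles, function(a) a[seq(2L, 2L * m, 2L)]))
  ref <- character(m); alt <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    obs <- sort(unique(obs[obs != "0"]))
    if (length(obs) > 2L) {
      abort(sprintf("SNP %s has more than two alleles.", map$snp[j]))
    }
    ref[j] <- if (length(obs)) obs[1L] else "A"
    alt[j] <- if (length(obs) == 2L) obs[2L] else "B"
    miss <- a1[, j] == "0" | a2[, j] == "0"
    geno[, j] <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
    geno[miss, j] <- NA_integer_
  }
  map$allele_ref <- ref
  map$allele_alt <- alt
  geno_data(geno, map)
}

#' Write and read genotypes as a dense TSV
#'
#' Tab-separated with a header row: first column `id`, then one column per
#' SNP holding 0/1/2 dosages with `NA` for missing. The SNP map is written
#' alongside with suffix `.map.tsv`.
#'
#' @param geno A [geno_data] object.
#' @param path Path of the genotype TSV.
#' @return `read_geno_tsv()` returns a `geno_data`.
#' @export
write_geno_tsv <- function(geno, path) {
  g <- geno_matrix(geno)
  tb <- dplyr::bind_cols(tibble::tibble(id = rownames(g)),
                         tibble::as_tibble(g))
  readr::write_tsv(tb, path)
  readr::write_tsv(snp_map(geno), paste0(path, ".map.tsv"))
  invisible(path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  map <- readr::read_tsv(paste0(path, ".map.tsv"), show_col_types = FALSE)
  g <- as.matrix(tb[, -1, drop = FALSE])
  rownames(g) <- as.character(tb$id)
  geno_data(g, map)
}

#' Write the simulation truth to TSV
#'
#' @param truth Truth list from [simulate_phenotypes()].
#' @param path File path.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth$qtl, path)
  readr::write_tsv(truth$breeding_values, paste0(path, ".bv.tsv"))
  invisible(path)
}
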