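#' Biallelic diploid genotype matrix
#'
#' The central container of the pipeline: one row per retained site, one
#' column per sample, entries counting alternate alleles (0, 1, 2) with
#' `NA` for missing genotypes. Invariant ("all sites" VCF) records are kept
#' with `alt = NA` so that windowed diversity statistics have honest
#' denominators.
#'
#' @param scaffold character vector of scaffold names, one per site.
#' @param pos integer vector of 1-based site positions (VCF convention);
#'   must be strictly increasing within each scaffold.
#' @param geno integer matrix (sites x samples) of alternate-allele counts
#'   in \{0, 1, 2\}, `NA` = missing. Column names are the sample ids.
#' @param ref,alt single-base reference/alternate alleles per site; `alt`
#'   is `NA` at invariant sites.
#' @param validate check invariants (default TRUE).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(scaffold, pos, geno, ref = NULL, alt = NULL,
                            validate = TRUE) {
  geno <- as.matrix(geno)
  n <- length(pos)
  if (length(scaffold) == 1 && n > 1) scaffold <- rep(scaffold, n)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("T", n)
  stop_if(is.null(colnames(geno)), "geno must have sample ids as colnames")
  gm <- structure(list(
    scaffold = as.character(scaffold),
    pos      = as.integer(pos),
    geno     = geno,
    ref      = as.character(ref),
    alt      = as.character(alt),
    samples  = colnames(geno)
  ), class = "genotype_matrix")
  if (validate) validate_genotype_matrix(gm)
  gm
}

validate_genotype_matrix <- function(gm) {
  n <- length(gm$pos)
  stop_if(length(gm$scaffold) != n || nrow(gm$geno) != n ||
            length(gm$ref) != n || length(gm$alt) != n,
          "genotype_matrix fields have inconsistent lengths")
  stop_if(ncol(gm$geno) != length(gm$samples),
          "genotype column count does not match sample ids")
  bad <- !(gm$geno %in% c(0L, 1L, 2L, NA))
  stop_if(any(bad), "genotypes must be 0, 1, 2 or NA")
  for (s in unique(gm$scaffold)) {
    p <- gm$pos[gm$scaffold == s]
    stop_if(any(diff(p) <= 0),
            "positions not strictly increasing on scaffold ", s)
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$pos), "sites x", length(x$samples),
      "samples on", length(unique(x$scaffold)), "scaffold(s)\n")
  nv <- sum(!is.na(x$alt))
  cat("  variant sites:", nv, " invariant:", length(x$pos) - nv,
      " missing genotypes:", sum(is.na(x$geno)), "\n")
  invisible(x)
}

#' Subset a genotype matrix by site index
#' @param gm a `genotype_matrix`.
#' @param i integer site indices (rows), kept in the given order.
#' @return a `genotype_matrix` with the selected sites.
#' @export
subset_sites <- function(gm, i) {
  genotype_matrix(gm$scaffold[i], gm$pos[i],
                  gm$geno[i, , drop = FALSE],
                  gm$ref[i], gm$alt[i], validate = FALSE)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$pos), length(x$samples))

#' Row indices of variable (SNP) sites
#'
#' A site counts as a SNP when it carries a called alternate allele and is
#' polymorphic among the non-missing genotypes.
#' @param gm a `genotype_matrix`.
#' @return integer vector of row indices.
#' @export
snp_sites <- function(gm) {
  cnt <- rowSums(gm$geno, na.rm = TRUE)
  nal <- 2L * rowSums(!is.na(gm$geno))
  which(!is.na(gm$alt) & cnt > 0 & cnt < nal)
}

#' Population alternate-allele frequencies
#'
#' @param gm a `genotype_matrix`.
#' @param samples character vector of sample ids forming the population.
#' @param sites optional integer row indices (default: all sites).
#' @return list with `p` (alt frequency, NA when no data), `n` (non-missing
#'   allele count) and `c` (alt allele count), each one value per site.
#' @export
pop_allele_freq <- function(gm, samples, sites = NULL) {
  miss <- setdiff(samples, gm$samples)
  stop_if(length(miss) > 0, "unknown samples: ", paste(miss, collapse = ", "))
  g <- gm$geno[, samples, drop = FALSE]
  if (!is.null(sites)) g <- g[sites, , drop = FALSE]
  cnt <- rowSums(g, na.rm = TRUE)
  n <- 2L * rowSums(!is.na(g))
  list(p = ifelse(n > 0, cnt / n, NA_real_), n = n, c = cnt)
}

#' Read a two-column sample-to-population map
#'
#' @param path TSV with columns sample and population (no header required;
#'   a header line `sample<TAB>population` is tolerated).
#' @return named character vector: population keyed by sample id.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("sample", "population"),
                          stringsAsFactors = FALSE)
  if (nrow(df) > 0 && identical(tolower(df$sample[1]), "sample"))
    df <- df[-1, , drop = FALSE]
  stats::setNames(df$population, df$sample)
}

#' Samples belonging to a population
#' @param popmap named character vector from [read_popmap()].
#' @param pop population label.
#' @return character vector of sample ids.
#' @export
pop_samples <- function(popmap, pop) {
  out <- names(popmap)[popmap == pop]
  stop_if(length(out) == 0, "unknown population: ", pop)
  out
}
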