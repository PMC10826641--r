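# Independent oracles and fixture builders used across the test files.

# expand a diploid genotype into its allele vector (0 = ref, 1 = alt)
expand_alleles <- function(g) {
  if (is.na(g)) return(integer(0))
  c(rep(1L, g), rep(0L, 2L - g))
}

# naive all-pairs pi: enumerate every allele pair explicitly, per site
naive_pi <- function(gm, samples, sites = seq_along(gm$pos)) {
  td <- 0; tc <- 0
  for (i in sites) {
    al <- unlist(lapply(gm$geno[i, samples], expand_alleles))
    if (length(al) >= 2) {
      prs <- utils::combn(length(al), 2)
      td <- td + sum(al[prs[1, ]] != al[prs[2, ]])
      tc <- tc + ncol(prs)
    }
  }
  if (tc == 0) NA_real_ else td / tc
}

# naive all-pairs dxy: every between-population allele pair
naive_dxy <- function(gm, samplesA, samplesB, sites = seq_along(gm$pos)) {
  td <- 0; tc <- 0
  for (i in sites) {
    a <- unlist(lapply(gm$geno[i, samplesA], expand_alleles))
    b <- unlist(lapply(gm$geno[i, samplesB], expand_alleles))
    for (x in a) for (y in b) { td <- td + (x != y); tc <- tc + 1 }
  }
  if (tc == 0) NA_real_ else td / tc
}

# random genotype matrix with missingness
rand_gm <- function(n_sites = 50, n_samples = 8, miss = 0.2, seed = 1) {
  set.seed(seed)
  g <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
              n_sites, n_samples)
  g[matrix(stats::runif(n_sites * n_samples) < miss,
           n_sites, n_samples)] <- NA
  colnames(g) <- paste0("s", seq_len(n_samples))
  genotype_matrix(rep("scaf1", n_sites), seq_len(n_sites), g,
                  alt = rep("T", n_sites))
}

# build a genotype matrix realising given per-population frequencies,
# one diploid per population (freq 0 / 0.5 / 1 -> genotype 0 / 1 / 2)
freq_gm <- function(freq_rows, pops = c("P1", "P2", "P3", "O")) {
  g <- t(vapply(freq_rows, function(r) as.integer(round(2 * r)),
                integer(length(pops))))
  colnames(g) <- paste0(tolower(pops), "_1")
  genotype_matrix(rep("s1", length(freq_rows)), seq_along(freq_rows), g,
                  alt = rep("T", length(freq_rows)))
}

freq_popmap <- function(pops = c("P1", "P2", "P3", "O"))
  stats::setNames(pops, paste0(tolower(pops), "_1"))

# write a toy VCF with GT:DP genotypes and per-record INFO DP
write_toy_vcf <- function(path, records, samples) {
  header <- c("##fileformat=VCFv4.2",
              '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">',
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
              '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_rec <- function(pos, ref, alt, qual, site_dp, gts, dps,
                    chrom = "scaf1") {
  paste(c(chrom, pos, ".", ref, alt, qual, "PASS",
          paste0("DP=", site_dp), "GT:DP",
          paste0(gts, ":", dps)), collapse = "\t")
}

# random binary unrooted-testable tree over given labels
rand_tree <- function(labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(length(labels))
  tr$tip.label <- sample(labels)
  tr
}
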