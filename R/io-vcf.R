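#' Soft-filter configuration for VCF import
#'
#' Thresholds follow common practice for medium-coverage resequencing:
#' sites below the quality threshold are converted to invariant reference
#' (not discarded), depth failures produce missing genotypes, and sites
#' with too much missing data are dropped.
#'
#' @param min_site_quality minimum phred-scaled site QUAL (default 20).
#' @param min_site_depth,max_site_depth bounds on site-level total read
#'   depth (defaults 3 and 60).
#' @param min_genotype_depth minimum per-genotype read depth (default 2).
#' @param max_site_missingness maximum tolerated fraction of missing
#'   genotypes per site (default 0.5); sites above it are dropped.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_site_quality = 20,
                          min_site_depth = 3, max_site_depth = 60,
                          min_genotype_depth = 2,
                          max_site_missingness = 0.5) {
  stop_if(min_site_depth > max_site_depth,
          "min_site_depth must not exceed max_site_depth")
  stop_if(max_site_missingness < 0 || max_site_missingness > 1,
          "max_site_missingness must lie in [0, 1]")
  structure(list(min_site_quality = min_site_quality,
                 min_site_depth = min_site_depth,
                 max_site_depth = max_site_depth,
                 min_genotype_depth = min_genotype_depth,
                 max_site_missingness = max_site_missingness),
            class = "filter_config")
}

gt_to_count <- function(gt) {
  # "0/1", "0|1", ".", "./." -> alt allele count or NA
  gt <- sub(":.*", "", gt)
  out <- rep(NA_integer_, length(gt))
  known <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "0|1" = 1L,
             "1/0" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L,
             "0" = 0L, "1" = 1L)
  hit <- gt %in% names(known)
  out[hit] <- known[gt[hit]]
  out
}

#' Read a multi-sample VCF into a filtered genotype matrix
#'
#' Applies the soft filters in order quality -> depth -> missingness:
#' (a) records failing the site-quality threshold are converted to
#' invariant reference (all genotypes 0); (b) genotypes below the
#' per-genotype depth, and all genotypes of sites whose total depth falls
#' outside the site-depth bounds, are set missing; (c) sites whose missing
#' fraction exceeds the threshold are dropped. Non-biallelic and non-SNP
#' records are dropped up front. Invariant records (ALT ".") from an
#' "all sites" VCF are retained so window denominators count them.
#'
#' If the file carries no QUAL or no depth annotations the corresponding
#' filter is skipped with a warning.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param filters a [filter_config()].
#' @param quality_mode apply the quality threshold to site QUAL
#'   (`"site"`, default) or per-genotype GQ (`"genotype"`, which sets
#'   failing genotypes missing instead of converting the site).
#' @return a [genotype_matrix()] with attribute `filter_log`, a named
#'   integer vector accounting for every input record.
#' @export
read_vcf <- function(path, filters = filter_config(),
                     quality_mode = c("site", "genotype")) {
  quality_mode <- match.arg(quality_mode)
  stop_if(!file.exists(path), "cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  n_in <- nrow(fix)
  log <- c(n_input = n_in, n_multiallelic = 0L, n_non_snp = 0L,
           n_qual_converted = 0L, n_geno_missing_depth = 0L,
           n_dropped_missingness = 0L, n_retained = 0L)
  if (n_in == 0) {
    stop("VCF contains no records: ", path, call. = FALSE)
  }

  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  invariant <- is.na(alt) | alt == "." | alt == ""
  multi <- !invariant & grepl(",", alt)
  nonsnp <- !invariant & !multi & (nchar(ref) != 1 | nchar(alt) != 1)
  keep <- !multi & !nonsnp
  log["n_multiallelic"] <- sum(multi)
  log["n_non_snp"] <- sum(nonsnp)

  gt_chr <- vcfR::extract.gt(v, element = "GT")
  stop_if(is.null(gt_chr), "VCF has no GT field: ", path)
  geno <- matrix(gt_to_count(gt_chr), nrow = nrow(gt_chr),
                 dimnames = dimnames(gt_chr))

  fix <- fix[keep, , drop = FALSE]
  geno <- geno[keep, , drop = FALSE]
  invariant <- invariant[keep]
  scaffold <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- ifelse(invariant, NA_character_, fix[, "ALT"])

  # --- quality filter ---
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  if (quality_mode == "site") {
    if (all(is.na(qual))) {
      warning("VCF has no QUAL values; site-quality filter skipped")
    } else {
      fail <- !is.na(qual) & qual < filters$min_site_quality & !invariant
      if (any(fail)) {
        geno[fail, ] <- 0L           # converted to invariant reference
        alt[fail] <- NA_character_
        invariant[fail] <- TRUE
        log["n_qual_converted"] <- sum(fail)
      }
    }
  } else {
    gq <- tryCatch(
      suppressWarnings(vcfR::extract.gt(v, element = "GQ",
                                        as.numeric = TRUE)[keep, ,
                                                           drop = FALSE]),
      error = function(e) NULL)
    if (is.null(gq)) {
      warning("VCF has no GQ values; genotype-quality filter skipped")
    } else {
      fail <- !is.na(gq) & gq < filters$min_site_quality
      geno[fail] <- NA_integer_
    }
  }

  # --- depth filters ---
  dp <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                      as.numeric = TRUE)[keep, ,
                                                         drop = FALSE]),
    error = function(e) NULL)
  if (!is.null(dp) && all(is.na(dp))) dp <- NULL
  qual_converted <- invariant & !is.na(qual) &
    qual < filters$min_site_quality
  if (is.null(dp)) {
    warning("VCF has no per-genotype DP; depth filters skipped")
  } else {
    fail_gt <- !is.na(dp) & dp < filters$min_genotype_depth
    site_dp <- vcfR::extract.info(v, element = "DP", as.numeric = TRUE)[keep]
    if (all(is.na(site_dp))) site_dp <- rowSums(dp, na.rm = TRUE)
    fail_site <- !is.na(site_dp) &
      (site_dp < filters$min_site_depth | site_dp > filters$max_site_depth)
    # quality-converted sites are already invariant reference; the stated
    # rule only sends non-converted sites to missing
    fail_gt[qual_converted, ] <- FALSE
    fail_site[qual_converted] <- FALSE
    before <- sum(is.na(geno))
    geno[fail_gt] <- NA_integer_
    geno[fail_site, ] <- NA_integer_
    log["n_geno_missing_depth"] <- sum(is.na(geno)) - before
  }

  # --- missingness filter ---
  miss_frac <- rowMeans(is.na(geno))
  drop <- miss_frac > filters$max_site_missingness
  log["n_dropped_missingness"] <- sum(drop)
  keep2 <- !drop

  ord <- order(scaffold[keep2], pos[keep2])
  idx <- which(keep2)[ord]
  gm <- genotype_matrix(scaffold[idx], pos[idx], geno[idx, , drop = FALSE],
                        ref[idx], alt[idx])
  log["n_retained"] <- length(idx)
  attr(gm, "filter_log") <- log
  gm
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits GT-only records (DP omitted); re-reading with permissive filters
#' reproduces the genotypes exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param qual QUAL value written for every record (default 99).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, qual = 99) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", gm$samples),
                     collapse = "\t")), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$geno + 1L], nrow = nrow(gm$geno))
  gt_str[is.na(gm$geno)] <- "./."
  alt <- ifelse(is.na(gm$alt), ".", gm$alt)
  rows <- paste(gm$scaffold, gm$pos, ".", gm$ref, alt, qual, "PASS", ".",
                "GT", apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(rows, con)
  invisible(path)
}
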