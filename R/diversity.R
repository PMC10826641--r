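# Missing-data-aware windowed diversity statistics.
#
# pi and dxy use ratio-of-sums aggregation: allele-pair differences and
# allele-pair comparisons are summed over sites first and divided once per
# window, so sites with missing genotypes contribute exactly the
# comparisons they support and invariant sites contribute comparisons
# only. FST aggregates Weir-Cockerham variance components the same way.

sites_in_window <- function(gm, window) {
  if (!is.null(window$snp_from) && !is.na(window$snp_from %||% NA))
    return(seq(window$snp_from, window$snp_to))
  which(gm$scaffold == window$scaffold &
          gm$pos - 1L >= window$start & gm$pos - 1L < window$end)
}

diversity_record <- function(window, pops, sum_diffs, sum_comparisons,
                             sum_missing, value, stat) {
  structure(list(window = window, pops = pops, sum_diffs = sum_diffs,
                 sum_comparisons = sum_comparisons,
                 sum_missing = sum_missing, value = value, stat = stat),
            class = "diversity_record")
}

#' @export
print.diversity_record <- function(x, ...) {
  cat(sprintf("%s[%s] %s:%d-%d = %s (diffs %s / comparisons %s)\n",
              x$stat, paste(x$pops, collapse = ","),
              x$window$scaffold %||% "?", x$window$start %||% NA,
              x$window$end %||% NA, format(x$value),
              format(x$sum_diffs), format(x$sum_comparisons)))
  invisible(x)
}

#' Nucleotide diversity (pi) in a window
#'
#' Per site with n non-missing alleles and alternate count c in the
#' population: differences `c(n-c)`, comparisons `n(n-1)/2`. The window
#' value is the ratio of the two sums; `NA` when no comparisons exist.
#'
#' @param gm a [genotype_matrix()].
#' @param window one row of a window table (list or data.frame row with
#'   scaffold/start/end or snp_from/snp_to).
#' @param popmap named population vector (see [read_popmap()]).
#' @param pop population label.
#' @return a `diversity_record`.
#' @export
pi_window <- function(gm, window, popmap, pop) {
  samples <- pop_samples(popmap, pop)
  idx <- sites_in_window(gm, window)
  af <- pop_allele_freq(gm, samples, idx)
  n <- af$n; c_ <- af$c
  diffs <- c_ * (n - c_)
  comps <- n * (n - 1) / 2
  n_max <- 2 * length(samples)
  missing <- n_max * (n_max - 1) / 2 * length(idx) - sum(comps)
  value <- if (sum(comps) > 0) sum(diffs) / sum(comps) else NA_real_
  diversity_record(as.list(window), pop, sum(diffs), sum(comps),
                   missing, value, "pi")
}

#' Absolute divergence (dxy) in a window
#'
#' Per site: differences `cA(nB-cB) + (nA-cA)cB`, comparisons `nA*nB`
#' over non-missing alleles; ratio of sums per window.
#'
#' @inheritParams pi_window
#' @param popA,popB distinct population labels.
#' @return a `diversity_record`.
#' @export
dxy_window <- function(gm, window, popmap, popA, popB) {
  stop_if(popA == popB, "popA and popB must differ (use pi_window within)")
  sA <- pop_samples(popmap, popA); sB <- pop_samples(popmap, popB)
  idx <- sites_in_window(gm, window)
  a <- pop_allele_freq(gm, sA, idx); b <- pop_allele_freq(gm, sB, idx)
  diffs <- a$c * (b$n - b$c) + (a$n - a$c) * b$c
  comps <- a$n * b$n
  missing <- (2 * length(sA)) * (2 * length(sB)) * length(idx) - sum(comps)
  value <- if (sum(comps) > 0) sum(diffs) / sum(comps) else NA_real_
  diversity_record(as.list(window), c(popA, popB), sum(diffs), sum(comps),
                   missing, value, "dxy")
}

# Weir & Cockerham (1984) two-population variance components per site,
# allele-frequency form with observed heterozygosity from genotypes.
wc_components <- function(gm, idx, sA, sB) {
  gA <- gm$geno[idx, sA, drop = FALSE]
  gB <- gm$geno[idx, sB, drop = FALSE]
  nA <- rowSums(!is.na(gA)); nB <- rowSums(!is.na(gB))   # diploids
  ok <- nA >= 1 & nB >= 1 & (nA + nB) >= 2
  pA <- rowSums(gA, na.rm = TRUE) / (2 * nA)
  pB <- rowSums(gB, na.rm = TRUE) / (2 * nB)
  hA <- rowSums(gA == 1L, na.rm = TRUE) / nA
  hB <- rowSums(gB == 1L, na.rm = TRUE) / nB
  r <- 2
  nbar <- (nA + nB) / r
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  use <- ok & poly & nbar > 1 & nc > 0 & !is.na(a)
  list(a = a[use], b = b[use], c = cc[use])
}

#' Weir-Cockerham FST in a window
#'
#' Ratio of summed variance components: `sum(a) / sum(a + b + c)`;
#' per-site FST values are never averaged. The estimator may be negative;
#' `NA` when no site contributes.
#'
#' @inheritParams dxy_window
#' @return a `diversity_record`.
#' @export
fst_window <- function(gm, window, popmap, popA, popB) {
  stop_if(popA == popB, "popA and popB must differ")
  sA <- pop_samples(popmap, popA); sB <- pop_samples(popmap, popB)
  idx <- sites_in_window(gm, window)
  comp <- wc_components(gm, idx, sA, sB)
  denom <- sum(comp$a + comp$b + comp$c)
  value <- if (length(comp$a) > 0 && denom != 0) sum(comp$a) / denom
           else NA_real_
  diversity_record(as.list(window), c(popA, popB), sum(comp$a), denom,
                   NA_real_, value, "fst")
}

#' Windowed diversity table
#'
#' Convenience wrapper computing pi for each population and dxy/FST for
#' each population pair over a window table.
#'
#' @param gm a [genotype_matrix()].
#' @param windows window data.frame ([bp_windows()] or [snp_windows()]).
#' @param popmap named population vector.
#' @param pops populations to include (default: all in `popmap`).
#' @return data.frame: stat, pop1, pop2, scaffold, start, end, value,
#'   sum_diffs, sum_comparisons, sum_missing.
#' @export
windowed_diversity <- function(gm, windows, popmap,
                               pops = unique(unname(popmap))) {
  rows <- list()
  pairs <- if (length(pops) > 1) utils::combn(sort(pops), 2) else NULL
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    for (p in pops) {
      r <- pi_window(gm, w, popmap, p)
      rows[[length(rows) + 1L]] <- data.frame(
        stat = "pi", pop1 = p, pop2 = NA, scaffold = w$scaffold,
        start = w$start, end = w$end, value = r$value,
        sum_diffs = r$sum_diffs, sum_comparisons = r$sum_comparisons,
        sum_missing = r$sum_missing, stringsAsFactors = FALSE)
    }
    if (!is.null(pairs)) for (j in seq_len(ncol(pairs))) {
      r <- dxy_window(gm, w, popmap, pairs[1, j], pairs[2, j])
      f <- fst_window(gm, w, popmap, pairs[1, j], pairs[2, j])
      rows[[length(rows) + 1L]] <- data.frame(
        stat = "dxy", pop1 = pairs[1, j], pop2 = pairs[2, j],
        scaffold = w$scaffold, start = w$start, end = w$end,
        value = r$value, sum_diffs = r$sum_diffs,
        sum_comparisons = r$sum_comparisons, sum_missing = r$sum_missing,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        stat = "fst", pop1 = pairs[1, j], pop2 = pairs[2, j],
        scaffold = w$scaffold, start = w$start, end = w$end,
        value = f$value, sum_diffs = f$sum_diffs,
        sum_comparisons = f$sum_comparisons, sum_missing = f$sum_missing,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Divergence outlier windows
#'
#' Windows are first filtered by the missing-data rule (drop windows with
#' more missing counts than count comparisons), then flagged as outliers
#' when their Z-score against the genome-wide mean exceeds `z_threshold`.
#' The standard deviation is the sample SD (n-1 denominator). When the SD
#' is zero the outlier set is empty.
#'
#' @param records data.frame with columns value, sum_missing,
#'   sum_comparisons, scaffold, start, end (one statistic, one pair).
#' @param z_threshold Z-score cut-off (default 3).
#' @return data.frame of outlier windows; attribute `retained` holds the
#'   windows that survived the missing-data pre-filter.
#' @export
dxy_outliers <- function(records, z_threshold = 3) {
  keep <- !is.na(records$value) &
    !(records$sum_missing > records$sum_comparisons)
  retained <- records[keep, , drop = FALSE]
  stop_if(nrow(retained) < 2, "need >= 2 retained windows for outlier scan")
  mu <- mean(retained$value)
  sdv <- stats::sd(retained$value)
  out <- if (sdv == 0) retained[0, , drop = FALSE]
         else retained[(retained$value - mu) / sdv > z_threshold, ,
                       drop = FALSE]
  attr(out, "retained") <- retained
  attr(out, "system") <- sort(paste(records$scaffold, records$start,
                                    records$end))
  attr(out, "mean") <- mu
  attr(out, "sd") <- sdv
  out
}

#' Outlier windows shared between two scans
#'
#' Exact intersection on (scaffold, start, end). Both outlier sets must
#' come from the same window system; when both carry the retained-window
#' attribute from [dxy_outliers()] this is verified.
#'
#' @param setA,setB outlier data.frames from [dxy_outliers()].
#' @return data.frame of shared windows (columns from `setA`).
#' @export
shared_outliers <- function(setA, setB) {
  sa <- attr(setA, "system"); sb <- attr(setB, "system")
  if (!is.null(sa) && !is.null(sb))
    stop_if(!identical(sa, sb),
            "outlier sets come from different window systems")
  keyA <- paste(setA$scaffold, setA$start, setA$end)
  keyB <- paste(setB$scaffold, setB$start, setB$end)
  setA[keyA %in% keyB, , drop = FALSE]
}
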