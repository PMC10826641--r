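# Four-taxon site-pattern statistics.
#
# All statistics work on population alternate-allele frequencies
# p1..p4 for an oriented trio (P1, P2, P3) plus outgroup O. Per site:
#   ABBA = (1 - p1) p2 p3 (1 - p4)
#   BABA = p1 (1 - p2) p3 (1 - p4)
# A site contributes only when every one of the four populations has at
# least one non-missing allele.

# per-site frequencies for the four populations over `sites`
trio_freqs <- function(gm, popmap, pops, sites = NULL) {
  stop_if(length(pops) != 4, "pops must be (P1, P2, P3, outgroup)")
  samp <- lapply(pops, function(p) pop_samples(popmap, p))
  overlap <- table(unlist(samp))
  stop_if(any(overlap > 1), "populations share samples: ",
          paste(names(overlap)[overlap > 1], collapse = ", "))
  f <- lapply(samp, function(s) pop_allele_freq(gm, s, sites)$p)
  names(f) <- c("p1", "p2", "p3", "p4")
  f$used <- !(is.na(f$p1) | is.na(f$p2) | is.na(f$p3) | is.na(f$p4))
  f
}

abba_baba_terms <- function(f) {
  ok <- f$used
  p1 <- f$p1[ok]; p2 <- f$p2[ok]; p3 <- f$p3[ok]; p4 <- f$p4[ok]
  list(abba = (1 - p1) * p2 * p3 * (1 - p4),
       baba = p1 * (1 - p2) * p3 * (1 - p4),
       site = which(ok))
}

#' ABBA/BABA site-pattern sums
#'
#' @param gm a [genotype_matrix()].
#' @param popmap named population vector.
#' @param pops character vector `(P1, P2, P3, outgroup)`.
#' @param sites optional site indices (default all).
#' @return list with `sum_abba`, `sum_baba`, `n_sites_used`.
#' @export
site_patterns <- function(gm, popmap, pops, sites = NULL) {
  f <- trio_freqs(gm, popmap, pops, sites)
  t <- abba_baba_terms(f)
  structure(list(sum_abba = sum(t$abba), sum_baba = sum(t$baba),
                 n_sites_used = sum(f$used)),
            class = "site_pattern_sums")
}

#' Patterson's D from site-pattern sums
#'
#' `D = (ABBA - BABA) / (ABBA + BABA)`; `NA` with a warning when no
#' informative sites were accumulated.
#'
#' @param patterns result of [site_patterns()].
#' @return D in [-1, 1], or NA.
#' @export
d_statistic <- function(patterns) {
  denom <- patterns$sum_abba + patterns$sum_baba
  if (denom == 0) { warning("no informative sites; D is NA"); return(NA_real_) }
  (patterns$sum_abba - patterns$sum_baba) / denom
}

#' D with block-jackknife significance
#'
#' Informative sites (nonzero ABBA+BABA contribution) are split into
#' `n_blocks` contiguous equal-count blocks in genome order; the
#' delete-one-block jackknife gives `SE^2 = (B-1)/B * sum_j (D_{-j} -
#' mean(D_{-j}))^2`, `Z = D/SE` and a two-tailed normal p-value. A zero
#' SE is flagged degenerate (`p = NA`).
#'
#' @inheritParams site_patterns
#' @param n_blocks number of jackknife blocks (default 20).
#' @return list: D, Z, p, se, n_informative, degenerate.
#' @export
d_jackknife <- function(gm, popmap, pops, n_blocks = 20, sites = NULL) {
  stop_if(n_blocks < 2, "need >= 2 jackknife blocks")
  f <- trio_freqs(gm, popmap, pops, sites)
  t <- abba_baba_terms(f)
  informative <- which(t$abba + t$baba > 0)
  stop_if(length(informative) < n_blocks,
          "fewer informative sites (", length(informative),
          ") than blocks (", n_blocks, ")")
  A <- t$abba[informative]; B <- t$baba[informative]
  D <- (sum(A) - sum(B)) / (sum(A) + sum(B))
  blk <- contiguous_blocks(length(informative), n_blocks)
  sa <- tapply(A, blk, sum); sb <- tapply(B, blk, sum)
  d_loo <- (sum(A) - sa - (sum(B) - sb)) / (sum(A) - sa + sum(B) - sb)
  se <- sqrt((n_blocks - 1) / n_blocks * sum((d_loo - mean(d_loo))^2))
  if (se == 0)
    return(list(D = D, Z = NA_real_, p = NA_real_, se = 0,
                n_informative = length(informative), degenerate = TRUE))
  Z <- D / se
  list(D = D, Z = Z, p = 2 * stats::pnorm(-abs(Z)), se = se,
       n_informative = length(informative), degenerate = FALSE)
}

#' f4-ratio admixture fraction estimate
#'
#' `f = S(P1,P2;P3,O) / S(P1,P3;P3,O)` where
#' `S = sum p3 (1 - p4) (p2 - p1)` and the denominator substitutes P3 for
#' P2. Estimates the admixture fraction contributed by a P3-related donor
#' into P2.
#'
#' @inheritParams site_patterns
#' @return admixture fraction estimate, NA on zero denominator.
#' @export
f4_ratio <- function(gm, popmap, pops, sites = NULL) {
  f <- trio_freqs(gm, popmap, pops, sites)
  ok <- f$used
  p1 <- f$p1[ok]; p2 <- f$p2[ok]; p3 <- f$p3[ok]; p4 <- f$p4[ok]
  num <- sum(p3 * (1 - p4) * (p2 - p1))
  den <- sum(p3 * (1 - p4) * (p3 - p1))
  if (den == 0) { warning("zero f4-ratio denominator"); return(NA_real_) }
  num / den
}

# fdM numerator and denominator terms from frequency vectors
fdm_terms <- function(p1, p2, p3, p4) {
  abba <- (1 - p1) * p2 * p3 * (1 - p4)
  baba <- p1 * (1 - p2) * p3 * (1 - p4)
  num <- abba - baba
  pos <- num >= 0
  pd2 <- pmax(p2, p3)
  den_pos <- (1 - p1) * pd2 * pd2 * (1 - p4) -
             p1 * (1 - pd2) * pd2 * (1 - p4)
  pd1 <- pmax(p1, p3)
  den_neg <- -((1 - pd1) * p2 * pd1 * (1 - p4) -
               pd1 * (1 - p2) * pd1 * (1 - p4))
  # sites where P3 carries no derived allele relative to the outgroup
  # (p3(1-p4) = 0) have a zero numerator and are excluded from the
  # denominator as well; this makes fdM exactly antisymmetric in P1/P2
  informative <- p3 * (1 - p4) > 0
  list(num = num,
       den = ifelse(informative, ifelse(pos, den_pos, den_neg), 0))
}

#' Windowed fdM introgression statistic
#'
#' Per window, `fdM = sum(ABBA - BABA) / sum(denominator)` where the
#' per-site denominator substitutes the larger of (p2, p3) for both when
#' the site's numerator is non-negative, and the larger of (p1, p3) for
#' both (with a sign flip) otherwise. Symmetric around 0 under no
#' introgression: positive values indicate P2-P3 allele sharing, negative
#' P1-P3.
#'
#' @inheritParams site_patterns
#' @param windows SNP windows from [snp_windows()].
#' @return the window data.frame with columns `fdm` and `n_used` added.
#' @export
fdm_windows <- function(gm, popmap, pops, windows) {
  f <- trio_freqs(gm, popmap, pops)
  out_fdm <- numeric(nrow(windows)); out_n <- integer(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    idx <- seq(windows$snp_from[i], windows$snp_to[i])
    ok <- f$used[idx]
    use <- idx[ok]
    t <- fdm_terms(f$p1[use], f$p2[use], f$p3[use], f$p4[use])
    den <- sum(t$den)
    out_fdm[i] <- if (length(use) == 0 || den == 0) NA_real_
                  else sum(t$num) / den
    out_n[i] <- length(use)
  }
  windows$fdm <- out_fdm
  windows$n_used <- out_n
  windows
}

#' Enumerate trio orientations from a guide tree
#'
#' Every unordered triple of ingroup populations, oriented so that
#' (P1, P2) is the pair with the most recent common ancestor on the
#' rooted guide tree; P1 < P2 lexicographically. Polytomies that leave
#' the orientation ambiguous are broken lexicographically and flagged.
#'
#' @param guide_tree rooted `phylo` whose tips are population labels.
#' @param outgroup outgroup tip label (excluded from trios).
#' @return data.frame: P1, P2, P3, tie (logical).
#' @export
enumerate_trios <- function(guide_tree, outgroup) {
  stop_if(!outgroup %in% guide_tree$tip.label,
          "outgroup not in guide tree: ", outgroup)
  if (is.null(guide_tree$edge.length))   # depths from topology alone
    guide_tree$edge.length <- rep(1, nrow(guide_tree$edge))
  ingroup <- setdiff(guide_tree$tip.label, outgroup)
  stop_if(length(ingroup) < 3, "need >= 3 ingroup populations")
  depth <- ape::node.depth.edgelength(guide_tree)
  trip <- utils::combn(sort(ingroup), 3)
  rows <- lapply(seq_len(ncol(trip)), function(j) {
    tr <- trip[, j]
    prs <- utils::combn(tr, 2)
    d <- vapply(seq_len(3), function(k)
      depth[ape::getMRCA(guide_tree, prs[, k])], numeric(1))
    tie <- sum(abs(d - max(d)) < 1e-10) > 1
    k <- which.max(d)   # deepest depth = most recent MRCA; ties -> first
    p12 <- sort(prs[, k])
    data.frame(P1 = p12[1], P2 = p12[2], P3 = setdiff(tr, p12), tie = tie,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' D and f4-ratio for all trios with Bonferroni correction
#'
#' @inheritParams d_jackknife
#' @param guide_tree rooted guide tree (population labels as tips).
#' @param outgroup outgroup population.
#' @param alpha family-wise error rate for the Bonferroni cut
#'   (default 0.05, divided by the number of trios).
#' @return data.frame: P1, P2, P3, D, Z, p, f4_ratio, significant.
#' @export
d_all_trios <- function(gm, popmap, guide_tree, outgroup, n_blocks = 20,
                        alpha = 0.05) {
  trios <- enumerate_trios(guide_tree, outgroup)
  res <- lapply(seq_len(nrow(trios)), function(i) {
    pops <- c(trios$P1[i], trios$P2[i], trios$P3[i], outgroup)
    jk <- d_jackknife(gm, popmap, pops, n_blocks)
    f4 <- suppressWarnings(f4_ratio(gm, popmap, pops))
    data.frame(P1 = pops[1], P2 = pops[2], P3 = pops[3], D = jk$D,
               Z = jk$Z, p = jk$p, f4_ratio = f4,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- !is.na(out$p) & out$p < alpha / nrow(out)
  out
}

# --- f-branch -------------------------------------------------------------

# tips below each node of a rooted tree, as labels
node_tipsets <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  lapply(seq_len(n), function(v) {
    if (v <= length(tree$tip.label)) tree$tip.label[v]
    else tree$tip.label[ape::prop.part(tree)[[v - length(tree$tip.label)]]]
  })
}

#' f-branch matrix: branch-specific excess allele sharing
#'
#' For each branch `b` of the rooted guide tree and each tip `C` that
#' descends from neither `b` nor `b`'s sister:
#' `f_b(C) = median over B in tips(sister(b)) of min over A in tips(b) of
#' f4_ratio(B, A, C, O)`, negatives truncated at 0. Cells where `C`
#' descends from `b` or its sister are marked invalid (inconsistent with
#' the guide topology). Optional block-jackknife Z-scores flag cells with
#' `Z > z_threshold` as significant.
#'
#' @param guide_tree rooted `phylo`; tips are population labels,
#'   including the outgroup.
#' @param gm a [genotype_matrix()].
#' @param popmap named population vector.
#' @param outgroup outgroup population label.
#' @param n_blocks jackknife blocks for significance (default 20).
#' @param z_threshold significance threshold on Z (default 3).
#' @param significance compute jackknife Z per cell (default TRUE).
#' @return list with matrices `fb`, `z`, `significant` and logical
#'   `valid`; rows are branches (named by their descendant tip sets),
#'   columns tips.
#' @export
f_branch <- function(guide_tree, gm, popmap, outgroup, n_blocks = 20,
                     z_threshold = 3, significance = TRUE) {
  stop_if(!ape::is.rooted(guide_tree), "guide tree must be rooted")
  tree <- ape::drop.tip(guide_tree, outgroup)
  tips <- tree$tip.label
  stop_if(length(tips) < 3, "need >= 4 populations including outgroup")
  ntip <- length(tips)
  root <- ntip + 1L
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  tipsets <- node_tipsets(tree)
  # branches: every non-root node with a resolved (single) sister
  branch_nodes <- setdiff(which(!is.na(parent)), integer(0))
  rows <- list()
  for (b in branch_nodes) {
    sibs <- setdiff(tree$edge[tree$edge[, 1] == parent[b], 2], b)
    if (length(sibs) != 1) { warning("unresolved node; branch skipped")
                             next }
    rows[[length(rows) + 1L]] <-
      list(node = b, tips_b = tipsets[[b]], tips_sister = tipsets[[sibs]])
  }
  nr <- length(rows)
  fb <- matrix(NA_real_, nr, ntip,
               dimnames = list(vapply(rows, function(r)
                 paste(sort(r$tips_b), collapse = ","), ""), tips))
  zmat <- fb
  valid <- matrix(FALSE, nr, ntip, dimnames = dimnames(fb))

  # per-population frequencies once
  pops_all <- c(tips, outgroup)
  freq <- sapply(pops_all, function(p)
    pop_allele_freq(gm, pop_samples(popmap, p))$p)
  pO <- freq[, outgroup]
  blocks <- contiguous_blocks(nrow(freq), n_blocks)

  f4_cell <- function(B, A, C, drop_block = 0) {
    ok <- stats::complete.cases(freq[, c(B, A, C)]) & !is.na(pO)
    if (drop_block > 0) ok <- ok & blocks != drop_block
    w <- freq[ok, C] * (1 - pO[ok])
    den <- sum(w * (freq[ok, C] - freq[ok, B]))
    if (den == 0) return(NA_real_)
    sum(w * (freq[ok, A] - freq[ok, B])) / den
  }
  fb_cell <- function(r, C, drop_block = 0) {
    meds <- vapply(r$tips_sister, function(B)
      min(vapply(r$tips_b, function(A) f4_cell(B, A, C, drop_block),
                 numeric(1))), numeric(1))
    max(0, stats::median(meds))
  }
  for (i in seq_len(nr)) {
    r <- rows[[i]]
    for (C in setdiff(tips, c(r$tips_b, r$tips_sister))) {
      valid[i, C] <- TRUE
      fb[i, C] <- fb_cell(r, C)
      if (significance) {
        loo <- vapply(seq_len(n_blocks), function(j) fb_cell(r, C, j),
                      numeric(1))
        se <- sqrt((n_blocks - 1) / n_blocks * sum((loo - mean(loo))^2))
        zmat[i, C] <- if (se > 0) fb[i, C] / se else NA_real_
      }
    }
  }
  list(fb = fb, z = zmat,
       significant = !is.na(zmat) & zmat > z_threshold, valid = valid)
}

#' One-tailed elevation test for a candidate region
#'
#' One-sample t-test of the fdM values of windows overlapping the region
#' against the scaffold-wide mean (treated as a constant), upper-tailed.
#'
#' @param fdm_records output of [fdm_windows()].
#' @param scaffold scaffold name.
#' @param region numeric `c(start, end)`, 0-based half-open.
#' @return list: mean_difference, t, df, p (one-tailed), n_region,
#'   n_scaffold.
#' @export
region_elevation_test <- function(fdm_records, scaffold, region) {
  on_scaf <- fdm_records[fdm_records$scaffold == scaffold &
                           !is.na(fdm_records$fdm), , drop = FALSE]
  stop_if(nrow(on_scaf) < 2, "need >= 2 windows on scaffold ", scaffold)
  in_region <- on_scaf[on_scaf$end > region[1] & on_scaf$start < region[2], ,
                       drop = FALSE]
  stop_if(nrow(in_region) < 2, "need >= 2 windows overlapping the region")
  mu <- mean(on_scaf$fdm)
  x <- in_region$fdm
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0) {   # degenerate but well-defined one-sample t limit
    tval <- if (mean(x) == mu) 0 else sign(mean(x) - mu) * Inf
  } else {
    tval <- (mean(x) - mu) / (s / sqrt(n))
  }
  list(mean_difference = mean(x) - mu,
       t = tval, df = n - 1,
       p = stats::pt(tval, df = n - 1, lower.tail = FALSE),
       n_region = n, n_scaffold = nrow(on_scaf))
}
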