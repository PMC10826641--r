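# Tree-based discordance statistics.
#
# Unrooted topologies are identified by canonical bipartition sets: each
# nontrivial bipartition is represented by the sorted tip-label set of the
# side NOT containing the alphabetically first tip, and a topology key is
# the sorted concatenation of its bipartition strings.

# canonical nontrivial bipartitions of an unrooted tree, as label strings
bipartition_keys <- function(tree, labels = tree$tip.label) {
  ntip <- length(labels)
  if (ntip < 4) return(character(0))
  ref <- min(labels)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (i in seq_along(pp)) {
    side <- labels[pp[[i]]]
    other <- setdiff(labels, side)
    if (length(side) < 2 || length(other) < 2) next
    canon <- if (ref %in% side) other else side
    keys <- c(keys, paste(sort(canon), collapse = ","))
  }
  unique(keys)
}

#' Normalized Robinson-Foulds distance
#'
#' Symmetric-difference count of nontrivial bipartitions divided by the
#' maximum possible -- `2(n-3)` for two binary trees of n tips; for
#' polytomous trees the normalizer is the total number of internal edges
#' of the two trees. Trees with different tip sets are pruned to the
#' shared tips first (with a warning).
#'
#' @param tree1,tree2 `phylo` objects.
#' @return distance in [0, 1].
#' @export
rf_normalized <- function(tree1, tree2) {
  shared <- intersect(tree1$tip.label, tree2$tip.label)
  if (length(shared) < length(tree1$tip.label) ||
      length(shared) < length(tree2$tip.label)) {
    warning("trees pruned to ", length(shared), " shared tips")
    tree1 <- ape::keep.tip(tree1, shared)
    tree2 <- ape::keep.tip(tree2, shared)
  }
  stop_if(length(shared) < 4, "need >= 4 shared tips for RF distance")
  k1 <- bipartition_keys(ape::unroot(tree1))
  k2 <- bipartition_keys(ape::unroot(tree2))
  denom <- length(k1) + length(k2)
  if (denom == 0) return(0)
  (length(setdiff(k1, k2)) + length(setdiff(k2, k1))) / denom
}

# induced taxon-level topology key for one sample combination
induced_topology_key <- function(tree, combo_tips, taxa) {
  sub <- ape::keep.tip(tree, combo_tips)
  sub$tip.label <- taxa[match(sub$tip.label, combo_tips)]
  paste(sort(bipartition_keys(ape::unroot(sub))), collapse = ";")
}

#' Topology weights across multi-sample taxa
#'
#' The weight of an unrooted taxon-level topology is the fraction of
#' one-tip-per-taxon sample combinations whose induced subtree matches
#' it. Combinations are enumerated exhaustively when their number is at
#' most `max_exact`, otherwise sampled uniformly (seeded) with a reported
#' Monte-Carlo standard error.
#'
#' @param tree a `phylo` window/gene tree whose tips are samples.
#' @param taxon_map named character vector mapping sample tip -> taxon.
#' @param taxa taxa to weight over (default: all in `taxon_map`).
#' @param max_exact exact-enumeration limit (default 10000).
#' @param n_samples Monte-Carlo draws in sampled mode (default 1000).
#' @param seed RNG seed for sampled mode.
#' @return a `topology_weighting`: list with `weights` (named by topology
#'   key), `bipartitions` (list of bipartition label-sets per topology),
#'   `method`, `n_combinations_evaluated`, `mc_se`.
#' @export
topology_weights <- function(tree, taxon_map, taxa = NULL,
                             max_exact = 10000, n_samples = 1000,
                             seed = 1) {
  taxa <- sort(taxa %||% unique(unname(taxon_map)))
  tips_by_taxon <- lapply(taxa, function(tx) {
    tp <- intersect(names(taxon_map)[taxon_map == tx], tree$tip.label)
    stop_if(length(tp) == 0, "taxon with zero tips in tree: ", tx)
    tp
  })
  names(tips_by_taxon) <- taxa
  n_comb <- prod(vapply(tips_by_taxon, length, 1))
  exact <- n_comb <= max_exact
  combos <- if (exact) {
    as.matrix(expand.grid(tips_by_taxon, stringsAsFactors = FALSE))
  } else {
    set.seed(seed)
    sapply(tips_by_taxon, function(tp)
      sample_int(tp, n_samples, replace = TRUE))
  }
  keys <- vapply(seq_len(nrow(combos)), function(i)
    induced_topology_key(tree, combos[i, ], taxa), "")
  tab <- table(keys)
  w <- as.numeric(tab) / length(keys)
  names(w) <- names(tab)
  bip <- lapply(names(w), function(k)
    lapply(strsplit(k, ";", fixed = TRUE)[[1]],
           function(b) strsplit(b, ",", fixed = TRUE)[[1]]))
  names(bip) <- names(w)
  structure(list(weights = w, bipartitions = bip, taxa = taxa,
                 method = if (exact) "exact" else "sampled",
                 n_combinations_evaluated = length(keys),
                 mc_se = if (exact) 0 else sqrt(w * (1 - w) / length(keys))),
            class = "topology_weighting")
}

#' @export
print.topology_weighting <- function(x, ...) {
  cat("topology_weighting (", x$method, ", ",
      x$n_combinations_evaluated, " combinations):\n", sep = "")
  for (k in names(sort(x$weights, decreasing = TRUE)))
    cat(sprintf("  %.4f  %s\n", x$weights[[k]], k))
  invisible(x)
}

# does taxon set `clade` form a clade (relative to any outgroup outside
# it) in the topology with the given bipartition list?
topology_has_clade <- function(bip_list, clade, taxa) {
  clade <- sort(clade)
  if (length(clade) < 2 || length(clade) > length(taxa) - 2) return(TRUE)
  ref <- min(taxa)
  canon <- if (ref %in% clade) sort(setdiff(taxa, clade)) else clade
  any(vapply(bip_list, function(b) identical(sort(b), canon), logical(1)))
}

#' Summed topology weight supporting an internal branch
#'
#' For each weighting, sums the weights of all topologies in which
#' `branch_def` forms a clade relative to the outgroup -- the per-window
#' support for that internal branch of the species tree.
#'
#' @param weightings a `topology_weighting` or list of them (one per
#'   window).
#' @param branch_def character vector of taxa defining the branch (e.g. a
#'   species pair).
#' @param guide_tree optional rooted species tree; a warning is issued if
#'   `branch_def` is not one of its clades.
#' @return numeric vector of summed weights, one per weighting.
#' @export
internal_branch_weights <- function(weightings, branch_def,
                                    guide_tree = NULL) {
  if (inherits(weightings, "topology_weighting"))
    weightings <- list(weightings)
  if (!is.null(guide_tree)) {
    sets <- node_tipsets(guide_tree)
    if (!any(vapply(sets, function(s) setequal(s, branch_def), logical(1))))
      warning("branch_def is not a clade of the guide tree")
  }
  vapply(weightings, function(w) {
    hit <- vapply(names(w$weights), function(k)
      topology_has_clade(w$bipartitions[[k]], branch_def, w$taxa),
      logical(1))
    sum(w$weights[hit])
  }, numeric(1))
}

# the four tip groups around each internal branch of a rooted binary tree
branch_quartet_groups <- function(species_tree) {
  tips <- species_tree$tip.label
  ntip <- length(tips)
  parent <- rep(NA_integer_, ntip + species_tree$Nnode)
  parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  tipsets <- node_tipsets(species_tree)
  root <- ntip + 1L
  out <- list()
  for (v in (ntip + 1L):(ntip + species_tree$Nnode)) {
    if (v == root || is.na(parent[v])) next
    kids <- species_tree$edge[species_tree$edge[, 1] == v, 2]
    if (length(kids) != 2) next   # concordance defined around binary nodes
    A <- tipsets[[kids[1]]]; B <- tipsets[[kids[2]]]
    sibs <- setdiff(species_tree$edge[species_tree$edge[, 1] == parent[v], 2],
                    v)
    C <- unlist(tipsets[sibs])
    D <- setdiff(tips, c(A, B, C))
    if (length(C) == 0 || length(D) == 0) next
    out[[length(out) + 1L]] <- list(node = v, A = A, B = B, C = C, D = D,
                                    clade = sort(c(A, B)))
  }
  out
}

#' Gene concordance factors
#'
#' For each internal branch of the species tree, the percentage of
#' decisive gene trees containing the branch's bipartition. A gene tree
#' is decisive for a branch when it holds at least one tip in each of the
#' four subtrees surrounding the branch.
#'
#' @param gene_trees list of `phylo` (tips may be a subset of species
#'   tree tips; multi-sample tips are mapped via `taxon_map`).
#' @param species_tree rooted binary `phylo`.
#' @param taxon_map optional named vector sample -> taxon for gene trees
#'   whose tips are samples.
#' @return data.frame: clade, gCF, n_decisive, n_concordant.
#' @export
gene_concordance <- function(gene_trees, species_tree, taxon_map = NULL) {
  groups <- branch_quartet_groups(species_tree)
  stop_if(length(groups) == 0, "species tree has no internal branches")
  res <- lapply(groups, function(g) {
    dec <- 0L; conc <- 0L
    for (gt in gene_trees) {
      labs <- gt$tip.label
      taxa_in <- if (is.null(taxon_map)) labs
                 else unname(taxon_map[labs])
      if (!all(vapply(list(g$A, g$B, g$C, g$D),
                      function(s) any(taxa_in %in% s), logical(1)))) next
      dec <- dec + 1L
      keep <- labs[taxa_in %in% c(g$A, g$B, g$C, g$D)]
      sub <- ape::keep.tip(gt, keep)
      tips_g <- sub$tip.label
      taxa_g <- if (is.null(taxon_map)) tips_g else unname(taxon_map[tips_g])
      side <- tips_g[taxa_g %in% c(g$A, g$B)]
      ref <- min(tips_g)
      canon <- if (ref %in% side) sort(setdiff(tips_g, side)) else sort(side)
      key_target <- paste(canon, collapse = ",")
      if (key_target %in% bipartition_keys(ape::unroot(sub)))
        conc <- conc + 1L
    }
    data.frame(clade = paste(g$clade, collapse = ","),
               gCF = if (dec > 0) 100 * conc / dec else NA_real_,
               n_decisive = dec, n_concordant = conc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Site concordance factors by quartet sampling
#'
#' For each internal branch, samples quartets with one sequence from each
#' of the four surrounding groups and counts decisive sites (exactly two
#' states, each carried by two quartet members). The concordant pairing
#' groups the two same-side members; sCF is the mean over quartets of
#' `100 * concordant / decisive`, skipping quartets with no decisive
#' site.
#'
#' @param aln named character vector of equal-length sequences (samples).
#' @param species_tree rooted binary `phylo` with taxon tips.
#' @param taxon_map named vector sample -> taxon (default: sample names
#'   are taxa).
#' @param n_quartets quartets per branch (default 100).
#' @param seed RNG seed.
#' @return data.frame: clade, sCF, n_quartets_used.
#' @export
site_concordance <- function(aln, species_tree, taxon_map = NULL,
                             n_quartets = 100, seed = 1) {
  stop_if(n_quartets < 1, "n_quartets must be >= 1")
  if (is.null(taxon_map))
    taxon_map <- stats::setNames(names(aln), names(aln))
  groups <- branch_quartet_groups(species_tree)
  stop_if(length(groups) == 0, "species tree has no internal branches")
  seq_mat <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(seq_mat) <- names(aln)
  samples_of <- function(taxa)
    intersect(names(taxon_map)[taxon_map %in% taxa], names(aln))
  set.seed(seed)
  res <- lapply(groups, function(g) {
    sa <- samples_of(g$A); sb <- samples_of(g$B)
    sc <- samples_of(g$C); sd_ <- samples_of(g$D)
    if (!all(lengths(list(sa, sb, sc, sd_)) > 0))
      return(data.frame(clade = paste(g$clade, collapse = ","),
                        sCF = NA_real_, n_quartets_used = 0L,
                        stringsAsFactors = FALSE))
    vals <- numeric(0)
    for (q in seq_len(n_quartets)) {
      rows <- seq_mat[c(sample_int(sa, 1), sample_int(sb, 1),
                        sample_int(sc, 1), sample_int(sd_, 1)), ,
                      drop = FALSE]
      ok <- colSums(matrix(rows %in% c("A", "C", "G", "T"), nrow = 4)) == 4
      if (!any(ok)) next
      r <- rows[, ok, drop = FALSE]
      eq <- function(i, j) r[i, ] == r[j, ]
      conc <- eq(1, 2) & eq(3, 4) & !eq(1, 3)
      dis1 <- eq(1, 3) & eq(2, 4) & !eq(1, 2)
      dis2 <- eq(1, 4) & eq(2, 3) & !eq(1, 2)
      dec <- sum(conc) + sum(dis1) + sum(dis2)
      if (dec == 0) next
      vals <- c(vals, 100 * sum(conc) / dec)
    }
    data.frame(clade = paste(g$clade, collapse = ","),
               sCF = if (length(vals) > 0) mean(vals) else NA_real_,
               n_quartets_used = length(vals), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
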