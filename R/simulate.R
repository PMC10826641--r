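#' Multispecies-coalescent model with migration pulses
#'
#' Describes the scenario gene trees are simulated under: an ultrametric
#' species tree with branch lengths in coalescent units (2N generations),
#' a number of diploid samples per taxon, and optional instantaneous
#' migration pulses. A pulse with fraction `f` moves each lineage present
#' in the recipient branch at the pulse time into the donor branch with
#' probability `f` (backward in time), which corresponds forward in time
#' to a donor-to-recipient admixture pulse of fraction `f` -- the quantity
#' the f4-ratio estimates.
#'
#' @param tree rooted ultrametric `phylo`; branch lengths in coalescent
#'   units; tip labels are the taxa.
#' @param samples_per_taxon named integer vector: diploid samples per
#'   taxon; unnamed scalar recycles over all taxa.
#' @param migrations list of [migration_pulse()] events.
#' @param ploidy 2 (diploid samples, two lineages each) or 1 (haploid
#'   tips, one lineage per sample; used for closed-form topology checks).
#' @return a `species_tree_model`.
#' @export
species_tree_model <- function(tree, samples_per_taxon = 1,
                               migrations = list(), ploidy = 2) {
  stop_if(!inherits(tree, "phylo"), "tree must be a phylo object")
  stop_if(!ape::is.rooted(tree), "species tree must be rooted")
  taxa <- tree$tip.label
  if (is.null(names(samples_per_taxon))) {
    stop_if(length(samples_per_taxon) != 1,
            "unnamed samples_per_taxon must be a scalar")
    samples_per_taxon <- stats::setNames(rep(as.integer(samples_per_taxon),
                                             length(taxa)), taxa)
  }
  miss <- setdiff(taxa, names(samples_per_taxon))
  stop_if(length(miss) > 0, "samples_per_taxon missing taxa: ",
          paste(miss, collapse = ", "))
  stop_if(!ploidy %in% c(1, 2), "ploidy must be 1 or 2")
  model <- structure(list(tree = tree,
                          samples_per_taxon = samples_per_taxon[taxa],
                          migrations = migrations, ploidy = ploidy),
                     class = "species_tree_model")
  prep_model(model)   # validates
  model
}

#' Instantaneous migration pulse
#'
#' @param donor,recipient taxon label, or character vector of taxa naming
#'   the branch above their MRCA.
#' @param time pulse time in coalescent units before present; must fall
#'   strictly within the lifetime of both branches.
#' @param fraction migrant fraction f in [0, 1].
#' @return a `migration_pulse`.
#' @export
migration_pulse <- function(donor, recipient, time, fraction) {
  stop_if(fraction < 0 || fraction > 1, "migrant fraction must be in [0,1]")
  stop_if(identical(sort(donor), sort(recipient)),
          "donor and recipient must differ")
  structure(list(donor = donor, recipient = recipient,
                 time = time, fraction = fraction),
            class = "migration_pulse")
}

# node ages of an ultrametric rooted tree (tips at 0)
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth[seq_along(tree$tip.label)]) - depth
  stop_if(any(abs(ages[seq_along(tree$tip.label)]) > 1e-8),
          "species tree must be ultrametric (tips at equal depth)")
  ages
}

# resolve a taxon label / clade spec to a species-tree node id
resolve_branch <- function(tree, spec) {
  if (length(spec) == 1 && spec %in% tree$tip.label)
    return(match(spec, tree$tip.label))
  idx <- match(spec, tree$tip.label)
  stop_if(anyNA(idx), "unknown taxa in branch spec: ",
          paste(spec[is.na(idx)], collapse = ", "))
  ape::getMRCA(tree, idx)
}

# validate model, precompute the event schedule for the coalescent
prep_model <- function(model) {
  tree <- model$tree
  ages <- node_ages(tree)
  ntax <- length(tree$tip.label)
  root <- ntax + 1L
  parent <- rep(NA_integer_, ntax + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  top_age <- ifelse(is.na(parent), Inf, ages[ifelse(is.na(parent), 1,
                                                    parent)])
  pulses <- lapply(model$migrations, function(m) {
    dn <- resolve_branch(tree, m$donor)
    rn <- resolve_branch(tree, m$recipient)
    stop_if(dn == rn, "pulse donor and recipient resolve to the same branch")
    for (v in c(dn, rn))
      stop_if(m$time <= ages[v] + 1e-12 || m$time >= top_age[v] - 1e-12,
              "pulse time ", m$time, " outside the lifetime of branch ",
              v, " [", signif(ages[v], 4), ", ", signif(top_age[v], 4), ")")
    list(donor = dn, recipient = rn, time = m$time, fraction = m$fraction)
  })
  internals <- order(ages[(ntax + 1L):(ntax + tree$Nnode)]) + ntax
  children <- lapply(seq_len(ntax + tree$Nnode), function(v)
    tree$edge[tree$edge[, 1] == v, 2])
  ev <- c(lapply(internals, function(v)
           list(type = "merge", node = v, time = ages[v])),
          lapply(pulses, function(p)
           list(type = "pulse", donor = p$donor, recipient = p$recipient,
                time = p$time, fraction = p$fraction)))
  ev <- ev[order(vapply(ev, `[[`, 0, "time"))]
  k <- model$samples_per_taxon * model$ploidy
  list(tree = tree, ages = ages, root = root, children = children,
       events = ev, lineages_per_taxon = k,
       n_tips = sum(k), ntax = ntax)
}

# tip labels: sample ids (ploidy 1) or sample.1/sample.2 haploid lineages
model_tip_labels <- function(model) {
  taxa <- model$tree$tip.label
  unlist(lapply(taxa, function(tx) {
    samples <- paste0(tx, "_", seq_len(model$samples_per_taxon[[tx]]))
    if (model$ploidy == 1) samples
    else as.vector(t(outer(samples, 1:2, paste, sep = ".")))
  }))
}

#' Sample ids implied by a species tree model
#' @param model a [species_tree_model()].
#' @return character vector of diploid sample ids, taxon order.
#' @export
model_samples <- function(model) {
  taxa <- model$tree$tip.label
  unlist(lapply(taxa, function(tx)
    paste0(tx, "_", seq_len(model$samples_per_taxon[[tx]]))))
}

# one gene tree under the MSC with pulses; flat representation
# returns list(parent, time) over nodes 1..(2L-1); tips 1..L
msc_sim_once <- function(prep) {
  L <- prep$n_tips
  parent <- integer(2L * L - 1L)
  time <- numeric(2L * L - 1L)
  next_node <- L + 1L
  # pools: lineages currently in each species-tree branch
  pools <- vector("list", length(prep$children))
  off <- 0L
  for (tx in seq_len(prep$ntax)) {
    k <- prep$lineages_per_taxon[[tx]]
    pools[[tx]] <- seq_len(k) + off
    off <- off + k
  }
  t_now <- 0
  coalesce_pool <- function(pool, t0, t1) {
    while (length(pool) >= 2) {
      k <- length(pool)
      t0 <- t0 + stats::rexp(1, rate = k * (k - 1) / 2)
      if (t0 >= t1) break
      pair <- sample.int(k, 2)
      anc <- next_node
      parent[pool[pair]] <<- anc
      time[anc] <<- t0
      next_node <<- next_node + 1L
      pool <- c(pool[-pair], anc)
    }
    pool
  }
  for (ev in prep$events) {
    for (v in seq_along(pools)) {
      if (length(pools[[v]]) >= 2)
        pools[[v]] <- coalesce_pool(pools[[v]], t_now, ev$time)
    }
    t_now <- ev$time
    if (ev$type == "merge") {
      merged <- unlist(pools[prep$children[[ev$node]]])
      for (ch in prep$children[[ev$node]]) pools[[ch]] <- integer()
      pools[[ev$node]] <- c(pools[[ev$node]], merged)
    } else {
      rec <- pools[[ev$recipient]]
      if (length(rec) > 0) {
        move <- stats::runif(length(rec)) < ev$fraction
        pools[[ev$donor]] <- c(pools[[ev$donor]], rec[move])
        pools[[ev$recipient]] <- rec[!move]
      }
    }
  }
  pools[[prep$root]] <- coalesce_pool(pools[[prep$root]], t_now, Inf)
  list(parent = parent, time = time, ntips = L)
}

# flat tree -> ape phylo (root renumbered to L+1)
flat_to_phylo <- function(flat, tip_labels) {
  L <- flat$ntips
  # internal node created k-th (id L+k) -> phylo id L + (L - k)
  map <- c(seq_len(L), L + rev(seq_len(L - 1L)))
  nodes <- seq_len(2L * L - 1L)[-(2L * L - 1L)]   # all but root (last made)
  edge <- cbind(map[flat$parent[nodes]], map[nodes])
  len <- flat$time[flat$parent[nodes]] - flat$time[nodes]
  phy <- structure(list(edge = edge, edge.length = len,
                        tip.label = tip_labels, Nnode = L - 1L),
                   class = "phylo")
  stats::reorder(phy, "cladewise")
}

phylo_to_flat <- function(phy) {
  L <- length(phy$tip.label)
  parent <- integer(L + phy$Nnode)
  elen <- numeric(L + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  elen[phy$edge[, 2]] <- if (is.null(phy$edge.length))
    rep(1, nrow(phy$edge)) else phy$edge.length
  list(parent = parent, edge_len = elen, ntips = L,
       tip_labels = phy$tip.label)
}

flat_edge_lengths <- function(flat) {
  if (!is.null(flat$edge_len)) return(flat$edge_len)
  el <- numeric(length(flat$parent))
  has_par <- flat$parent != 0L
  el[has_par] <- flat$time[flat$parent[has_par]] - flat$time[has_par]
  el
}

# tip sets below every node (list of integer vectors)
flat_descendants <- function(flat) {
  n <- length(flat$parent)
  L <- flat$ntips
  kids <- vector("list", n)
  for (v in seq_len(n)) {
    p <- flat$parent[v]
    if (p != 0L) kids[[p]] <- c(kids[[p]], v)
  }
  desc <- vector("list", n)
  # topological order: process nodes after their children; use DFS postorder
  root <- which(flat$parent == 0L)[1]
  stack <- root; order_out <- integer(0)
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_out <- c(order_out, v)
    stack <- c(stack, kids[[v]])
  }
  for (v in rev(order_out)) {
    desc[[v]] <- if (v <= L) v else unlist(desc[kids[[v]]])
  }
  desc
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Lineages within a species-tree branch coalesce at pairwise rate 1 per
#' coalescent time unit; at each migration pulse every lineage in the
#' recipient branch jumps to the donor branch with the pulse's migrant
#' fraction. Deterministic given `seed`.
#'
#' @param model a [species_tree_model()].
#' @param n_trees number of gene trees (>= 1).
#' @param seed RNG seed.
#' @return list of `phylo` gene trees; tips are haploid lineages labelled
#'   `<taxon>_<sample>.<1|2>` (or sample ids under ploidy 1).
#' @export
simulate_gene_trees <- function(model, n_trees, seed = 1) {
  stop_if(!inherits(model, "species_tree_model"), "malformed model")
  stop_if(n_trees < 1, "n_trees must be >= 1")
  prep <- prep_model(model)
  labels <- model_tip_labels(model)
  set.seed(seed)
  lapply(seq_len(n_trees), function(i)
    flat_to_phylo(msc_sim_once(prep), labels))
}

#' Infinite-sites mutation model
#' @param snps_per_tree expected biallelic SNP count per gene tree
#'   (Poisson mean); mutations fall on branches proportionally to length.
#' @return a `mutation_model`.
#' @export
mutation_model <- function(snps_per_tree) {
  stop_if(snps_per_tree <= 0, "expected SNP count must be > 0")
  structure(list(snps_per_tree = snps_per_tree), class = "mutation_model")
}

#' Scaffold layout assigning gene trees to coordinate blocks
#'
#' Each gene tree occupies a fixed-width block so that genomic windows cut
#' across trees, emulating recombination-driven landscape variation.
#'
#' @param n_trees number of gene trees.
#' @param block_bp block width in bp (default 10000).
#' @param trees_per_scaffold trees per scaffold (default: all on one).
#' @param scaffold_prefix scaffold name prefix (default "scaffold_").
#' @return data.frame with columns tree, scaffold, start, end (0-based
#'   half-open).
#' @export
scaffold_layout <- function(n_trees, block_bp = 10000,
                            trees_per_scaffold = n_trees,
                            scaffold_prefix = "scaffold_") {
  scaf_idx <- (seq_len(n_trees) - 1L) %/% trees_per_scaffold
  within <- (seq_len(n_trees) - 1L) %% trees_per_scaffold
  data.frame(tree = seq_len(n_trees),
             scaffold = paste0(scaffold_prefix, scaf_idx + 1L),
             start = within * block_bp,
             end = (within + 1L) * block_bp,
             stringsAsFactors = FALSE)
}

# place mutations on a list of flat trees; returns genotype_matrix
sprinkle_flat <- function(flats, tip_labels, ploidy, model, layout) {
  n_samples <- length(tip_labels) / ploidy
  samples <- if (ploidy == 2) unique(sub("\\.[12]$", "", tip_labels))
             else tip_labels
  scaf_all <- character(0); pos_all <- integer(0)
  geno_list <- list()
  for (i in seq_along(flats)) {
    flat <- flats[[i]]
    el <- flat_edge_lengths(flat)
    nodes <- which(flat$parent != 0L)
    tot <- sum(el[nodes])
    S <- stats::rpois(1, model$snps_per_tree)
    if (S == 0 || tot <= 0) next
    counts <- as.integer(stats::rmultinom(1, S, prob = el[nodes]))
    hit <- which(counts > 0)
    if (length(hit) == 0) next
    desc <- flat_descendants(flat)
    block <- layout[layout$tree == i, ]
    width <- block$end - block$start
    S_eff <- sum(counts[hit])
    if (S_eff > width) { counts <- pmin(counts, 1L); S_eff <- sum(counts[hit]) }
    pos <- sort(sample.int(width, min(S_eff, width))) + block$start
    rows <- matrix(0L, nrow = S_eff, ncol = n_samples)
    r <- 1L
    for (j in hit) {
      tips <- desc[[nodes[j]]]
      gvec <- tabulate(if (ploidy == 2) (tips + 1L) %/% 2L else tips,
                       nbins = n_samples)
      for (rep_k in seq_len(counts[j])) { rows[r, ] <- gvec; r <- r + 1L }
    }
    keep <- seq_len(length(pos))
    scaf_all <- c(scaf_all, rep(block$scaffold, length(keep)))
    pos_all <- c(pos_all, pos)   # 1-based VCF-style positions within block
    geno_list[[length(geno_list) + 1L]] <- rows[keep, , drop = FALSE]
  }
  stop_if(length(geno_list) == 0, "no mutations produced; increase rate")
  geno <- do.call(rbind, geno_list)
  colnames(geno) <- samples
  ord <- order(scaf_all, pos_all)
  genotype_matrix(scaf_all[ord], pos_all[ord], geno[ord, , drop = FALSE],
                  ref = rep("A", length(pos_all)),
                  alt = rep("T", length(pos_all)))
}

#' Sprinkle infinite-sites mutations onto gene trees
#'
#' Each mutation defines one biallelic SNP whose derived allele is carried
#' by exactly the tips below the mutated branch; haploid tips are paired
#' into diploid genotypes. Deterministic given `seed`.
#'
#' @param trees list of `phylo` gene trees (e.g. from
#'   [simulate_gene_trees()]); all trees share one tip label set.
#' @param model a [mutation_model()].
#' @param layout a [scaffold_layout()] covering `length(trees)` trees.
#' @param seed RNG seed.
#' @param ploidy 2 if tips are haploid lineage pairs `sample.1/.2`, 1 for
#'   haploid samples.
#' @return a [genotype_matrix()].
#' @export
sprinkle_mutations <- function(trees, model, layout, seed = 1, ploidy = 2) {
  stop_if(length(trees) == 0, "empty tree list")
  stop_if(!inherits(model, "mutation_model"), "model must be mutation_model")
  set.seed(seed)
  flats <- lapply(trees, phylo_to_flat)
  sprinkle_flat(flats, flats[[1]]$tip_labels, ploidy, model, layout)
}

#' Simulate a genotype matrix in one pass
#'
#' Runs the coalescent and mutation sprinkling without materialising
#' `phylo` objects; used for large calibration simulations. Identical
#' model semantics to [simulate_gene_trees()] + [sprinkle_mutations()].
#'
#' @inheritParams simulate_gene_trees
#' @param mut a [mutation_model()].
#' @param layout a [scaffold_layout()]; default one 10-kb block per tree.
#' @return a [genotype_matrix()] with samples named `<taxon>_<i>`.
#' @export
simulate_genotypes <- function(model, n_trees, mut, layout = NULL,
                               seed = 1) {
  prep <- prep_model(model)
  labels <- model_tip_labels(model)
  if (is.null(layout)) layout <- scaffold_layout(n_trees)
  set.seed(seed)
  flats <- lapply(seq_len(n_trees), function(i) msc_sim_once(prep))
  sprinkle_flat(flats, labels, model$ploidy, mut, layout)
}

#' Population map implied by a species tree model
#' @param model a [species_tree_model()].
#' @return named character vector: taxon keyed by sample id.
#' @export
model_popmap <- function(model) {
  samples <- model_samples(model)
  stats::setNames(sub("_[0-9]+$", "", samples), samples)
}
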