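test_that("normalized RF: identity, maximum, and hand example", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  expect_equal(rf_normalized(t1, t1), 0)
  t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  expect_equal(rf_normalized(t1, t2), 1)   # both splits conflict
  # two binary 5-tip trees sharing no internal splits
  t3 <- ape::read.tree(text = "((a,b),((c,d),e));")
  t4 <- ape::read.tree(text = "((a,c),((b,e),d));")
  expect_equal(rf_normalized(t3, t4), 1)
  expect_error(rf_normalized(ape::read.tree(text = "(a,(b,c));"),
                             ape::read.tree(text = "(a,(b,c));")),
               ">= 4")
})

test_that("normalized RF agrees with phangorn on random binary trees", {
  skip_if_not_installed("phangorn")
  labels <- letters[1:8]
  for (seed in 1:10) {
    ta <- rand_tree(labels, seed)
    tb <- rand_tree(labels, seed + 100)
    expect_equal(rf_normalized(ta, tb),
                 phangorn::RF.dist(ape::unroot(ta), ape::unroot(tb),
                                   normalize = TRUE))
  }
})

test_that("RF is a metric on random tree triples", {
  labels <- letters[1:6]
  set.seed(42)
  for (i in 1:25) {
    ta <- rand_tree(labels); tb <- rand_tree(labels); tc <- rand_tree(labels)
    dab <- rf_normalized(ta, tb)
    dba <- rf_normalized(tb, ta)
    expect_equal(dab, dba)                       # symmetry
    expect_equal(rf_normalized(ta, ta), 0)       # identity
    expect_lte(dab, rf_normalized(ta, tc) + rf_normalized(tc, tb) + 1e-12)
  }
})

test_that("topology weights: worked two-tip example and exact mode", {
  tr <- ape::read.tree(text = "(((a1,b),(a2,c)),o);")
  tm <- c(a1 = "A", a2 = "A", b = "B", c = "C", o = "O")
  w <- topology_weights(tr, tm)
  expect_equal(w$method, "exact")
  expect_equal(w$n_combinations_evaluated, 2)
  expect_equal(sum(w$weights), 1, tolerance = 1e-12)
  # weight(AB|CO) = 0.5, weight(AC|BO) = 0.5, weight(BC|AO) = 0
  expect_equal(internal_branch_weights(w, c("A", "B")), 0.5)
  expect_equal(internal_branch_weights(w, c("A", "C")), 0.5)
  expect_equal(internal_branch_weights(w, c("B", "C")), 0)

  # single sample per taxon, tree matching T -> weight(T) = 1
  tr1 <- ape::read.tree(text = "(((a,b),c),o);")
  w1 <- topology_weights(tr1, stats::setNames(c("A", "B", "C", "O"),
                                              c("a", "b", "c", "o")))
  expect_equal(unname(w1$weights), 1)
  expect_equal(internal_branch_weights(w1, c("A", "B")), 1)
  expect_error(topology_weights(tr1, c(a = "A", b = "B", c = "C", o = "O"),
                                taxa = c("A", "B", "Z")), "zero tips")
})

test_that("exact weights equal brute-force enumeration via an RF oracle", {
  skip_if_not_installed("phangorn")
  taxa <- c("A", "B", "C", "O")
  cand <- list(AB = ape::read.tree(text = "((A,B),(C,O));"),
               AC = ape::read.tree(text = "((A,C),(B,O));"),
               BC = ape::read.tree(text = "((B,C),(A,O));"))
  set.seed(8)
  for (rep in 1:5) {
    # random sample tree with 2-4 tips per taxon
    counts <- sample(2:4, 4, replace = TRUE)
    tips <- unlist(mapply(function(tx, k) paste0(tolower(tx), seq_len(k)),
                          taxa, counts, SIMPLIFY = FALSE))
    tm <- stats::setNames(rep(taxa, counts), tips)
    tr <- rand_tree(tips)
    w <- topology_weights(tr, tm)
    expect_equal(sum(w$weights), 1, tolerance = 1e-12)
    # brute force: every one-tip-per-taxon combination, matched to the
    # three candidate quartets with phangorn
    combos <- expand.grid(split(names(tm), unname(tm)),
                          stringsAsFactors = FALSE)
    hits <- c(AB = 0, AC = 0, BC = 0)
    for (i in seq_len(nrow(combos))) {
      sub <- ape::keep.tip(tr, unlist(combos[i, ]))
      sub$tip.label <- unname(tm[sub$tip.label])
      for (k in names(cand))
        if (phangorn::RF.dist(ape::unroot(sub), ape::unroot(cand[[k]])) == 0)
          hits[k] <- hits[k] + 1
    }
    bf <- hits / nrow(combos)
    expect_equal(internal_branch_weights(w, c("A", "B")), unname(bf["AB"]))
    expect_equal(internal_branch_weights(w, c("A", "C")), unname(bf["AC"]))
    expect_equal(internal_branch_weights(w, c("B", "C")), unname(bf["BC"]))
  }
})

test_that("sampled weights are deterministic and converge to exact", {
  tips <- c(paste0("a", 1:4), paste0("b", 1:4), paste0("c", 1:4),
            paste0("o", 1:4))
  tm <- stats::setNames(rep(c("A", "B", "C", "O"), each = 4), tips)
  tr <- rand_tree(tips, seed = 12)
  ws1 <- topology_weights(tr, tm, max_exact = 10, n_samples = 400, seed = 5)
  ws2 <- topology_weights(tr, tm, max_exact = 10, n_samples = 400, seed = 5)
  expect_equal(ws1$weights, ws2$weights)
  expect_equal(ws1$method, "sampled")
  we <- topology_weights(tr, tm)   # exact (256 combinations)
  for (k in names(we$weights)) {
    se <- max(ws1$mc_se[k], 1e-3, na.rm = TRUE)
    got <- if (k %in% names(ws1$weights)) ws1$weights[[k]] else 0
    expect_lt(abs(got - we$weights[[k]]), 4 * se + 0.05)
  }
})

test_that("five-taxon internal-branch weight sums enumerate clades", {
  # window tree equal to the species tree, single samples: all internal
  # branch weights are 1
  sp <- ape::read.tree(text = "((((a,b),c),(d,e)),o);")
  tm <- stats::setNames(c("A", "B", "C", "D", "E", "O"),
                        c("a", "b", "c", "d", "e", "o"))
  w <- topology_weights(sp, tm)
  expect_equal(internal_branch_weights(w, c("A", "B")), 1)
  expect_equal(internal_branch_weights(w, c("A", "B", "C")), 1)
  expect_equal(internal_branch_weights(w, c("D", "E")), 1)
  expect_equal(internal_branch_weights(w, c("A", "C")), 0)
  # two samples in one taxon placed discordantly: the clade-containing
  # topologies' weights sum
  tr <- ape::read.tree(text = "((((a1,b),c),((a2,b2),(d,e))),o);")
  tm2 <- stats::setNames(c("A", "A", "B", "B", "C", "D", "E", "O"),
                         c("a1", "a2", "b", "b2", "c", "d", "e", "o"))
  w2 <- topology_weights(tr, tm2)
  expect_equal(sum(w2$weights), 1, tolerance = 1e-12)
  ib <- internal_branch_weights(w2, c("A", "B"))
  # brute force over the 4 combinations by hand: a1/b and a2/b2 pair up
  # as (A,B) clades in 2 of 4 combinations
  expect_equal(ib, 0.5)
})

test_that("gene concordance factors count decisive trees", {
  sp <- ape::read.tree(text = "(((a,b),c),d);")
  conc <- ape::read.tree(text = "(((a,b),c),d);")
  disc <- ape::read.tree(text = "(((a,c),b),d);")
  g1 <- gene_concordance(rep(list(conc), 4), sp)
  expect_true(all(g1$gCF == 100))
  g2 <- gene_concordance(c(rep(list(conc), 3), list(disc)), sp)
  ab <- g2[g2$clade == "a,b", ]
  expect_equal(ab$gCF, 75)
  expect_equal(ab$n_decisive, 4)
  # a gene tree missing one side of the branch is not decisive for it
  partial <- ape::read.tree(text = "((a,c),d);")   # no b tip
  g3 <- gene_concordance(c(rep(list(conc), 2), list(partial)), sp)
  expect_equal(g3[g3$clade == "a,b", "n_decisive"], 2)
})

test_that("site concordance factors from constructed alignments", {
  sp <- ape::read.tree(text = "(((a,b),c),d);")
  mk <- function(pats) {
    m <- do.call(cbind, pats)
    stats::setNames(apply(m, 1, paste, collapse = ""), c("a", "b", "c", "d"))
  }
  conc_site <- c("A", "A", "T", "T")
  dis1_site <- c("A", "T", "A", "T")
  dis2_site <- c("A", "T", "T", "A")
  aln_conc <- mk(rep(list(conc_site), 12))
  s1 <- site_concordance(aln_conc, sp, n_quartets = 5, seed = 1)
  expect_true(all(s1$sCF == 100))
  aln_mix <- mk(c(rep(list(conc_site), 10), rep(list(dis1_site), 10),
                  rep(list(dis2_site), 10)))
  s2 <- site_concordance(aln_mix, sp, n_quartets = 5, seed = 1)
  expect_equal(s2$sCF[1], 100 * 10 / 30, tolerance = 1e-9)
  aln_inv <- mk(rep(list(c("A", "A", "A", "A")), 12))
  s3 <- site_concordance(aln_inv, sp, n_quartets = 5, seed = 1)
  expect_true(all(is.na(s3$sCF)))
})
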