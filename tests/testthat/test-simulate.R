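test_that("MSC gene-tree topology frequencies match the closed form", {
  # 3-taxon tree with internal branch t = 0.5: discordant triplets each
  # at (1/3) exp(-t)
  spt <- ape::read.tree(text = "((A:1,B:1):0.5,C:1.5);")
  m <- species_tree_model(spt, 1, ploidy = 1)
  trees <- simulate_gene_trees(m, 3000, seed = 11)
  conc <- vapply(trees, function(t) {
    d <- ape::node.depth.edgelength(t)
    d[ape::getMRCA(t, c("A_1", "B_1"))] >
      d[ape::getMRCA(t, c("A_1", "C_1"))]
  }, logical(1))
  expected <- 1 - (2 / 3) * exp(-0.5)
  expect_lt(abs(mean(conc) - expected), 0.03)

  # infinite internal branch: all trees concordant
  spt_inf <- ape::read.tree(text = "((A:1,B:1):50,C:51);")
  m_inf <- species_tree_model(spt_inf, 1, ploidy = 1)
  trees_inf <- simulate_gene_trees(m_inf, 200, seed = 3)
  conc_inf <- vapply(trees_inf, function(t) {
    d <- ape::node.depth.edgelength(t)
    d[ape::getMRCA(t, c("A_1", "B_1"))] >
      d[ape::getMRCA(t, c("A_1", "C_1"))]
  }, logical(1))
  expect_true(all(conc_inf))
})

test_that("simulation is deterministic under a fixed seed", {
  spt <- ape::read.tree(text = "((A:1,B:1):0.5,C:1.5);")
  m <- species_tree_model(spt, 2)
  t1 <- simulate_gene_trees(m, 5, seed = 99)
  t2 <- simulate_gene_trees(m, 5, seed = 99)
  expect_equal(lapply(t1, ape::write.tree), lapply(t2, ape::write.tree))
  gm1 <- simulate_genotypes(m, 20, mutation_model(10), seed = 7)
  gm2 <- simulate_genotypes(m, 20, mutation_model(10), seed = 7)
  expect_equal(gm1$geno, gm2$geno)
  expect_equal(gm1$pos, gm2$pos)
})

test_that("migration pulse validation", {
  spt <- ape::read.tree(text = "(((P1:1,P2:1):0.5,P3:1.5):1,O:2.5);")
  expect_error(migration_pulse("P3", "P2", 0.5, 1.5), "\\[0,1\\]")
  expect_error(migration_pulse("P2", "P2", 0.5, 0.1), "differ")
  # pulse outside the recipient branch lifetime
  expect_error(species_tree_model(
    spt, 1, migrations = list(migration_pulse("P3", "P2", 1.2, 0.1))),
    "lifetime")
  # valid pulse constructs fine
  m <- species_tree_model(
    spt, 1, migrations = list(migration_pulse("P3", "P2", 0.5, 0.1)))
  expect_s3_class(m, "species_tree_model")
})

test_that("mutations land on branches and map to carriers (infinite sites)", {
  # hand-built tree: mutation above the {a_1.1, a_1.2} cherry must give
  # sample a_1 genotype 2 and b_1 genotype 0
  tr <- ape::read.tree(
    text = "((a_1.1:0.1,a_1.2:0.1):5,(b_1.1:0.1,b_1.2:0.1):5);")
  layout <- scaffold_layout(1)
  gm <- sprinkle_mutations(list(tr), mutation_model(50), layout, seed = 2)
  expect_setequal(colnames(gm$geno), c("a_1", "b_1"))
  # with tip branches of length 0.1 vs internal 5, nearly all sites are
  # fixed differences between the two samples; all genotypes in {0,2}
  fixed <- gm$geno[, "a_1"] + gm$geno[, "b_1"]
  expect_true(all(gm$geno %in% c(0L, 2L, 1L)))
  expect_gt(mean((gm$geno[, "a_1"] == 2 & gm$geno[, "b_1"] == 0) |
                   (gm$geno[, "a_1"] == 0 & gm$geno[, "b_1"] == 2)), 0.9)
  expect_false(is.unsorted(gm$pos))

  # zero-length branches are never mutated
  tr0 <- ape::read.tree(text = "((a_1.1:0,a_1.2:0):1,(b_1.1:1,b_1.2:1):0);")
  gm0 <- sprinkle_mutations(list(tr0), mutation_model(200),
                            scaffold_layout(1), seed = 4)
  # no site can separate a_1.1 from a_1.2 (their branches have length 0)
  expect_false(any(gm0$geno[, "a_1"] == 1L))
  expect_error(sprinkle_mutations(list(), mutation_model(10),
                                  scaffold_layout(1)), "empty")
})

test_that("SNP counts are Poisson-distributed around the expectation", {
  spt <- ape::read.tree(text = "((A:1,B:1):0.5,C:1.5);")
  m <- species_tree_model(spt, 1)
  tot <- vapply(1:30, function(s)
    nrow(simulate_genotypes(m, 10, mutation_model(10), seed = s)$geno), 1)
  # mean 100 per replicate; 30 replicates give SE ~ sqrt(100/30) ~ 1.8
  expect_lt(abs(mean(tot) - 100), 8)
  expect_gt(stats::var(tot), 30)   # not degenerate
})

test_that("no-migration D is null; pulse recovers the migrant fraction", {
  spt <- ape::read.tree(text = "(((P1:1,P2:1):0.3,P3:1.3):1.2,O:2.5);")
  pm <- stats::setNames(rep(c("P1", "P2", "P3", "O"), each = 2),
                        paste0(rep(c("P1", "P2", "P3", "O"), each = 2),
                               "_", rep(1:2, 4)))
  m0 <- species_tree_model(spt, 2)
  d0 <- vapply(1:12, function(s) {
    gm <- simulate_genotypes(m0, 150, mutation_model(60), seed = 100 + s)
    d_statistic(site_patterns(gm, pm, c("P1", "P2", "P3", "O")))
  }, numeric(1))
  expect_lt(abs(mean(d0)), 3 * stats::sd(d0) / sqrt(length(d0)))

  m1 <- species_tree_model(
    spt, 2, migrations = list(migration_pulse("P3", "P2", 0.3, 0.2)))
  f4 <- vapply(1:12, function(s) {
    gm <- simulate_genotypes(m1, 200, mutation_model(80), seed = 200 + s)
    f4_ratio(gm, pm, c("P1", "P2", "P3", "O"))
  }, numeric(1))
  expect_gt(mean(f4), 0.05)   # clearly positive under the pulse
  expect_lt(abs(mean(f4) - 0.2), 0.1)
})

test_that("CDS fixtures carry exactly the injected mutations", {
  ref <- random_cds(200, seed = 6)
  specs <- list(lof_spec("frameshift_insertion", 120, 4),
                lof_spec("large_deletion", 60, 120))
  set <- make_cds_fixture(ref, exons = data.frame(start = c(1, 301),
                                                  end = c(300, 600)),
                          specs = specs, seed = 1, n_clean = 2)
  aln <- set$aln
  expect_equal(length(aln), 5)   # reference + 2 mutants + 2 clean
  # the insertion adds 4 columns gapped in the reference row
  expect_equal(nchar(aln[["reference"]]), 604)
  expect_equal(lengths(regmatches(aln[["reference"]],
                                  gregexpr("-", aln[["reference"]]))), 4)
  # the deletion row has 120 gaps plus the 4 insertion columns
  del_row <- aln[["mut2_large_deletion"]]
  expect_equal(lengths(regmatches(del_row, gregexpr("-", del_row))), 124)
  # clean copies are identical to the reference row
  expect_equal(aln[["clean_1"]], aln[["reference"]])
  # empty spec list -> identical copies
  set0 <- make_cds_fixture(ref, specs = list(), n_clean = 3)
  expect_true(all(set0$aln == set0$aln[[1]]))
  expect_error(make_cds_fixture(ref, specs = list(
    lof_spec("large_deletion", 9999, 10))), "outside")
})
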