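test_that("protein distances follow the p / Poisson models", {
  s <- strrep("MKVLAWHQST", 3)
  expect_equal(protein_distance(s, s, "p"), 0)
  expect_equal(protein_distance(s, s, "poisson"), 0)
  a <- strrep("A", 10); b <- paste0(strrep("A", 9), "C")
  expect_equal(protein_distance(a, b, "p"), 0.1)
  expect_equal(protein_distance(a, b, "poisson"), -log(0.9))
  expect_equal(protein_distance(a, b), protein_distance(b, a))
})

test_that("NJ recovers additive trees exactly", {
  # known 4-taxon tree: ((A:1,B:2):1,(C:3,D:4):2)
  lab <- c("A", "B", "C", "D")
  dm <- matrix(0, 4, 4, dimnames = list(lab, lab))
  dm["A", "B"] <- dm["B", "A"] <- 3
  dm["A", "C"] <- dm["C", "A"] <- 1 + 1 + 2 + 3
  dm["A", "D"] <- dm["D", "A"] <- 1 + 1 + 2 + 4
  dm["B", "C"] <- dm["C", "B"] <- 2 + 1 + 2 + 3
  dm["B", "D"] <- dm["D", "B"] <- 2 + 1 + 2 + 4
  dm["C", "D"] <- dm["D", "C"] <- 7
  tr <- build_nj_tree(dm, root = FALSE)
  truth <- ape::read.tree(text = "((A:1,B:2):3,C:3,D:4);")
  expect_equal(ape::dist.topo(tr, truth), 0, ignore_attr = TRUE)
  # branch lengths: patristic distances reproduce the input matrix
  expect_equal(ape::cophenetic.phylo(tr)[lab, lab], dm, tolerance = 1e-10)

  expect_error(build_nj_tree(dm[1:2, 1:2]), "at least 3")
  asym <- dm; asym[1, 2] <- 99
  expect_error(build_nj_tree(asym), "symmetric")

  # input-order invariance
  perm <- c("C", "A", "D", "B")
  tr2 <- build_nj_tree(dm[perm, perm], root = FALSE)
  expect_equal(ape::dist.topo(tr, tr2), 0, ignore_attr = TRUE)
})

test_that("NJ on true simulator distances reproduces the true topology", {
  fam <- simulate_family(8, 0.02, 0.02, 36, seed = 12)
  tr_true <- fam$tree
  # additive distances straight from the true tree (unit branch lengths)
  tr_bl <- ape::compute.brlen(tr_true, 1)
  dm <- ape::cophenetic.phylo(tr_bl)
  tr_nj <- build_nj_tree(dm, root = FALSE)
  expect_equal(ape::dist.topo(tr_nj, ape::unroot(tr_bl)), 0,
               ignore_attr = TRUE)
})

test_that("bootstrap support is seeded and saturates on congruent data", {
  set.seed(2)
  block <- function(ch, n) strrep(ch, n)
  # four taxa, two clean groups; every variable column supports the same
  # split and a constant block keeps distances off saturation
  aln <- c(a1 = paste0(block("A", 30), block("M", 30)),
           a2 = paste0(block("A", 30), block("M", 30)),
           b1 = paste0(block("W", 30), block("M", 30)),
           b2 = paste0(block("W", 30), block("M", 30)))
  bs <- bootstrap_support(aln, reps = 50, seed = 7)
  inner <- bs$support[!is.na(bs$support)]
  expect_true(all(inner == 100))
  bs2 <- bootstrap_support(aln, reps = 50, seed = 7)
  expect_identical(bs$support, bs2$support)
  expect_error(bootstrap_support(aln, reps = 0), "reps")
})

test_that("species-overlap labels match hand reconciliations", {
  t1 <- reconcile_species_overlap(tree_from_text("(P|a,T|b);"))
  expect_equal(t1$node.label, "speciation")
  # root children are {P} and {T}: disjoint, so the root is a speciation
  # and the inner cherry a lineage-specific duplication
  t2 <- reconcile_species_overlap(tree_from_text("((P|a,P|b),T|c);"))
  expect_equal(t2$node.label, c("speciation", "duplication_lineage"))
  t3 <- reconcile_species_overlap(tree_from_text("((P|a,T|b),(P|c,T|d));"))
  expect_equal(t3$node.label[1], "duplication_ancestral")
  expect_equal(t3$node.label[2:3], c("speciation", "speciation"))
  expect_error(
    reconcile_species_overlap(tree_from_text("((P|a,T|b),(Q|c,R|d));")),
    "at most 2 species")
  expect_warning(
    reconcile_species_overlap(tree_from_text("(P|a,P|b,T|c);")),
    "polytomies|midpoint")
})

test_that("gain/loss inference matches hand counts", {
  g1 <- infer_gain_loss(tree_from_text("((P|a,T|b),(P|c,T|d));"))
  expect_equal(g1$units, 2)
  expect_equal(g1$summary$gains, c(0, 0))
  expect_equal(g1$summary$losses, c(0, 0))
  expect_equal(g1$summary$extant, c(2, 2))

  g2 <- infer_gain_loss(tree_from_text("((P|a,T|b),P|c);"))
  expect_equal(g2$units, 2)
  expect_equal(g2$summary$losses[g2$summary$species == "T"], 1)
  expect_equal(g2$summary$gains, c(0, 0))

  g3 <- infer_gain_loss(tree_from_text("((P|a,P|b),T|c);"))
  expect_equal(g3$units, 1)
  expect_equal(g3$summary$gains[g3$summary$species == "P"], 1)
  expect_equal(g3$summary$extant[g3$summary$species == "P"], 2)
})

test_that("units partition the leaves and the identity holds on random trees", {
  for (s in 1:40) {
    fam <- simulate_family(6, 0.03, 0.03, 30, seed = 100 + s)
    if (is.null(fam$tree)) next
    gl <- infer_gain_loss(fam$tree)
    expect_equal(sort(unlist(gl$unit_leaves)), sort(fam$tree$tip.label))
    with(gl$summary,
         expect_equal(extant, mrca_units - losses + gains))
  }
})

test_that("gainloss_from_counts solves the published lineage numbers", {
  expect_equal(gainloss_from_counts(mrca = 55, losses = 13, extant = 59), 17)
  expect_equal(gainloss_from_counts(mrca = 55, losses = 11, extant = 57), 13)
  expect_equal(gainloss_from_counts(mrca = 7, losses = 1, gains = 0), 6)
  expect_error(gainloss_from_counts(mrca = 10, losses = 0, extant = 5),
               "inconsistent")
  expect_error(gainloss_from_counts(mrca = 1, losses = 1), "exactly one")
})
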