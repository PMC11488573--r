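test_that("newick parsing reads lengths and round-trips", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tr) + tr$Nnode, 5)
  expect_equal(sum(tr$edge.length), 5)
  t1 <- parse_newick("(A:1);")
  expect_equal(ape::Ntip(t1), 1)
  expect_equal(sum(t1$edge.length), 1)

  set.seed(31)
  tr2 <- random_test_tree(50)
  back <- parse_newick(write_newick(tr2))
  expect_equal(sort(back$tip.label), sort(tr2$tip.label))
  ## topology via bipartitions and distances via the patristic matrix
  expect_equal(as.matrix(ape::cophenetic.phylo(back))[tr2$tip.label, tr2$tip.label],
               as.matrix(ape::cophenetic.phylo(tr2)), tolerance = 1e-8)
})

test_that("malformed newick and missing branch lengths are rejected", {
  expect_error(parse_newick("((A:1,B:1):1,C:2))));"), "offset")
  expect_error(parse_newick("((A:1,B:1):1,C:2)"), "';'")
  expect_error(parse_newick("((A,B):1,C:2);"), "branch length")
  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicate")
})

test_that("tip-name normalization treats spaces and underscores alike", {
  tr <- parse_newick("((Vicia_cracca:1,Vicia_sepium:1):1,Quercus_robur:2);")
  expect_equal(faith_pd(tr, c("Vicia cracca", "Vicia_sepium")), 3)
  expect_equal(genus_of("Vicia cracca"), "Vicia")
})

test_that("pruning preserves patristic distances among kept tips", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(patristic_matrix(prune_to_taxa(tr, c("A", "C")),
                                c("A", "C"))["A", "C"], 4)
  expect_identical(prune_to_taxa(tr, c("A", "B", "C"))$tip.label, tr$tip.label)
  expect_error(prune_to_taxa(tr, c("A", "Z")), "Z")

  set.seed(101)
  for (rep in 1:25) {
    tr <- random_test_tree(sample(8:30, 1))
    keep <- random_subset(tr, sample(2:6, 1))
    pr <- prune_to_taxa(tr, keep)
    expect_setequal(pr$tip.label, keep)
    D_pre <- patristic_matrix(tr, keep)
    D_post <- patristic_matrix(pr, keep)
    expect_equal(D_post[keep, keep], D_pre[keep, keep], tolerance = 1e-9)
    expect_lte(sum(pr$edge.length), sum(tr$edge.length) + 1e-9)
  }
})

test_that("patristic matrix matches path-walk oracle and ape", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  D <- patristic_matrix(tr, c("A", "B", "C"))
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(unname(diag(D)), c(0, 0, 0))
  expect_identical(dim(patristic_matrix(tr, "A")), c(1L, 1L))
  expect_equal(patristic_matrix(tr, "A")[1, 1], 0)
  expect_error(patristic_matrix(tr, character(0)), "non-empty")

  set.seed(77)
  tr <- random_test_tree(30)
  taxa <- tr$tip.label
  D <- patristic_matrix(tr, taxa)
  expect_equal(D, t(D))
  Dape <- as.matrix(ape::cophenetic.phylo(tr))[taxa, taxa]
  expect_equal(D, Dape, tolerance = 1e-9)
  for (k in 1:15) {
    ab <- sample(taxa, 2)
    expect_equal(D[ab[1], ab[2]], oracle_patristic(tr, ab[1], ab[2]),
                 tolerance = 1e-9)
  }
})

test_that("grafting places new species at the expected depths", {
  traits <- data.frame(
    species = c("Gen_a", "Oth_b", "Far_c", "Gen_new"),
    genus = c("Gen", "Oth", "Far", "Gen"),
    family = c("FamA", "FamA", "FamB", "FamA"),
    is_fixer = c(1, 0, 0, 1))
  tr <- parse_newick("((Gen_a:50,Oth_b:50):50,Far_c:100);")

  ## grafting an already-present species is a no-op
  same <- graft_missing(tr, traits[1:3, ])
  expect_identical(same$tip.label, tr$tip.label)

  ## single congener at depth 100 -> cherry, new tip depth = 100
  g <- graft_missing(tr, traits)
  expect_true("Gen_new" %in% g$tip.label)
  d <- node_depths(g)[match("Gen_new", g$tip.label)]
  expect_equal(d, 100, tolerance = 1e-12)
  ## the cherry splits the stem at its midpoint: Gen_a/Gen_new distance 50
  expect_equal(patristic_matrix(g, c("Gen_a", "Gen_new"))[1, 2], 50)

  ## species with neither genus nor family in the tree errors by name
  orphan <- rbind(traits[1:3, ],
                  data.frame(species = "Alien_z", genus = "Alien",
                             family = "FamZ", is_fixer = 0))
  expect_error(graft_missing(tr, orphan), "Alien_z")
})

test_that("grafting preserves ultrametricity and earlier distances", {
  set.seed(202)
  tr <- random_test_tree(100)
  taxa <- assign_fixer_clades(tr, 2, 0.1)
  tt <- taxa$traits
  add <- data.frame(species = paste0(tt$genus[1:10], "_x", 1:10),
                    genus = tt$genus[1:10], family = tt$family[1:10],
                    is_fixer = as.integer(tt$is_fixer[1:10]))
  g <- graft_missing(taxa$tree, rbind(tt, add))
  expect_equal(ape::Ntip(g), 110)
  expect_true(is_ultrametric_tree(g, 1e-9))

  ## graft-then-prune round trip recovers the original distances exactly
  back <- prune_to_taxa(g, taxa$tree$tip.label)
  D0 <- patristic_matrix(taxa$tree, taxa$tree$tip.label)
  D1 <- patristic_matrix(back, taxa$tree$tip.label)
  expect_equal(D1[rownames(D0), colnames(D0)], D0, tolerance = 1e-10)

  ## grafting order does not change placements
  g2 <- graft_missing(taxa$tree, rbind(tt, add)[sample(110), ])
  Da <- patristic_matrix(g, g$tip.label)
  Db <- patristic_matrix(g2, g$tip.label)[rownames(Da), colnames(Da)]
  expect_equal(Da, Db, tolerance = 1e-10)
})

test_that("trait table validation enforces genus-constant fixer status", {
  bad <- data.frame(species = c("A_x", "A_y"), genus = "A",
                    family = "F", is_fixer = c(0, 1))
  expect_error(validate_traits(bad), "varies within genus")
  bad2 <- data.frame(species = "A_x", genus = "", family = "F", is_fixer = 1)
  expect_error(validate_traits(bad2), "non-empty")
})
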