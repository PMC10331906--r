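test_that("parse_newick reads topologies, polytomies, and rejects bad input", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(ape::Ntip(tr), 3L)

  star <- parse_newick("(A:1,B:1,C:1);")
  expect_equal(ape::Ntip(star), 3L)
  expect_equal(star$Nnode, 1L)  # single basal polytomy

  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicate tip label")
  expect_error(parse_newick("((A:1,B:1:1,C:2);"), "offset")
  expect_error(parse_newick("(A:1,B:1)"), "offset")
  expect_error(parse_newick("((A:1,B:-1):1,C:2);"), "negative")
})

test_that("newick round trip preserves topology and branch lengths", {
  set.seed(11)
  for (i in 1:10) {
    tr <- random_labeled_tree(8)
    tr2 <- parse_newick(serialize_newick(tr))
    expect_equal(sort(oracle_clade_keys(tr2)), sort(oracle_clade_keys(tr)))
    V1 <- phylo_vcv(tr); V2 <- phylo_vcv(tr2)
    expect_equal(V2[rownames(V1), colnames(V1)], unclass(V1)[, ],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("read_tree_set preserves order and enforces a shared taxon set", {
  set.seed(3)
  trees <- replicate(12, random_labeled_tree(6), simplify = FALSE)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(vapply(trees, serialize_newick, character(1)), f)
  ts <- read_tree_set(f, "newick")
  expect_length(ts, 12L)
  expect_equal(sort(ts[[5]]$tip.label), sort(trees[[5]]$tip.label))

  bad <- trees
  bad[[7]] <- ape::rtree(6)
  bad[[7]]$tip.label <- sprintf("x%02d", 1:6)
  writeLines(vapply(bad, serialize_newick, character(1)), f)
  expect_error(read_tree_set(f, "newick"), "tree 7")
})

test_that("read_tree_set resolves a NEXUS TRANSLATE table", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c(
    "#NEXUS", "BEGIN TREES;",
    "  TRANSLATE", "    1 Parus_major,", "    2 Turdus_merula,",
    "    3 Sylvia_atricapilla;",
    "  TREE one = ((1:1.0,2:1.0):1.0,3:2.0);",
    "  TREE two = ((1:1.0,3:1.0):1.0,2:2.0);",
    "END;"), f)
  ts <- read_tree_set(f, "nexus")
  expect_length(ts, 2L)
  expect_setequal(ts[[1]]$tip.label,
                  c("Parus_major", "Turdus_merula", "Sylvia_atricapilla"))
})

test_that("prune_to_taxa preserves root-to-tip distances", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  pr <- prune_to_taxa(tr, c("A", "C"))
  expect_equal(ape::Ntip(pr), 2L)
  V <- phylo_vcv(pr, order = c("A", "C"))
  expect_equal(unclass(V), matrix(c(2, 0, 0, 2), 2, 2,
                                  dimnames = list(c("A", "C"), c("A", "C"))),
               ignore_attr = TRUE)
  expect_equal(prune_to_taxa(tr, c("A", "B", "C")), tr)
  expect_error(prune_to_taxa(tr, "A"), "at least 2")
  expect_error(prune_to_taxa(tr, c("A", "Z")), "Z")
})

test_that("phylo_vcv matches hand-derived matrices and the path-sum oracle", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  V <- phylo_vcv(tr, order = c("A", "B", "C"))
  expect_equal(unclass(V), matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
                                  dimnames = list(c("A", "B", "C"),
                                                  c("A", "B", "C"))),
               ignore_attr = TRUE)
  star <- parse_newick("(A:1,B:1,C:1);")
  Vs <- phylo_vcv(star)
  expect_equal(unclass(Vs), diag(3), ignore_attr = TRUE)

  set.seed(7)
  for (i in 1:20) {
    rt <- random_labeled_tree(8)
    V <- phylo_vcv(rt)
    O <- oracle_vcv(rt)
    expect_equal(unclass(V), O[rownames(V), colnames(V)],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("ultrametric trees give a constant vcv diagonal", {
  tr <- simulate_yule_tree(30, 1, seed = 5)
  d <- diag(phylo_vcv(tr))
  expect_lt(diff(range(d)), 1e-9)
})

test_that("pruning then vcv equals subsetting the full vcv", {
  set.seed(13)
  for (i in 1:10) {
    tr <- random_labeled_tree(10)
    keep <- sample(tr$tip.label, 5)
    V_full <- phylo_vcv(tr)
    V_sub <- phylo_vcv(prune_to_taxa(tr, keep), order = keep)
    expect_equal(unclass(V_sub), unclass(V_full)[keep, keep],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("lambda_transform scales off-diagonals only, once, within bounds", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  V <- phylo_vcv(tr, order = c("A", "B", "C"))
  expect_equal(unclass(lambda_transform(V, 1)), unclass(V), ignore_attr = TRUE)
  W0 <- lambda_transform(V, 0)
  expect_equal(unclass(W0), diag(c(2, 2, 2)), ignore_attr = TRUE)
  Wh <- lambda_transform(V, 0.5)
  expect_equal(Wh["A", "B"], 0.5, ignore_attr = TRUE)
  expect_equal(diag(Wh), diag(V), ignore_attr = TRUE)
  # entrywise linearity in lambda off the diagonal
  lams <- c(0.2, 0.4, 0.8)
  offs <- vapply(lams, function(l) lambda_transform(V, l)["A", "B"], numeric(1))
  expect_equal(offs, lams * V["A", "B"], ignore_attr = TRUE)
  expect_error(lambda_transform(Wh, 0.3), "already")
  expect_error(lambda_transform(V, 1.2), "\\[0, 1\\]")
  expect_error(lambda_transform(V, -0.1), "\\[0, 1\\]")
  expect_silent(lambda_transform(V, 1.2, lambda_max = 1.5))
})

test_that("maximum_clade_credibility picks the majority topology, lowest index on ties", {
  set.seed(21)
  base <- random_labeled_tree(6)
  alt <- random_labeled_tree(6, labels = base$tip.label)
  while (identical(sort(oracle_clade_keys(alt)), sort(oracle_clade_keys(base)))) {
    alt <- random_labeled_tree(6, labels = base$tip.label)
  }
  trees <- c(alt, base, base, base)
  class(trees) <- "multiPhylo"
  res <- maximum_clade_credibility(trees)
  expect_true(res$index %in% 2:4)
  expect_identical(sort(oracle_clade_keys(res$tree)),
                   sort(oracle_clade_keys(base)))

  # singleton and all-identical sets
  one <- c(base); class(one) <- "multiPhylo"
  expect_equal(maximum_clade_credibility(one)$index, 1L)
  same <- c(base, base, base); class(same) <- "multiPhylo"
  expect_equal(maximum_clade_credibility(same)$index, 1L)

  # output is always a member of the input set
  set.seed(31)
  trees <- replicate(15, random_labeled_tree(7, sprintf("s%d", 1:7)),
                     simplify = FALSE)
  class(trees) <- "multiPhylo"
  res <- maximum_clade_credibility(trees)
  keys <- lapply(trees, function(t) sort(oracle_clade_keys(t)))
  expect_true(any(vapply(keys, identical, logical(1),
                         sort(oracle_clade_keys(res$tree)))))
})
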