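# Strict and Adams consensus, wildcard detection, reduced consensus and the
# character bootstrap.

test_that("strict consensus of a single tree is that tree", {
  set.seed(2)
  tr <- random_topology(7)
  expect_setequal(tree_bipartitions(strict_consensus(list(tr))),
                  tree_bipartitions(tr))
})

test_that("conflicting quartets collapse to a star", {
  ts <- list(read_newick("((A,B),(C,D),E);"), read_newick("((A,C),(B,D),E);"))
  expect_length(tree_bipartitions(strict_consensus(ts)), 0)
})

test_that("strict consensus agrees with ape::consensus on random tree sets", {
  set.seed(14)
  for (i in 1:20) {
    trees <- lapply(1:4, function(j) random_topology(7))
    ours <- strict_consensus(trees)
    apes <- ape::consensus(trees, p = 1, rooted = FALSE)
    expect_setequal(tree_bipartitions(ours), tree_bipartitions(apes))
  }
})

test_that("strict consensus bipartitions occur in every input tree", {
  set.seed(15)
  for (i in 1:30) {
    base <- random_topology(8)
    trees <- c(list(base), lapply(seq_len(3), function(j) {
      nb <- tbr_neighbours(base)
      nb[[sample.int(length(nb), 1)]]
    }))
    common <- tree_bipartitions(strict_consensus(trees))
    for (t in trees)
      expect_true(all(common %in% tree_bipartitions(t)))
  }
})

test_that("leaf-set mismatches are rejected", {
  t1 <- read_newick("((A,B),(C,D),E);")
  t2 <- read_newick("((A,B),(C,X),E);")
  expect_error(strict_consensus(list(t1, t2)), "leaf set")
})

test_that("adams consensus of one tree is the tree itself", {
  set.seed(3)
  tr <- ape::rtree(6, br = NULL)
  expect_identical(rooted_clusters(adams_consensus(list(tr))),
                   rooted_clusters(tr))
})

test_that("adams consensus matches the nesting-set oracle on random pairs", {
  trees5 <- all_rooted_trees(letters[1:5])
  set.seed(8)
  for (i in 1:60) {
    pair <- trees5[sample.int(length(trees5), 2, replace = TRUE)]
    expect_identical(rooted_clusters(adams_consensus(pair)),
                     adams_oracle_clusters(pair))
  }
  expect_error(adams_consensus(list(random_topology(5), random_topology(5))),
               "outgroup")
})

test_that("adams places a rogue at the deepest shared node while strict collapses", {
  fam <- rogue_family()
  strict <- strict_consensus(fam)
  adams <- adams_consensus(fam, outgroup = "F")
  # strict loses backbone resolution entirely
  expect_lt(length(tree_bipartitions(strict)),
            length(tree_bipartitions(fam[[1]])))
  # adams keeps non-trivial clusters that do not contain the rogue
  cl <- rooted_clusters(adams)
  keep <- cl[cl != paste(sort(adams$tip.label), collapse = "|")]
  expect_true(any(!grepl("RG", keep)))
})

test_that("a constructed rogue is detected and pruning restores resolution", {
  fam <- rogue_family()
  wc <- find_wildcards(fam, max_wildcards = 3)
  expect_identical(wc$wildcards, "RG")
  expect_gt(wc$steps$gain[1], 0)
  red <- reduced_consensus(fam, wc$wildcards)
  # backbone has 6 leaves: full resolution is n - 3 internal edges
  expect_length(tree_bipartitions(red$consensus), 3)
  expect_equal(red$n_trees, 1L)
})

test_that("tree sets without conflict yield no wildcards", {
  set.seed(5)
  tr <- random_topology(7)
  wc <- find_wildcards(list(tr, tr, tr))
  expect_length(wc$wildcards, 0)
})

test_that("reduced consensus with an empty prune set equals strict consensus", {
  set.seed(9)
  trees <- lapply(1:3, function(i) random_topology(6))
  expect_setequal(tree_bipartitions(reduced_consensus(trees)$consensus),
                  tree_bipartitions(strict_consensus(trees)))
  expect_error(reduced_consensus(trees, trees[[1]]$tip.label[1:4]),
               "fewer than 3")
  expect_error(reduced_consensus(trees, "NOPE"), "not in the trees")
})

test_that("reduced consensus recomputes lengths on the pruned leaf set", {
  fam <- rogue_family()
  cells <- cbind(c("1", "1", "0", "0", "0", "0", "0"),
                 c("0", "0", "1", "1", "0", "0", "1"))
  cm <- character_matrix(c("A", "B", "C", "D", "E", "F", "RG"), cells)
  red <- reduced_consensus(fam, "RG", matrix = cm)
  expect_length(red$lengths, red$n_trees)
  expect_true(all(red$lengths >= 0))
})

test_that("bootstrap gives unanimous support to unanimous signal", {
  cells <- cbind(
    matrix(rep(c("1", "1", "0", "0", "0", "0"), 8), ncol = 8),
    matrix(rep(c("0", "0", "1", "1", "0", "0"), 8), ncol = 8)
  )
  cm <- character_matrix(LETTERS[1:6], cells)
  bs <- bootstrap_support(cm, search_config(n_replicates = 2, seed = 3),
                          n_boot = 20)
  # the A|B cherry reads as the complement-side canonical key
  expect_true("C|D|E|F" %in% names(bs$support))
  expect_true(max(bs$support) == 100)
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  bs2 <- bootstrap_support(cm, search_config(n_replicates = 2, seed = 3),
                           n_boot = 20)
  expect_identical(bs$support, bs2$support)
})

test_that("bootstrap favours the true cherry at strong signal", {
  # 6 taxa; 20 characters support the (A,B) cherry, 2 contradict it
  cells <- cbind(
    matrix(rep(c("1", "1", "0", "0", "0", "0"), 20), ncol = 20),
    matrix(rep(c("1", "0", "1", "0", "0", "0"), 2), ncol = 2)
  )
  cm <- character_matrix(LETTERS[1:6], cells)
  bs <- bootstrap_support(cm, search_config(n_replicates = 2, seed = 6),
                          n_boot = 40)
  cherry_key <- "C|D|E|F"   # complement-side canonical key of (A,B)
  contradict_key <- "B|D|E|F"
  s_true <- if (cherry_key %in% names(bs$support))
    bs$support[[cherry_key]] else 0
  s_false <- if (contradict_key %in% names(bs$support))
    bs$support[[contradict_key]] else 0
  expect_gt(s_true, s_false)
  expect_gt(s_true, 80)
})

test_that("support percentages annotate matching consensus nodes", {
  cells <- matrix(rep(c("1", "1", "0", "0", "0", "0"), 10), ncol = 10)
  cm <- character_matrix(LETTERS[1:6], cells)
  res <- heuristic_search(cm, search_config(n_replicates = 2, seed = 2))
  bs <- bootstrap_support(cm, search_config(n_replicates = 2, seed = 2),
                          n_boot = 10)
  st <- annotate_support(strict_consensus(res), bs)
  expect_true("100" %in% st$node.label)
})
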