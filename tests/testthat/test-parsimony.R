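# Fitch optimization, step bounds, ensemble indices, TBR moves and the
# heuristic search.

test_that("fitch length matches the textbook four-taxon cases", {
  tr <- read_newick("((A,B),(C,D));")
  cm1 <- character_matrix(c("A", "B", "C", "D"), cbind(c("0", "0", "1", "1")))
  expect_equal(fitch_length(tr, cm1), 1L)
  cm2 <- character_matrix(c("A", "B", "C", "D"), cbind(c("0", "1", "0", "1")))
  expect_equal(fitch_length(tr, cm2), 2L)
  const <- character_matrix(c("A", "B", "C", "D"), cbind(rep("1", 4)))
  expect_equal(fitch_length(tr, const), 0L)
  expect_error(fitch_length(tr, character_matrix(c("A", "B", "X", "Y"),
                                                 cbind(rep("0", 4)))),
               "absent")
})

test_that("fitch length equals the brute-force labeling minimum", {
  set.seed(20210211)
  for (i in 1:40) {
    n <- sample(4:6, 1)
    k <- sample(2:3, 1)
    sim <- gen_matrix_on_tree(n, 4, k, change_prob = 0.4,
                              missing_prob = 0.15, seed = i)
    cm <- sim$matrix
    if (i %% 3 == 0) cm$cells[1, 1] <- paste(c("0", "1"), collapse = "/")
    tr <- sim$tree
    expected <- sum(vapply(seq_len(cm$n_chars), function(j)
      brute_force_fitch(tr, column_state_sets(cm, j), k), 0L))
    expect_equal(fitch_length(tr, cm), expected)
  }
})

test_that("fitch length is invariant under re-rooting", {
  sim <- gen_matrix_on_tree(7, 20, 3, change_prob = 0.3, seed = 99)
  base <- fitch_length(sim$tree, sim$matrix)
  for (tip in sim$tree$tip.label) {
    rooted <- ape::root(sim$tree, outgroup = tip, resolve.root = TRUE)
    expect_equal(fitch_length(rooted, sim$matrix), base)
  }
})

test_that("fitch length agrees with phangorn on unambiguous matrices", {
  for (seed in 1:5) {
    sim <- gen_matrix_on_tree(8, 30, 2, change_prob = 0.25, seed = seed)
    pd <- phangorn::phyDat(sim$matrix$cells, type = "USER",
                           levels = sim$matrix$symbols)
    expect_equal(fitch_length(sim$tree, sim$matrix),
                 as.integer(phangorn::parsimony(sim$tree, pd,
                                                method = "fitch")))
  }
})

test_that("polytomies other than the basal trifurcation are refused", {
  poly <- read_newick("(A,B,C,D,E);")
  cm <- character_matrix(LETTERS[1:5], cbind(c("0", "0", "1", "1", "0")))
  expect_error(fitch_length(poly, cm), "polytom")
})

test_that("step bounds match their definitions and the exhaustive maximum", {
  cm <- character_matrix(paste0("t", 1:6),
                         cbind(c("0", "0", "0", "1", "1", "2"),
                               rep("0", 6),
                               c("?", "?", "?", "?", "?", "?"),
                               c("0", "1", "2", "?", "0/1", "-")))
  b <- char_step_bounds(cm)
  expect_equal(b$min_steps, c(2, 0, 0, 2))
  expect_equal(b$max_steps[2:3], c(0, 0))
  expect_equal(b$max_steps[1], 3)
  # exhaustive check of the maximum for column 1 over all 105 topologies
  col1 <- character_matrix(paste0("t", 1:6),
                           cbind(c("0", "0", "0", "1", "1", "2")))
  topos <- quarrypal:::all_unrooted_topologies(paste0("t", 1:6))
  lens <- vapply(topos, fitch_length, 0L, matrix = col1)
  expect_equal(max(lens), 3L)
  expect_equal(min(lens), 2L)
})

test_that("ensemble CI and RI hit their boundary cases", {
  sim <- gen_matrix_on_tree(6, 40, 2, change_prob = 0.3, seed = 5)
  b <- char_step_bounds(sim$matrix)
  expect_equal(ensemble_ci_ri(sum(b$min_steps), sim$matrix)$CI, 1)
  expect_equal(ensemble_ci_ri(sum(b$max_steps), sim$matrix)$RI, 0)
  L <- fitch_length(sim$tree, sim$matrix)
  expect_gte(L, sum(b$min_steps))
  expect_lte(L, sum(b$max_steps))
  const <- character_matrix(c("A", "B", "C"), cbind(rep("0", 3)))
  expect_warning(r <- ensemble_ci_ri(0, const), "RI undefined")
  expect_true(is.na(r$RI))
  # excluding uninformative characters changes the sums consistently
  both <- ensemble_ci_ri(L, sim$matrix)
  excl <- ensemble_ci_ri(L, sim$matrix, exclude_uninformative = TRUE)
  expect_lte(excl$sum_min, both$sum_min)
  expect_lte(excl$length, both$length)
})

test_that("TBR neighbourhoods are valid, leaf-preserving and self-excluding", {
  set.seed(31)
  for (n in c(5, 6, 8)) {
    tr <- random_topology(n)
    nb <- tbr_neighbours(tr)
    expect_gt(length(nb), 0)
    self <- quarrypal:::topology_key(tr)
    keys <- vapply(nb, quarrypal:::topology_key, "")
    expect_false(self %in% keys)
    expect_equal(anyDuplicated(keys), 0L)
    for (x in nb[seq_len(min(5, length(nb)))]) {
      expect_setequal(x$tip.label, tr$tip.label)
      expect_true(quarrypal:::tree_is_searchable(x))
    }
  }
})

test_that("perfectly congruent data yield the generating tree as unique MPT", {
  sim <- gen_matrix_on_tree(7, 60, 2, change_prob = 0, seed = 4, tree = NULL)
  # change_prob 0 gives constant characters; build clean clade signal instead
  truth <- read_newick("(((A,B),(C,D)),(E,F),G);")
  cells <- cbind(
    matrix(rep(c("1", "1", "0", "0", "0", "0", "0"), 10), ncol = 10),
    matrix(rep(c("0", "0", "1", "1", "0", "0", "0"), 10), ncol = 10),
    matrix(rep(c("0", "0", "0", "0", "1", "1", "0"), 10), ncol = 10),
    matrix(rep(c("1", "1", "1", "1", "0", "0", "0"), 10), ncol = 10)
  )
  cm <- character_matrix(c("A", "B", "C", "D", "E", "F", "G"), cells)
  res <- heuristic_search(cm, search_config(n_replicates = 3, seed = 17))
  expect_equal(res$n_trees, 1L)
  expect_equal(res$length, sum(char_step_bounds(cm)$min_steps))
  expect_setequal(tree_bipartitions(res$trees[[1]]),
                  tree_bipartitions(truth))
})

test_that("search is deterministic given the seed", {
  sim <- gen_matrix_on_tree(7, 15, 2, change_prob = 0.35, seed = 12)
  r1 <- heuristic_search(sim$matrix, search_config(n_replicates = 3, seed = 8))
  r2 <- heuristic_search(sim$matrix, search_config(n_replicates = 3, seed = 8))
  expect_equal(r1$length, r2$length)
  expect_setequal(vapply(r1$trees, quarrypal:::topology_key, ""),
                  vapply(r2$trees, quarrypal:::topology_key, ""))
})

test_that("degenerate and invalid search inputs are refused", {
  tiny <- character_matrix(c("A", "B", "C"), cbind(c("0", "1", "0")))
  expect_error(heuristic_search(tiny), "at least 4")
  blank <- character_matrix(c("A", "B", "C", "D"),
                            matrix("?", 4, 3))
  expect_error(heuristic_search(blank), "ambiguous")
  expect_error(search_config(n_replicates = 0), "positive")
})

test_that("all-constant matrices give zero length on any tree", {
  cm <- character_matrix(paste0("t", 1:5), matrix("1", 5, 8))
  for (seed in 1:3) {
    set.seed(seed)
    expect_equal(fitch_length(random_topology(5, paste0("t", 1:5)), cm), 0L)
  }
})
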