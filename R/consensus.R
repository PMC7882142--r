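# Consensus methods and wildcard handling for sets of most parsimonious
# trees: strict consensus (bipartitions present in every tree), the classic
# nesting-based Adams consensus, greedy wildcard (rogue) detection by
# pruning gain, reduced strict consensus after pruning, and nonparametric
# character bootstrap.

check_shared_leaves <- function(trees) {
  if (!length(trees)) stopf("empty tree set")
  if (inherits(trees, "tree_set")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees))
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stopf("tree %d has a different leaf set", i)
  trees
}

# contract the internal edges of `tree` whose split key is not in `keep`
collapse_to_splits <- function(tree, keep) {
  tree <- ape::unroot(tree)
  E <- tree$edge
  ntip <- length(tree$tip.label)
  sets <- edge_tipsets(tree)
  merge_into <- seq_len(max(E))   # union-find style parent map
  find <- function(x) {
    while (merge_into[x] != x) x <- merge_into[x]
    x
  }
  for (e in seq_len(nrow(E))) {
    ch <- E[e, 2]
    if (ch <= ntip) next
    sz <- length(sets[[e]])
    if (sz <= 1 || sz >= ntip - 1) next
    if (!(split_key(sets[[e]], tree$tip.label) %in% keep))
      merge_into[ch] <- E[e, 1]
  }
  E2 <- cbind(vapply(E[, 1], find, 0L), vapply(E[, 2], find, 0L))
  E2 <- E2[E2[, 1] != E2[, 2], , drop = FALSE]
  build_phylo(E2, tree$tip.label)
}

#' Strict consensus tree
#'
#' The tree containing exactly the bipartitions present in every input tree.
#'
#' @param trees a list of [ape::phylo] trees (or a `tree_set`) over one leaf
#'   set.
#' @return an unrooted, possibly polytomous `phylo` tree.
#' @export
strict_consensus <- function(trees) {
  trees <- check_shared_leaves(trees)
  keys <- lapply(trees, tree_bipartitions)
  common <- Reduce(intersect, keys)
  collapse_to_splits(trees[[1]], common)
}

# remove a single-child root left by restriction
drop_root_singles <- function(tree) {
  repeat {
    E <- tree$edge
    root <- setdiff(E[, 1], E[, 2])
    kids <- which(E[, 1] == root)
    if (length(kids) > 1 || nrow(E) <= 1) return(tree)
    E2 <- E[-kids, , drop = FALSE]
    tree <- build_phylo(E2, tree$tip.label)
  }
}

# clade tip sets hanging off the root of a rooted tree
root_partition <- function(tree) {
  E <- tree$edge
  root <- setdiff(E[, 1], E[, 2])
  sets <- edge_tipsets(tree)
  sets[which(E[, 1] == root)]
}

restrict_rooted <- function(tree, leaves) {
  if (length(leaves) == 1) return(leaves)
  drop_root_singles(ape::keep.tip(tree, leaves))
}

#' Adams consensus tree
#'
#' The classic nesting-based Adams consensus of rooted trees: the root
#' partition of the consensus is the partition product (common refinement) of
#' the input trees' root partitions, and the construction recurses inside
#' each block on the restricted trees. Unstable ("rogue") taxa are pulled
#' down to the deepest node below which their placement is consistent,
#' instead of collapsing the topology as the strict consensus does.
#'
#' @param trees list of [ape::phylo] trees over one leaf set; rooted, or
#'   unrooted with `outgroup` designated.
#' @param outgroup leaf label used to root unrooted inputs.
#' @return a rooted, possibly polytomous `phylo` tree.
#' @export
adams_consensus <- function(trees, outgroup = NULL) {
  trees <- check_shared_leaves(trees)
  rooted <- vapply(trees, ape::is.rooted, TRUE)
  if (!all(rooted)) {
    if (is.null(outgroup))
      stopf("unrooted input: designate an outgroup for Adams consensus")
    trees <- lapply(trees, function(t)
      if (ape::is.rooted(t)) t else
        ape::root(t, outgroup = outgroup, resolve.root = TRUE))
  }
  nwk <- adams_rec(trees)
  read_newick(paste0(nwk, ";"))
}

adams_rec <- function(trees) {
  leaves <- trees[[1]]$tip.label
  if (length(leaves) == 2)
    return(paste0("(", leaves[1], ",", leaves[2], ")"))
  # block signature of each leaf: which root-child clade holds it, per tree
  sig <- vapply(trees, function(t) {
    part <- root_partition(t)
    id <- integer(length(leaves))
    for (b in seq_along(part)) id[match(part[[b]], leaves)] <- b
    id
  }, integer(length(leaves)))
  blocks <- split(leaves, apply(sig, 1, paste, collapse = "."))
  kids <- vapply(blocks, function(B) {
    if (length(B) == 1) return(B)
    adams_rec(lapply(trees, restrict_rooted, leaves = B))
  }, "")
  if (length(kids) == 1) return(kids)   # cannot happen for valid partitions
  paste0("(", paste(sort(kids), collapse = ","), ")")
}

#' Rooted cluster set of a tree
#'
#' Canonical keys of every non-trivial rooted clade (size >= 2, including the
#' full leaf set). Used to compare rooted consensus topologies.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @return sorted character vector of cluster keys.
#' @export
rooted_clusters <- function(tree) {
  sets <- edge_tipsets(tree)
  keys <- vapply(sets[vapply(sets, length, 0L) >= 2],
                 function(s) paste(sort(s), collapse = "|"), "")
  sort(unique(c(keys, paste(sort(tree$tip.label), collapse = "|"))))
}

# internal-edge count of the (unrooted) strict consensus: the resolution score
consensus_resolution <- function(trees) {
  length(tree_bipartitions(strict_consensus(trees)))
}

#' Detect wildcard (rogue) taxa
#'
#' Greedy selection: each leaf is scored by how many internal edges the
#' strict consensus of the leaf-pruned trees gains over the current one;
#' the best-scoring leaf is removed while the gain is positive and at most
#' `max_wildcards` leaves are taken. When an `outgroup` is supplied each
#' selection is annotated with whether the leaf's smallest containing cluster
#' differs between the strict and Adams consensus trees (the classical
#' diagnostic for rogue behaviour).
#'
#' @param trees list of trees (or `tree_set`) over one leaf set; >= 2 trees.
#' @param max_wildcards cap on the number of leaves pruned.
#' @param outgroup optional leaf for rooting the strict/Adams comparison;
#'   never selected as a wildcard.
#' @return an object of class `wildcard_report`: `wildcards` (character
#'   vector, possibly empty) and `steps` (data frame of per-selection gains
#'   and annotations).
#' @export
find_wildcards <- function(trees, max_wildcards = 5, outgroup = NULL) {
  trees <- check_shared_leaves(trees)
  if (length(trees) < 2) stopf("wildcard detection needs >= 2 trees")
  leaves <- trees[[1]]$tip.label

  disagree <- rep(NA, length(leaves))
  names(disagree) <- leaves
  if (!is.null(outgroup)) {
    strict_r <- ape::root(strict_consensus(trees), outgroup = outgroup,
                          resolve.root = TRUE)
    adams <- adams_consensus(trees, outgroup = outgroup)
    smallest_cluster <- function(tr, leaf) {
      sets <- edge_tipsets(tr)
      sets <- sets[vapply(sets, function(s)
        leaf %in% s && length(s) >= 2, TRUE)]
      if (!length(sets)) return(paste(sort(tr$tip.label), collapse = "|"))
      s <- sets[[which.min(vapply(sets, length, 0L))]]
      paste(sort(s), collapse = "|")
    }
    for (lf in setdiff(leaves, outgroup))
      disagree[lf] <- !identical(smallest_cluster(strict_r, lf),
                                 smallest_cluster(adams, lf))
  }

  selected <- character(0)
  steps <- list()
  cur_trees <- trees
  cur_res <- consensus_resolution(cur_trees)
  candidates <- setdiff(leaves, outgroup)
  while (length(selected) < max_wildcards &&
         length(cur_trees[[1]]$tip.label) > 4) {
    gains <- vapply(sort(candidates), function(lf) {
      pruned <- lapply(cur_trees, ape::drop.tip, tip = lf)
      consensus_resolution(pruned) - cur_res
    }, 0)
    if (!length(gains) || max(gains) <= 0) break
    pick <- names(gains)[which.max(gains)]   # ties: lexicographically first
    selected <- c(selected, pick)
    steps[[length(steps) + 1L]] <- data.frame(
      taxon = pick, gain = max(gains),
      strict_adams_disagree = disagree[[pick]], stringsAsFactors = FALSE)
    cur_trees <- lapply(cur_trees, ape::drop.tip, tip = pick)
    cur_res <- consensus_resolution(cur_trees)
    candidates <- setdiff(candidates, pick)
  }
  structure(
    list(wildcards = selected,
         steps = if (length(steps)) do.call(rbind, steps) else
           data.frame(taxon = character(), gain = numeric(),
                      strict_adams_disagree = logical())),
    class = "wildcard_report"
  )
}

#' @export
print.wildcard_report <- function(x, ...) {
  if (!length(x$wildcards)) {
    cat("no wildcard taxa detected\n")
  } else {
    cat("wildcard taxa:", paste(x$wildcards, collapse = ", "), "\n")
    print(x$steps, row.names = FALSE)
  }
  invisible(x)
}

#' Reduced strict consensus after pruning
#'
#' Prunes `prune_set` from every tree (suppressing the degree-2 nodes this
#' leaves), removes duplicate topologies, and computes the strict consensus
#' of the remainder. Tree lengths on the pruned leaf set are recomputed when
#' a matrix is supplied.
#'
#' @param trees list of trees (or `tree_set`) over one leaf set.
#' @param prune_set leaves to remove; must leave >= 3 leaves.
#' @param matrix optional [character_matrix()] for recomputing lengths.
#' @return list with `consensus` (`phylo`), `trees` (deduplicated pruned
#'   list), `n_trees`, and `lengths` (or `NULL`).
#' @export
reduced_consensus <- function(trees, prune_set = character(0), matrix = NULL) {
  trees <- check_shared_leaves(trees)
  leaves <- trees[[1]]$tip.label
  bad <- setdiff(prune_set, leaves)
  if (length(bad)) stopf("prune_set taxon '%s' not in the trees", bad[1])
  if (length(setdiff(leaves, prune_set)) < 3)
    stopf("pruning would leave fewer than 3 leaves")
  pruned <- if (length(prune_set))
    lapply(trees, ape::drop.tip, tip = prune_set) else trees
  keys <- vapply(pruned, topology_key, "")
  uniq <- pruned[!duplicated(keys)]
  lens <- if (!is.null(matrix))
    vapply(uniq, fitch_length, 0L, matrix = matrix) else NULL
  list(consensus = strict_consensus(uniq), trees = uniq,
       n_trees = length(uniq), lengths = lens)
}

#' Nonparametric character bootstrap
#'
#' Resamples characters with replacement, runs a (reduced-budget) heuristic
#' search on each pseudo-matrix, and tabulates how often each bipartition
#' appears in the replicate's strict consensus. Deterministic given the
#' seed in `config`.
#'
#' @param matrix a [character_matrix()].
#' @param config a [search_config()]; its `n_replicates` is the per-bootstrap
#'   search budget (default here is deliberately small).
#' @param n_boot number of bootstrap replicates.
#' @return an object of class `bootstrap_support`: named numeric vector
#'   `support` (percentages keyed by split key) plus metadata.
#' @export
bootstrap_support <- function(matrix,
                              config = search_config(n_replicates = 10),
                              n_boot = 100) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (n_boot < 1) stopf("n_boot must be >= 1")
  set.seed(substream_seed(config$seed, "bootstrap"))
  rep_seeds <- sample.int(2^31 - 2, n_boot)
  tally <- new.env(parent = emptyenv())
  for (b in seq_len(n_boot)) {
    cols <- sample.int(matrix$n_chars, matrix$n_chars, replace = TRUE)
    bm <- character_matrix(matrix$taxon_names,
                           matrix$cells[, cols, drop = FALSE],
                           symbols = matrix$symbols,
                           missing_char = matrix$missing_char,
                           gap_char = matrix$gap_char)
    cfg <- search_config(n_replicates = config$n_replicates,
                         trees_kept_per_replicate =
                           config$trees_kept_per_replicate,
                         seed = rep_seeds[b],
                         max_trees_total = config$max_trees_total)
    res <- heuristic_search(bm, cfg)
    for (k in tree_bipartitions(strict_consensus(res)))
      assign(k, (if (exists(k, envir = tally))
        get(k, envir = tally) else 0L) + 1L, envir = tally)
  }
  counts <- unlist(as.list(tally))
  structure(
    list(support = sort(100 * counts / n_boot, decreasing = TRUE),
         n_boot = n_boot, seed = config$seed),
    class = "bootstrap_support"
  )
}

#' @export
print.bootstrap_support <- function(x, ...) {
  cat(sprintf("bootstrap support (%d replicates, seed %d):\n",
              x$n_boot, x$seed))
  for (k in names(x$support))
    cat(sprintf("  %5.1f%%  {%s}\n", x$support[[k]], k))
  invisible(x)
}

#' Write bootstrap percentages onto a tree's internal nodes
#'
#' @param tree a `phylo` tree.
#' @param support a [bootstrap_support()] result (or named vector keyed by
#'   split key).
#' @return the tree with `node.label` set to the matching percentages
#'   (empty where no split matches).
#' @export
annotate_support <- function(tree, support) {
  if (inherits(support, "bootstrap_support")) support <- support$support
  E <- tree$edge
  ntip <- length(tree$tip.label)
  sets <- edge_tipsets(tree)
  labs <- rep("", tree$Nnode)
  for (e in seq_len(nrow(E))) {
    ch <- E[e, 2]
    if (ch <= ntip) next
    sz <- length(sets[[e]])
    if (sz <= 1 || sz >= ntip - 1) next
    key <- split_key(sets[[e]], tree$tip.label)
    if (key %in% names(support))
      labs[ch - ntip] <- format(round_half_up(support[[key]], 0))
  }
  tree$node.label <- labs
  tree
}
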