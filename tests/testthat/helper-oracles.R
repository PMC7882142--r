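# Independent oracles and constructed fixtures shared across tests.

# Brute-force Fitch oracle: minimum changes over every assignment of states
# to internal nodes. Tips may carry state sets (ambiguity); an edge into a
# tip is free iff the parent state is in the tip's set.
brute_force_fitch <- function(tree, state_sets, n_states) {
  rt <- if (ape::is.rooted(tree)) tree else
    ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  E <- rt$edge
  ntip <- length(rt$tip.label)
  internals <- sort(unique(E[, 1]))
  k <- length(internals)
  best <- Inf
  idx <- rep(1L, k)
  repeat {
    assign_state <- stats::setNames(idx, internals)
    cost <- 0L
    for (e in seq_len(nrow(E))) {
      p_state <- assign_state[[as.character(E[e, 1])]]
      ch <- E[e, 2]
      if (ch <= ntip) {
        if (!(p_state %in% state_sets[[rt$tip.label[ch]]])) cost <- cost + 1L
      } else {
        if (p_state != assign_state[[as.character(ch)]]) cost <- cost + 1L
      }
    }
    best <- min(best, cost)
    j <- 1L
    while (j <= k && idx[j] == n_states) { idx[j] <- 1L; j <- j + 1L }
    if (j > k) break
    idx[j] <- idx[j] + 1L
  }
  as.integer(best)
}

# Nesting-set Adams oracle: builds the cluster set of the Adams consensus via
# pairwise root-block equivalence (mrca against the root) and leaf deletion
# (drop.tip), a code path disjoint from the implementation's partition-product
# recursion over keep.tip restrictions.
adams_oracle_clusters <- function(trees) {
  out <- character(0)
  rec <- function(ts) {
    lv <- ts[[1]]$tip.label
    out <<- c(out, paste(sort(lv), collapse = "|"))
    n <- length(lv)
    if (n <= 2) return(invisible())
    same <- matrix(TRUE, n, n, dimnames = list(lv, lv))
    for (t in ts) {
      M <- ape::mrca(t)
      root <- length(t$tip.label) + 1L
      same <- same & (M[lv, lv, drop = FALSE] != root)
    }
    diag(same) <- TRUE
    remaining <- lv
    while (length(remaining)) {
      blk <- lv[same[remaining[1], ]]
      remaining <- setdiff(remaining, blk)
      if (length(blk) > 1)
        rec(lapply(ts, function(t)
          ape::drop.tip(t, setdiff(t$tip.label, blk))))
    }
  }
  rec(trees)
  sort(unique(out))
}

# A tree family in which one leaf wanders over every backbone position while
# the backbone itself is fixed: the classical rogue/wildcard situation.
rogue_family <- function(backbone_newick = "(((A,B),(C,D)),(E,F));",
                         rogue = "RG") {
  bb <- ape::unroot(read_newick(backbone_newick))
  lapply(seq_len(nrow(bb$edge)), function(e)
    ape::unroot(quarrypal:::attach_leaf(bb, e, rogue)))
}

# random unrooted binary tree without using package internals
random_topology <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  ape::unroot(ape::rtree(n, br = NULL, tip.label = labels))
}

# all rooted binary topologies on the given labels (phangorn, uncompressed)
all_rooted_trees <- function(labels) {
  tt <- phangorn::allTrees(length(labels), rooted = TRUE, tip.label = labels)
  lapply(seq_along(tt), function(i) tt[[i]])
}

# state-set list for brute_force_fitch from a character_matrix column
column_state_sets <- function(cm, j) {
  full <- seq_along(cm$symbols)
  sets <- lapply(seq_len(cm$n_taxa), function(i) {
    cell <- cm$cells[i, j]
    if (cell %in% c(cm$missing_char, cm$gap_char)) return(full)
    match(strsplit(cell, "/")[[1]], cm$symbols)
  })
  stats::setNames(sets, cm$taxon_names)
}
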