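# Morphological maximum parsimony under Fitch (unordered, equally weighted)
# optimization: tree length, per-character step bounds, ensemble consistency
# and retention indices, and a random-addition-sequence + TBR heuristic
# search. Characters are held as bitmask state sets, so missing ("?") and gap
# ("-") scorings are the full alphabet and polymorphic scorings are the union
# of their states.

# ---- encoding ---------------------------------------------------------------

# character_matrix -> integer bitmask matrix (taxa x characters)
encode_matrix <- function(cm) {
  stopifnot(inherits(cm, "character_matrix"))
  k <- length(cm$symbols)
  if (k > 30) stopf("at most 30 states supported, got %d", k)
  full <- as.integer(2^k - 1)
  bit_of <- stats::setNames(as.integer(2^(seq_len(k) - 1)), cm$symbols)
  enc <- matrix(0L, cm$n_taxa, cm$n_chars,
                dimnames = list(cm$taxon_names, NULL))
  for (i in seq_len(cm$n_taxa)) {
    enc[i, ] <- vapply(cm$cells[i, ], function(cell) {
      if (cell %in% c(cm$missing_char, cm$gap_char)) return(full)
      sum(bit_of[strsplit(cell, "/")[[1]]])
    }, 0L)
  }
  attr(enc, "full_mask") <- full
  enc
}

# ---- low-level tree machinery ----------------------------------------------

# renumber an edge matrix with tips 1..ntip and arbitrary internal ids into a
# valid ape phylo (internals ntip+1.., root first)
build_phylo <- function(edge, tip_labels) {
  ntip <- length(tip_labels)
  kids <- edge[, 2]
  root <- setdiff(edge[, 1], kids)
  if (length(root) != 1) stopf("edge matrix has %d roots", length(root))
  internals <- unique(edge[, 1])
  # preorder numbering of internal nodes starting at the root
  ord <- integer(0)
  stack <- root
  ch <- split(edge[, 2], edge[, 1])
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(ord, nd)
    ints <- ch[[as.character(nd)]]
    ints <- ints[ints > ntip]
    if (length(ints)) stack <- c(stack, rev(ints))
  }
  map <- integer(max(c(edge)))
  map[seq_len(ntip)] <- seq_len(ntip)
  map[ord] <- ntip + seq_along(ord)
  e2 <- cbind(map[edge[, 1]], map[edge[, 2]])
  structure(list(edge = e2, Nnode = length(ord),
                 tip.label = tip_labels),
            class = "phylo", order = "cladewise")
}

# postorder edge indices for an ape phylo (children before parents)
postorder_edges <- function(tree) {
  E <- tree$edge
  root <- setdiff(E[, 1], E[, 2])
  ch_edges <- split(seq_len(nrow(E)), E[, 1])
  # iterative preorder over edges, reversed gives postorder
  estack <- ch_edges[[as.character(root)]]
  k <- 0L
  pre <- integer(nrow(E))
  while (length(estack)) {
    e <- estack[length(estack)]
    estack <- estack[-length(estack)]
    k <- k + 1L
    pre[k] <- e
    child <- E[e, 2]
    more <- ch_edges[[as.character(child)]]
    if (!is.null(more)) estack <- c(estack, more)
  }
  rev(pre)
}

# precompute the traversal used by fitch_steps(); tip order = tree$tip.label
fitch_prep <- function(tree) {
  E <- tree$edge
  po <- postorder_edges(tree)
  list(parent = E[po, 1], child = E[po, 2],
       n_nodes = max(E), ntip = length(tree$tip.label),
       tip_labels = tree$tip.label)
}

# Fitch length given prepared traversal and an encoded bitmask matrix whose
# rows are already ordered to match prep$tip_labels
fitch_steps <- function(prep, enc_ordered) {
  nch <- ncol(enc_ordered)
  S <- matrix(0L, prep$n_nodes, nch)
  S[seq_len(prep$ntip), ] <- enc_ordered
  seen <- logical(prep$n_nodes)
  steps <- 0L
  for (i in seq_along(prep$parent)) {
    p <- prep$parent[i]; ch <- prep$child[i]
    if (!seen[p]) {
      S[p, ] <- S[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(S[p, ], S[ch, ])
      z <- inter == 0L
      if (any(z)) {
        steps <- steps + sum(z)
        inter[z] <- bitwOr(S[p, ], S[ch, ])[z]
      }
      S[p, ] <- inter
    }
  }
  steps
}

#' Fitch parsimony length of a tree
#'
#' Minimum number of unordered character-state changes required by `tree`
#' under the matrix, summed over characters. Missing and gap scorings
#' contribute the full state alphabet, polymorphic scorings their state set.
#' The length is independent of root placement; trees may be rooted binary or
#' unrooted (basal trifurcation). Other polytomies are refused -- resolve
#' them upstream.
#'
#' @param tree an [ape::phylo] tree whose tips all occur in the matrix.
#' @param matrix a [character_matrix()], or a pre-encoded bitmask matrix from
#'   the internal encoder.
#' @return integer number of steps.
#' @examples
#' cm <- character_matrix(c("A", "B", "C", "D"),
#'                        rbind("0", "0", "1", "1"))
#' fitch_length(read_newick("((A,B),(C,D));"), cm) # 1
#' @export
fitch_length <- function(tree, matrix) {
  stopifnot(inherits(tree, "phylo"))
  enc <- if (inherits(matrix, "character_matrix")) encode_matrix(matrix)
         else matrix
  missing_tips <- setdiff(tree$tip.label, rownames(enc))
  if (length(missing_tips))
    stopf("leaf '%s' absent from the character matrix", missing_tips[1])
  if (!tree_is_searchable(tree))
    stopf("tree has unresolved polytomies; fitch_length needs a binary tree")
  prep <- fitch_prep(tree)
  fitch_steps(prep, enc[prep$tip_labels, , drop = FALSE])
}

# binary rooted, or unrooted-with-basal-trifurcation (both exact for Fitch)
tree_is_searchable <- function(tree) {
  E <- tree$edge
  root <- setdiff(E[, 1], E[, 2])
  deg <- table(E[, 1])
  root_deg <- deg[as.character(root)]
  other <- deg[names(deg) != as.character(root)]
  ntip <- length(tree$tip.label)
  if (ntip <= 2) return(TRUE)
  all(other == 2) && (root_deg == 2 || root_deg == 3)
}

# ---- step bounds and ensemble indices ---------------------------------------

#' Per-character minimum and maximum parsimony steps
#'
#' For each character: the minimum steps any tree can need (number of
#' distinct unambiguously observed states minus one) and the maximum any
#' binary tree can need (number of unambiguously scored taxa minus the count
#' of the modal state). Cells that are missing, gap or polymorphic are
#' ambiguous and contribute to neither bound; an all-ambiguous character gets
#' (0, 0).
#'
#' @param matrix a [character_matrix()].
#' @return a data frame with columns `min_steps`, `max_steps` (one row per
#'   character) and an `informative` logical column (`max_steps > min_steps`).
#' @export
char_step_bounds <- function(matrix) {
  stopifnot(inherits(matrix, "character_matrix"))
  res <- t(vapply(seq_len(matrix$n_chars), function(j) {
    col <- matrix$cells[, j]
    unamb <- col[!(col %in% c(matrix$missing_char, matrix$gap_char)) &
                   !grepl("/", col)]
    if (!length(unamb)) return(c(0, 0))
    tab <- table(unamb)
    c(length(tab) - 1L, length(unamb) - max(tab))
  }, c(0, 0)))
  data.frame(min_steps = res[, 1], max_steps = res[, 2],
             informative = res[, 2] > res[, 1])
}

#' Ensemble consistency and retention indices
#'
#' CI = sum(min_steps) / L and RI = (sum(max_steps) - L) /
#' (sum(max_steps) - sum(min_steps)) for a tree of length `L` on `matrix`,
#' reported to 2 decimals. By default all characters enter the sums
#' (parsimony-uninformative ones included, the convention of the usual
#' headline CI); `exclude_uninformative = TRUE` drops uninformative
#' characters from the sums and subtracts their (fixed) contribution from
#' `L`.
#'
#' @param tree_length parsimony steps of the tree being summarized.
#' @param matrix a [character_matrix()].
#' @param exclude_uninformative drop parsimony-uninformative characters.
#' @return list with `CI`, `RI` (NA with a warning when no informative
#'   variation exists), and the underlying `sum_min`, `sum_max`, `length`.
#' @export
ensemble_ci_ri <- function(tree_length, matrix, exclude_uninformative = FALSE) {
  b <- char_step_bounds(matrix)
  L <- tree_length
  if (exclude_uninformative) {
    L <- L - sum(b$min_steps[!b$informative])
    b <- b[b$informative, , drop = FALSE]
  }
  smin <- sum(b$min_steps); smax <- sum(b$max_steps)
  if (L < smin)
    stopf("tree length %g below the additive minimum %g", L, smin)
  ci <- if (L > 0) round_half_up(smin / L, 2) else NA_real_
  ri <- if (smax > smin) round_half_up((smax - L) / (smax - smin), 2)
        else {
          warning("no informative variation: RI undefined", call. = FALSE)
          NA_real_
        }
  list(CI = ci, RI = ri, sum_min = smin, sum_max = smax, length = L)
}

# ---- tree surgery for stepwise addition and TBR -----------------------------

# attach a new leaf in the middle of edge `edge_index`
attach_leaf <- function(tree, edge_index, label) {
  E <- tree$edge
  ntip <- length(tree$tip.label)
  # shift ids: old internals +1 (new tip takes id ntip+1)
  sh <- function(v) ifelse(v > ntip, v + 1L, v)
  E2 <- cbind(sh(E[, 1]), sh(E[, 2]))
  w <- max(E2) + 1L
  u <- E2[edge_index, 1]; v <- E2[edge_index, 2]
  E2[edge_index, ] <- c(u, w)
  E2 <- rbind(E2, c(w, v), c(w, ntip + 1L))
  build_phylo(E2, c(tree$tip.label, label))
}

# all unrooted binary trees on 3 taxa collapse to one topology
star3 <- function(labels) {
  build_phylo(matrix(c(4L, 1L, 4L, 2L, 4L, 3L), ncol = 2, byrow = TRUE),
              labels)
}

# bipartition (tip label set below each edge); list parallel to edge rows
edge_tipsets <- function(tree) {
  E <- tree$edge
  ntip <- length(tree$tip.label)
  po <- postorder_edges(tree)
  below <- vector("list", max(E))
  for (i in seq_len(ntip)) below[[i]] <- i
  out <- vector("list", nrow(E))
  for (e in po) {
    ch <- E[e, 2]
    out[[e]] <- below[[ch]]
    p <- E[e, 1]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply(out, function(ix) tree$tip.label[ix])
}

# canonical key of one split (side not containing the reference leaf)
split_key <- function(side, all_labels) {
  ref <- min(all_labels)
  s <- if (ref %in% side) setdiff(all_labels, side) else side
  paste(sort(s), collapse = "|")
}

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge of the unrooted topology defines a bipartition of the
#' leaf set; bipartitions are returned as canonical keys (the sorted side not
#' containing the alphabetically first leaf, joined by `|`). Used for tree
#' identity, consensus and bootstrap tabulation.
#'
#' @param tree an [ape::phylo] tree.
#' @return character vector of split keys (may be empty for a star tree).
#' @export
tree_bipartitions <- function(tree) {
  E <- tree$edge
  ntip <- length(tree$tip.label)
  sets <- edge_tipsets(tree)
  keys <- character(0)
  root <- setdiff(E[, 1], E[, 2])
  root_children <- sum(E[, 1] == root)
  for (e in seq_len(nrow(E))) {
    sz <- length(sets[[e]])
    if (sz <= 1 || sz >= ntip - 1) next        # trivial on the unrooted tree
    keys <- c(keys, split_key(sets[[e]], tree$tip.label))
  }
  # a rooted binary tree's two root edges give the same unrooted split
  unique(keys)
}

# identity on unrooted topologies
topology_key <- function(tree) {
  paste(sort(tree_bipartitions(tree)), collapse = ";")
}

# split the unrooted tree at edge e; returns the two induced subtrees (a bare
# label for single-leaf sides)
split_tree_at <- function(tree, edge_index, tipsets = NULL) {
  sets <- tipsets %||% edge_tipsets(tree)
  X <- sets[[edge_index]]
  Y <- setdiff(tree$tip.label, X)
  side <- function(S) {
    if (length(S) == 1) return(S)
    sub <- ape::keep.tip(tree, S)
    if (length(S) == 2) return(sub)   # bare edge; nothing to unroot
    ape::unroot(sub)
  }
  list(side(X), side(Y))
}

# join two components (phylo or bare leaf label) at edges e1/e2 (ignored for
# bare leaves); returns an unrooted phylo on the union of the leaves
join_components <- function(t1, e1, t2, e2) {
  leaf1 <- is.character(t1)
  leaf2 <- is.character(t2)
  if (leaf1 && leaf2) stopf("cannot join two bare leaves")
  if (leaf1) return(attach_leaf_unrooted(t2, e2, t1))
  if (leaf2) return(attach_leaf_unrooted(t1, e1, t2))
  n1 <- length(t1$tip.label); n2 <- length(t2$tip.label)
  E1 <- t1$edge
  # relabel t2 tips after t1's, internals after everything
  off_tip <- n1
  ntot <- n1 + n2
  m1 <- max(E1)
  sh1 <- function(v) ifelse(v > n1, v + n2, v)       # t1 internals shifted
  E1b <- cbind(sh1(E1[, 1]), sh1(E1[, 2]))
  E2 <- t2$edge
  sh2 <- function(v) ifelse(v > n2, v - n2 + ntot + t1$Nnode, v + off_tip)
  E2b <- cbind(sh2(E2[, 1]), sh2(E2[, 2]))
  u <- max(c(E1b, E2b)) + 1L
  v <- u + 1L
  # subdivide e1 in t1 with u, e2 in t2 with v, connect u-v
  a1 <- E1b[e1, 1]; b1 <- E1b[e1, 2]
  E1b[e1, ] <- c(a1, u)
  a2 <- E2b[e2, 1]; b2 <- E2b[e2, 2]
  E2b[e2, ] <- c(a2, v)
  edge <- rbind(E1b, c(u, b1), E2b, c(v, b2), c(u, v))
  # u currently has no parent and v has parent u: u is the (degree-3...) root?
  # u has children b1, v; plus its own parent a1 -> wait, a1 is u's parent.
  build_phylo_unrooted(edge, c(t1$tip.label, t2$tip.label))
}

# attach a bare leaf onto edge e of an unrooted tree (2-tip trees allowed)
attach_leaf_unrooted <- function(tree, e, label) {
  if (is.character(tree)) stopf("cannot attach to a bare leaf")
  ntip <- length(tree$tip.label)
  if (ntip == 2) {
    # single real edge; result is the 3-leaf star
    return(star3(c(tree$tip.label, label)))
  }
  tr <- attach_leaf(tree, e, label)
  ape::unroot(tr)
}

# build a phylo from an edge list that may contain degree-2 nodes left over
# from subdivision bookkeeping; suppresses them, then normalizes numbering
build_phylo_unrooted <- function(edge, tip_labels) {
  ntip <- length(tip_labels)
  repeat {
    deg_in <- tabulate(edge[, 2], nbins = max(edge))
    deg_out <- tabulate(edge[, 1], nbins = max(edge))
    deg <- deg_in + deg_out
    d2 <- which(deg == 2 & seq_along(deg) > ntip)
    d2 <- d2[d2 %in% edge]
    if (!length(d2)) break
    nd <- d2[1]
    up <- which(edge[, 2] == nd)
    down <- which(edge[, 1] == nd)
    if (length(up) == 1 && length(down) == 1) {
      edge[up, 2] <- edge[down, 2]
      edge <- edge[-down, , drop = FALSE]
    } else if (length(down) == 2) {
      # nd is a root of degree 2: splice its two children together
      edge[down[1], ] <- c(edge[down[1], 2], edge[down[2], 2])
      # orientation fixed below by rebuild
      edge <- edge[-down[2], , drop = FALSE]
      edge <- orient_edges(edge, ntip)
    } else stopf("internal error: cannot suppress node")
  }
  edge <- orient_edges(edge, ntip)
  ape::unroot(build_phylo(edge, tip_labels))
}

# re-orient an undirected edge list away from an arbitrary internal root
orient_edges <- function(edge, ntip) {
  nodes <- unique(c(edge))
  adj <- list()
  for (i in seq_len(nrow(edge))) {
    a <- as.character(edge[i, 1]); b <- as.character(edge[i, 2])
    adj[[a]] <- c(adj[[a]], edge[i, 2])
    adj[[b]] <- c(adj[[b]], edge[i, 1])
  }
  root <- nodes[nodes > ntip][1]
  out <- matrix(0L, nrow(edge), 2)
  k <- 0L
  visited <- logical(max(nodes))
  stack <- root
  visited[root] <- TRUE
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (nb in adj[[as.character(nd)]]) {
      if (!visited[nb]) {
        visited[nb] <- TRUE
        k <- k + 1L
        out[k, ] <- c(nd, nb)
        stack <- c(stack, nb)
      }
    }
  }
  out[seq_len(k), , drop = FALSE]
}

#' TBR neighbourhood of an unrooted binary tree
#'
#' All trees obtainable by one tree-bisection-reconnection move: cut any
#' edge, re-root each resulting fragment on any of its edges, and reconnect.
#' Pendant-edge bisections reduce to subtree-pruning-regrafting of single
#' leaves. Duplicates (by bipartition set) are removed; the input topology is
#' excluded.
#'
#' @param tree an unrooted binary [ape::phylo] tree with >= 4 leaves.
#' @return list of `phylo` trees.
#' @export
tbr_neighbours <- function(tree) {
  tree <- ape::unroot(tree)
  sets <- edge_tipsets(tree)
  self_key <- topology_key(tree)
  seen <- new.env(parent = emptyenv())
  assign(self_key, TRUE, envir = seen)
  out <- list()
  for (e in seq_along(sets)) {
    parts <- split_tree_at(tree, e, sets)
    t1 <- parts[[1]]; t2 <- parts[[2]]
    e1s <- if (is.character(t1)) 0L else seq_len(nrow(t1$edge))
    e2s <- if (is.character(t2)) 0L else seq_len(nrow(t2$edge))
    for (a in e1s) for (b in e2s) {
      cand <- join_components(t1, a, t2, b)
      key <- topology_key(cand)
      if (!exists(key, envir = seen)) {
        assign(key, TRUE, envir = seen)
        out[[length(out) + 1L]] <- cand
      }
    }
  }
  out
}

# ---- heuristic search -------------------------------------------------------

#' Heuristic-search configuration
#'
#' @param n_replicates random-addition-sequence replicates.
#' @param trees_kept_per_replicate cap on equally short trees retained per
#'   replicate during TBR swapping.
#' @param seed integer master seed; the search is deterministic given it.
#' @param max_trees_total cap on the global deduplicated tree set.
#' @return an object of class `search_config`.
#' @export
search_config <- function(n_replicates = 10, trees_kept_per_replicate = 10,
                          seed = 20210211, max_trees_total = 1000) {
  vals <- c(n_replicates, trees_kept_per_replicate, max_trees_total)
  if (any(vals < 1)) stopf("all search_config limits must be positive")
  structure(list(n_replicates = as.integer(n_replicates),
                 trees_kept_per_replicate = as.integer(trees_kept_per_replicate),
                 seed = as.integer(seed),
                 max_trees_total = as.integer(max_trees_total)),
            class = "search_config")
}

#' Maximum-parsimony heuristic search
#'
#' PAUP-style search: each replicate builds a starting tree by random-order
#' greedy stepwise addition, then swaps it with tree-bisection-reconnection
#' (TBR) until no neighbour is shorter, keeping up to
#' `trees_kept_per_replicate` equally short trees per replicate. The result
#' is the deduplicated union of the shortest trees found across replicates,
#' truncated (with a warning) at `max_trees_total`.
#'
#' @param matrix a [character_matrix()] with at least 4 taxa.
#' @param config a [search_config()].
#' @return an object of class `tree_set`: list with `trees` (list of
#'   unrooted `phylo`), `length` (parsimony steps), and search metadata.
#' @export
heuristic_search <- function(matrix, config = search_config()) {
  stopifnot(inherits(matrix, "character_matrix"),
            inherits(config, "search_config"))
  if (matrix$n_taxa < 4) stopf("heuristic search needs at least 4 taxa")
  enc <- encode_matrix(matrix)
  full <- attr(enc, "full_mask")
  if (all(enc == full))
    stopf("matrix is entirely ambiguous ('?'/'-'); nothing to search on")
  set.seed(substream_seed(config$seed, "search"))
  score <- function(tr) {
    prep <- fitch_prep(tr)
    fitch_steps(prep, enc[prep$tip_labels, , drop = FALSE])
  }

  best_len <- Inf
  best <- list()   # keyed list of trees
  best_keys <- character(0)
  moves_examined <- 0L
  truncated <- FALSE

  for (rep_i in seq_len(config$n_replicates)) {
    order_i <- sample(matrix$taxon_names)
    tr <- star3(order_i[1:3])
    for (tx in order_i[-(1:3)]) {
      cands <- lapply(seq_len(nrow(tr$edge)), function(e)
        ape::unroot(attach_leaf(tr, e, tx)))
      lens <- vapply(cands, score, 0L)
      ties <- which(lens == min(lens))
      tr <- cands[[ties[sample.int(length(ties), 1)]]]
    }
    # TBR hill climb with plateau collection
    pool_len <- score(tr)
    pool <- stats::setNames(list(tr), topology_key(tr))
    queue <- names(pool)
    while (length(queue)) {
      key <- queue[1]; queue <- queue[-1]
      cur <- pool[[key]]
      if (is.null(cur)) next
      nb <- tbr_neighbours(cur)
      moves_examined <- moves_examined + length(nb)
      lens <- vapply(nb, score, 0L)
      if (length(lens) && min(lens) < pool_len) {
        pool_len <- min(lens)
        ix <- which(lens == pool_len)
        ix <- ix[sample.int(length(ix))]
        pool <- list()
        for (i in ix[seq_len(min(length(ix), config$trees_kept_per_replicate))])
          pool[[topology_key(nb[[i]])]] <- nb[[i]]
        queue <- names(pool)
      } else {
        for (i in which(lens == pool_len)) {
          k2 <- topology_key(nb[[i]])
          if (is.null(pool[[k2]]) &&
              length(pool) < config$trees_kept_per_replicate) {
            pool[[k2]] <- nb[[i]]
            queue <- c(queue, k2)
          }
        }
      }
    }
    if (pool_len < best_len) {
      best_len <- pool_len
      best <- pool
      best_keys <- names(pool)
    } else if (pool_len == best_len) {
      for (k in names(pool)) if (is.null(best[[k]])) best[[k]] <- pool[[k]]
    }
    if (length(best) > config$max_trees_total) {
      warning("max_trees_total reached; tree set truncated", call. = FALSE)
      truncated <- TRUE
      best <- best[seq_len(config$max_trees_total)]
    }
  }

  structure(
    list(trees = unname(best), length = best_len,
         n_trees = length(best),
         metadata = list(n_replicates = config$n_replicates,
                         trees_kept_per_replicate =
                           config$trees_kept_per_replicate,
                         seed = config$seed,
                         moves_examined = moves_examined,
                         truncated = truncated)),
    class = "tree_set"
  )
}

#' @export
print.tree_set <- function(x, ...) {
  cat(sprintf("tree set: %d tree(s) of length %g (%d replicates, seed %d)\n",
              x$n_trees, x$length, x$metadata$n_replicates,
              x$metadata$seed))
  invisible(x)
}

#' Exhaustive minimum parsimony length (small problems)
#'
#' Enumerates every unrooted binary topology (via [phangorn::allTrees] when
#' available, otherwise by recursive leaf addition) and returns the global
#' minimum Fitch length. Intended as an oracle for <= 9 taxa.
#'
#' @param matrix a [character_matrix()].
#' @return list with `length` (the optimum) and `n_topologies` examined.
#' @export
exhaustive_search <- function(matrix) {
  stopifnot(inherits(matrix, "character_matrix"))
  n <- matrix$n_taxa
  if (n > 9) stopf("exhaustive search is limited to 9 taxa (got %d)", n)
  enc <- encode_matrix(matrix)
  key <- paste(sort(matrix$taxon_names), collapse = "|")
  preps <- .topology_prep_cache[[key]]
  if (is.null(preps)) {
    preps <- lapply(all_unrooted_topologies(matrix$taxon_names), fitch_prep)
    .topology_prep_cache[[key]] <- preps
  }
  lens <- vapply(preps, function(prep)
    fitch_steps(prep, enc[prep$tip_labels, , drop = FALSE]), 0L)
  list(length = min(lens), n_topologies = length(preps))
}

# prepared traversals for enumerated topologies, keyed by sorted label set
.topology_prep_cache <- new.env(parent = emptyenv())

# every unrooted binary topology on the given labels
all_unrooted_topologies <- function(labels) {
  if (requireNamespace("phangorn", quietly = TRUE) && length(labels) >= 4) {
    tt <- phangorn::allTrees(length(labels), tip.label = labels)
    # index with [[ to expand the shared-TipLabel compression
    return(lapply(seq_along(tt), function(i) tt[[i]]))
  }
  if (length(labels) < 4) return(list(star3(labels)))
  grow <- function(trees, lab) {
    out <- list()
    for (tr in trees)
      for (e in seq_len(nrow(tr$edge)))
        out[[length(out) + 1L]] <- ape::unroot(attach_leaf(tr, e, lab))
    out
  }
  trees <- list(star3(labels[1:3]))
  for (lab in labels[-(1:3)]) trees <- grow(trees, lab)
  trees
}
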