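#' Dispersal-vicariance (DIVA) parsimony reconstruction
#'
#' Exact dynamic-programming reconstruction of ancestral distributions under
#' the DIVA event costs: speciation is free, either by vicariance (a
#' widespread ancestral distribution divides into two nonempty disjoint
#' parts, one per daughter) or by duplication (a single-area ancestor is
#' inherited by both daughters); each area gained by dispersal along a
#' branch costs 1, and each area lost by extinction costs 1. Unlike the DEC
#' state space, no adjacency restriction applies: all nonempty subsets of
#' the areas (up to `max_areas`) are candidate distributions.
#'
#' The DP computes, for every node and every candidate distribution, the
#' minimum event count of the subtree (upward pass) and of the rest of the
#' tree (downward pass); a distribution is reported at a node iff it
#' participates in at least one globally optimal reconstruction. Per node,
#' at most `max_alternatives` optimal distributions are kept, in
#' deterministic order (size, then bitmask).
#'
#' @param tree Rooted binary `phylo` tree (branch lengths ignored).
#' @param tips A `tip_areas` table (multi-area tips allowed).
#' @param aset An `area_set` (adjacency ignored).
#' @param max_areas Optional cap on the number of areas in ancestral
#'   distributions (`NULL` = unconstrained).
#' @param max_alternatives Cap on retained optimal distributions per node
#'   (default 1000).
#' @return A `diva_reconstruction`: list with `cost` (minimum total
#'   dispersal + extinction count), `node_distributions` (per internal node,
#'   character vector of optimal distributions), `root` (node id).
#' @examples
#' tr <- parse_newick("(a:1,b:1);")
#' dv <- diva_reconstruct(tr, tip_areas(c(a = "A", b = "B")))
#' dv$cost  # 0: pure vicariance
#' @export
diva_reconstruct <- function(tree, tips, aset = default_area_set(),
                             max_areas = NULL, max_alternatives = 1000L) {
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) stop("tree must be rooted and binary")
  validate_tip_areas(tree, tips)
  n_areas <- length(aset$areas)
  if (is.null(max_areas)) max_areas <- n_areas
  masks <- seq_len(2L^n_areas - 1L)
  sizes <- bit_count(masks)
  states <- masks[sizes <= max_areas]
  states <- states[order(bit_count(states), states)]
  ns <- length(states)
  sidx <- integer(2L^n_areas); sidx[states] <- seq_len(ns)

  tip_masks <- range_mask(unname(tips[tree$tip.label]), aset)
  if (any(tip_masks == 0L)) stop("tip with empty area set")

  # symmetric-difference cost between inherited and realized distributions:
  # |Z \ Y| dispersals + |Y \ Z| extinctions
  dist <- outer(states, states, function(a, b) bit_count(bitwXor(a, b)))

  # allowed splits per state: list of (left index, right index) pairs
  splits <- lapply(states, function(m) {
    if (bit_count(m) == 1L) return(cbind(sidx[m], sidx[m]))
    subs <- Filter(function(s) bitwAnd(s, m) == s && s != 0L && s != m,
                   seq_len(m))
    out <- cbind(sidx[subs], sidx[m - subs])
    out[out[, 1] > 0L & out[, 2] > 0L, , drop = FALSE]
  })

  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  INF <- 1e9  # numeric sentinel: sums of two sentinels must not overflow

  # upward: cost[n, x] = min events in subtree of n given n realizes state x;
  # m_up[n, y] = min over realized z of dist(y, z) + cost[n, z]  (branch above n)
  cost <- matrix(INF, nn, ns)
  m_up <- matrix(INF, nn, ns)
  for (i in seq_len(ntip)) {
    k <- sidx[tip_masks[i]]
    if (k == 0L) stop("tip distribution exceeds max_areas")
    cost[i, k] <- 0L
    m_up[i, ] <- dist[, k]
  }
  nodes <- unique(po$edge[, 1])
  for (p in nodes) {
    ch <- po$edge[kids[[as.character(p)]], 2]
    for (xi in seq_len(ns)) {
      sp <- splits[[xi]]
      cost[p, xi] <- min(m_up[ch[1], sp[, 1]] + m_up[ch[2], sp[, 2]])
    }
    m_up[p, ] <- apply(dist + rep(cost[p, ], each = ns), 1, min)
  }
  root <- ntip + 1L
  total <- min(cost[root, ])

  # downward: out[n, z] = min events outside the subtree of n given n
  # realizes z; root has no branch above.
  out <- matrix(INF, nn, ns)
  out[root, ] <- 0L
  for (p in rev(nodes)) {
    ch <- po$edge[kids[[as.character(p)]], 2]
    # h[x] = out[p, x] minimized over ... for each split side
    for (side in 1:2) {
      me <- ch[side]; sib <- ch[3 - side]
      best_inherit <- rep(INF, ns)  # min outside cost given inherited state y at top of me's branch
      for (xi in seq_len(ns)) {
        if (out[p, xi] >= INF) next
        sp <- splits[[xi]]
        mine <- sp[, side]; theirs <- sp[, 3 - side]
        v <- out[p, xi] + m_up[sib, theirs]
        for (j in seq_along(mine)) {
          if (v[j] < best_inherit[mine[j]]) best_inherit[mine[j]] <- v[j]
        }
      }
      out[me, ] <- apply(best_inherit + dist, 2, min)
    }
  }

  node_dists <- lapply(root:nn, function(n) {
    opt <- which(cost[n, ] + out[n, ] == total)
    opt <- opt[seq_len(min(length(opt), max_alternatives))]
    range_label(states[opt], aset)
  })
  names(node_dists) <- as.character(root:nn)
  structure(list(cost = as.integer(total), node_distributions = node_dists,
                 root = root, max_areas = max_areas, tree = tree),
            class = "diva_reconstruction")
}

#' @export
print.diva_reconstruction <- function(x, ...) {
  cat(sprintf("DIVA reconstruction: minimum cost %d (dispersal + extinction events)\n",
              x$cost))
  cat(sprintf("root (node %d): %s\n", x$root,
              paste(x$node_distributions[[as.character(x$root)]], collapse = " | ")))
  invisible(x)
}
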