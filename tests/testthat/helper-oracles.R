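# Independent brute-force oracles. These deliberately avoid the package's
# pruning/DP recursions: likelihoods and costs are obtained by exhaustive
# enumeration of every joint assignment of internal-node states (and, for
# DEC, of the cladogenetic scenario at every node).

# DEC likelihood by enumeration over (scenario at every internal node).
brute_dec_loglik <- function(tree, tips, params, aset = default_area_set(),
                             root_range = NULL) {
  sp <- biogeodec:::dec_state_space(aset, NULL)
  Q <- build_q(sp, params)
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  Plist <- vector("list", nn)
  for (r in seq_len(nrow(po$edge)))
    Plist[[po$edge[r, 2]]] <- branch_probs(Q, po$edge.length[r])
  cl <- sp$clado
  tipidx <- sp$idx_of[biogeodec:::range_mask(unname(tips[tree$tip.label]), aset)]
  internals <- (ntip + 1L):nn
  nout <- length(cl$parent)
  grid <- do.call(expand.grid, rep(list(seq_len(nout)), length(internals)))
  lik <- rep(1, nrow(grid))
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  node_range <- function(node) {
    if (node <= ntip) rep(tipidx[node], nrow(grid))
    else cl$parent[grid[[match(node, internals)]]]
  }
  for (k in seq_along(internals)) {
    n <- internals[k]
    o <- grid[[k]]
    lik <- lik * cl$weight[o]
    ch <- po$edge[kids[[as.character(n)]], 2]
    starts <- list(cl$left[o], cl$right[o])
    for (side in 1:2) {
      cn <- ch[side]
      lik <- lik * Plist[[cn]][cbind(starts[[side]], node_range(cn))]
    }
  }
  if (!is.null(root_range)) {
    rr <- cl$parent[grid[[match(ntip + 1L, internals)]]]
    lik <- lik * (sp$labels[rr] == root_range)
  }
  tot <- sum(lik)
  if (tot <= 0) -Inf else log(tot)
}

# Mk likelihood (and exact node-state marginals) by enumeration over
# internal-node states.
brute_mk <- function(tree, tips, rates, aset = default_area_set()) {
  ns <- length(aset$areas)
  Q <- biogeodec:::mk_q_matrix(rates, ns)
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  Plist <- vector("list", nn)
  for (r in seq_len(nrow(po$edge)))
    Plist[[po$edge[r, 2]]] <- branch_probs(Q, po$edge.length[r])
  tipst <- match(unname(tips[tree$tip.label]), aset$areas)
  internals <- (ntip + 1L):nn
  grid <- do.call(expand.grid, rep(list(seq_len(ns)), length(internals)))
  state_of <- function(node) {
    if (node <= ntip) rep(tipst[node], nrow(grid))
    else grid[[match(node, internals)]]
  }
  lik <- rep(1 / ns, nrow(grid))  # uniform root prior
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1]; cn <- po$edge[r, 2]
    lik <- lik * Plist[[cn]][cbind(state_of(p), state_of(cn))]
  }
  tot <- sum(lik)
  marg <- sapply(seq_along(internals), function(k)
    vapply(seq_len(ns), function(s) sum(lik[grid[[k]] == s]), numeric(1)) / tot)
  marg <- t(marg)
  dimnames(marg) <- list(as.character(internals), aset$areas)
  list(lnL = if (tot <= 0) -Inf else log(tot), node_probs = marg)
}

# DIVA minimum cost and optimal per-node distributions by enumeration over
# realized distributions at every internal node.
brute_diva <- function(tree, tips, aset = default_area_set(), max_areas = NULL) {
  n_areas <- length(aset$areas)
  if (is.null(max_areas)) max_areas <- n_areas
  masks <- seq_len(2L^n_areas - 1L)
  states <- masks[biogeodec:::bit_count(masks) <= max_areas]
  states <- states[order(biogeodec:::bit_count(states), states)]
  ns <- length(states)
  sidx <- integer(2L^n_areas); sidx[states] <- seq_len(ns)
  dist <- outer(states, states, function(a, b) biogeodec:::bit_count(bitwXor(a, b)))
  # M[x, z1, z2]: cheapest way for realized x to split and evolve into
  # realized child distributions z1, z2
  M <- array(Inf, c(ns, ns, ns))
  for (xi in seq_len(ns)) {
    m <- states[xi]
    sp <- if (biogeodec:::bit_count(m) == 1L) cbind(xi, xi) else {
      subs <- Filter(function(s) bitwAnd(s, m) == s && s != 0L && s != m, seq_len(m))
      cbind(sidx[subs], sidx[m - subs])
    }
    for (z1 in seq_len(ns)) for (z2 in seq_len(ns))
      M[xi, z1, z2] <- min(dist[sp[, 1], z1] + dist[sp[, 2], z2])
  }
  tipst <- sidx[biogeodec:::range_mask(unname(tips[tree$tip.label]), aset)]
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  internals <- (ntip + 1L):nn
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  grid <- do.call(expand.grid, rep(list(seq_len(ns)), length(internals)))
  state_of <- function(node) {
    if (node <= ntip) rep(tipst[node], nrow(grid))
    else grid[[match(node, internals)]]
  }
  cost <- rep(0, nrow(grid))
  for (k in seq_along(internals)) {
    n <- internals[k]
    ch <- po$edge[kids[[as.character(n)]], 2]
    cost <- cost + M[cbind(grid[[k]], state_of(ch[1]), state_of(ch[2]))]
  }
  total <- min(cost)
  opt <- lapply(seq_along(internals), function(k)
    biogeodec:::range_label(states[sort(unique(grid[[k]][cost == total]))], aset))
  names(opt) <- as.character(internals)
  list(cost = total, node_distributions = opt)
}
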