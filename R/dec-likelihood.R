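# ---- internal pruning machinery ----

# Map tip range labels to state indices; errors on missing tips or tips whose
# range is not an allowed state.
dec_tip_states <- function(tree, tips, space) {
  validate_tip_areas(tree, tips)
  masks <- range_mask(unname(tips[tree$tip.label]), space$aset)
  idx <- space$idx_of[masks]
  if (any(masks == 0L)) stop("tip with empty range")
  if (any(idx == 0L))
    stop("tip range not an allowed state: ",
         paste(unique(tips[tree$tip.label][idx == 0L]), collapse = ", "))
  idx
}

# Post-order pruning pass over the range CTMC with cladogenesis at nodes.
# Returns per-node conditional likelihood vectors (optionally rescaled, with
# per-node accumulated log scale) and, when keep = TRUE, the per-child
# branch-bottom vectors DL and transition matrices needed by the downward
# pass of reconstruct_splits().
dec_upward <- function(tree, tip_idx, space, Q, scale = TRUE, keep = FALSE) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  S <- space$n_states
  Pfun <- ctmc_prob_factory(Q)
  partial <- matrix(0, nn, S)
  partial[cbind(seq_len(ntip), tip_idx)] <- 1
  logsc <- numeric(nn)
  DL <- if (keep) matrix(NA_real_, nn, S) else NULL
  Pmats <- if (keep) vector("list", nn) else NULL
  cl <- space$clado
  edge <- po$edge
  elen <- po$edge.length
  nodes <- unique(edge[, 1])  # postorder: children before parents
  child_rows <- split(seq_len(nrow(edge)), edge[, 1])
  for (p in nodes) {
    rows <- child_rows[[as.character(p)]]
    ch <- edge[rows, 2]
    P1 <- Pfun(elen[rows[1]])
    P2 <- Pfun(elen[rows[2]])
    dl1 <- as.vector(P1 %*% partial[ch[1], ])
    dl2 <- as.vector(P2 %*% partial[ch[2], ])
    if (keep) {
      DL[ch[1], ] <- dl1; DL[ch[2], ] <- dl2
      Pmats[[ch[1]]] <- P1; Pmats[[ch[2]]] <- P2
    }
    vals <- cl$weight * dl1[cl$left] * dl2[cl$right]
    clv <- numeric(S)
    clv[seq_len(space$K)] <- rowsum(vals, cl$parent)
    sc <- logsc[ch[1]] + logsc[ch[2]]
    if (scale) {
      mx <- max(clv)
      if (mx > 0) {
        clv <- clv / mx
        sc <- sc + log(mx)
      }
    }
    partial[p, ] <- clv
    logsc[p] <- sc
  }
  root <- ntip + 1L
  list(partial = partial, logsc = logsc, root = root, ntip = ntip,
       edge = edge, elen = elen, DL = DL, Pmats = Pmats)
}

#' DEC log-likelihood of tip ranges on a chronogram
#'
#' Computes the log-likelihood of observed tip ranges under the
#' dispersal-extinction-cladogenesis model by post-order pruning: anagenetic
#' range evolution along branches follows the CTMC of [build_q()], and at
#' every internal node the ancestral range is inherited through one of the
#' equally weighted cladogenetic scenarios of [cladogenesis_outcomes()]. At
#' the root the conditional likelihoods of all allowed (non-null) ranges are
#' summed without a range-size prior; no conditioning on survival is applied.
#' An impossible data set yields `-Inf`.
#'
#' @param tree Ultrametric binary `phylo` chronogram.
#' @param tips A `tip_areas` table covering every tip.
#' @param params A `dec_params`.
#' @param aset An `area_set` (default [default_area_set()]).
#' @param max_range_size Optional cap on ancestral range size.
#' @param root_range Optional range label fixing the root state instead of
#'   summing (used by tests and simulations).
#' @return Log-likelihood in nats (possibly `-Inf`).
#' @export
dec_loglik <- function(tree, tips, params, aset = default_area_set(),
                       max_range_size = NULL, root_range = NULL) {
  validate_chronogram(tree)
  space <- if (inherits(aset, "dec_state_space")) aset else dec_state_space(aset, max_range_size)
  tip_idx <- dec_tip_states(tree, tips, space)
  Q <- build_q(space, params)
  up <- dec_upward(tree, tip_idx, space, Q, scale = TRUE)
  clr <- up$partial[up$root, ]
  L <- if (is.null(root_range)) {
    sum(clr[seq_len(space$K)])
  } else {
    k <- space$idx_of[range_mask(root_range, space$aset)]
    if (k == 0L) stop("root_range is not an allowed state")
    clr[k]
  }
  if (L <= 0) return(-Inf)
  log(L) + up$logsc[up$root]
}
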