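#' Ancestral range-inheritance scenarios at every internal node
#'
#' For each internal node, evaluates the likelihood of the whole data set
#' with that node constrained to each cladogenetic scenario (ancestral range
#' plus the ranges inherited by the two daughters), via an upward pruning
#' pass combined with a downward "outside" pass. Each scenario's relative
#' probability is its likelihood divided by the summed likelihood over all
#' scenarios at that node (which equals the global likelihood). Scenarios
#' within `lnl_window` log-likelihood units of the node's best scenario are
#' retained, best first.
#'
#' The implementation works on unscaled likelihoods and is intended for trees
#' of up to a few hundred tips.
#'
#' @param fit A `dec_fit` from [fit_dec()].
#' @param tree,tips Data to reconstruct on (default: those stored in `fit`).
#' @param lnl_window Retention window in log-likelihood units (default 2).
#' @return A `dec_splits` object: list with `nodes` (per-node data frames of
#'   `range`, `left`, `right`, `lnL`, `rel_prob`), `lnL` (global), and
#'   `node_ages`.
#' @export
reconstruct_splits <- function(fit, tree = fit$tree, tips = fit$tips,
                               lnl_window = 2) {
  stopifnot(inherits(fit, "dec_fit"))
  space <- dec_state_space(fit$aset, fit$max_range_size)
  tip_idx <- dec_tip_states(tree, tips, space)
  params <- dec_params(fit$d, fit$e, D = fit$D, model = fit$model)
  Q <- build_q(space, params)
  up <- dec_upward(tree, tip_idx, space, Q, scale = FALSE, keep = TRUE)
  S <- space$n_states
  K <- space$K
  cl <- space$clado
  ntip <- up$ntip
  nn <- ntip + tree$Nnode

  # downward (outside) pass: G[n, r] = likelihood of everything outside the
  # subtree of n, given node n is in range r; at the root every allowed
  # range has outside likelihood 1 (unweighted root sum).
  G <- matrix(0, nn, S)
  G[up$root, seq_len(K)] <- 1
  pre <- rev(unique(up$edge[, 1]))  # parents before children
  kids <- split(seq_len(nrow(up$edge)), up$edge[, 1])
  for (p in pre) {
    rows <- kids[[as.character(p)]]
    ch <- up$edge[rows, 2]
    vals <- G[p, cl$parent] * cl$weight
    for (side in 1:2) {
      me <- ch[side]; sib <- ch[3 - side]
      own <- if (side == 1) cl$left else cl$right
      other <- if (side == 1) cl$right else cl$left
      x <- vals * up$DL[sib, other]
      H <- numeric(S)
      agg <- rowsum(x, own)
      H[as.integer(rownames(agg))] <- agg
      if (me > ntip) G[me, ] <- as.vector(H %*% up$Pmats[[me]])
    }
  }

  total <- sum(up$partial[up$root, seq_len(K)])
  if (total <= 0) stop("global likelihood is zero; nothing to reconstruct")
  internal <- (ntip + 1L):nn
  out <- vector("list", length(internal))
  names(out) <- as.character(internal)
  for (n in internal) {
    rows <- kids[[as.character(n)]]
    ch <- up$edge[rows, 2]
    lik <- G[n, cl$parent] * cl$weight * up$DL[ch[1], cl$left] * up$DL[ch[2], cl$right]
    node_total <- sum(lik)
    keep <- lik > 0
    df <- data.frame(range = space$labels[cl$parent[keep]],
                     left = space$labels[cl$left[keep]],
                     right = space$labels[cl$right[keep]],
                     lnL = log(lik[keep]),
                     rel_prob = lik[keep] / node_total,
                     stringsAsFactors = FALSE)
    df <- df[order(-df$lnL), , drop = FALSE]
    df <- df[df$lnL >= df$lnL[1] - lnl_window, , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "node_total") <- node_total
    out[[as.character(n)]] <- df
  }
  structure(list(nodes = out, lnL = log(total),
                 node_ages = node_ages(tree)[internal],
                 tree = tree),
            class = "dec_splits")
}

#' @export
print.dec_splits <- function(x, ...) {
  cat(sprintf("DEC split reconstruction, global lnL = %.4f\n", x$lnL))
  for (n in names(x$nodes)) {
    df <- x$nodes[[n]]
    cat(sprintf("node %s (age %.2f): %s -> %s|%s (rel. prob %.2f)%s\n",
                n, x$node_ages[[match(n, names(x$nodes))]],
                df$range[1], df$left[1], df$right[1], df$rel_prob[1],
                if (nrow(df) > 1) sprintf(" + %d alternatives", nrow(df) - 1L) else ""))
  }
  invisible(x)
}

#' Tabulate a split reconstruction
#' @param x A `dec_splits` object.
#' @param ... Unused.
#' @return Data frame with one row per retained scenario per node.
#' @export
as.data.frame.dec_splits <- function(x, ...) {
  do.call(rbind, lapply(names(x$nodes), function(n) {
    df <- x$nodes[[n]]
    cbind(node = as.integer(n), df)
  }))
}
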