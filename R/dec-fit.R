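#' Maximum-likelihood DEC fit under a dispersal hypothesis
#'
#' Estimates the dispersal rate `d` and extinction rate `e` by bounded
#' quasi-Newton optimization on the log-rate scale (L-BFGS-B, bounds
#' `[1e-8, 10]` per Ma), restarted from three fixed points to guard against
#' flat likelihood surfaces near the boundary. Both rates are free under all
#' three hypotheses, so `k = 2` throughout.
#'
#' @inheritParams dec_loglik
#' @param hypothesis One of `"H0"`, `"HIA"`, `"HAI"` (see
#'   [build_dispersal_matrix()]).
#' @param starts Matrix of `(d, e)` starting points, one row each.
#' @return A `dec_fit`: list with `d`, `e`, `lnL`, `k`, `model`, the
#'   multiplier matrix `D`, and the data (`tree`, `tips`) used.
#' @export
fit_dec <- function(tree, tips, hypothesis = c("H0", "HIA", "HAI"),
                    aset = default_area_set(), max_range_size = NULL,
                    starts = rbind(c(1e-2, 1e-2), c(1e-3, 1e-4), c(1e-4, 1e-2))) {
  hypothesis <- match.arg(hypothesis)
  validate_chronogram(tree)
  space <- dec_state_space(aset, max_range_size)
  tip_idx <- dec_tip_states(tree, tips, space)
  D <- build_dispersal_matrix(hypothesis, aset)
  nll <- function(logpar) {
    p <- dec_params(exp(logpar[1]), exp(logpar[2]), D = D, model = hypothesis)
    ll <- tryCatch({
      Q <- build_q(space, p)
      up <- dec_upward(tree, tip_idx, space, Q, scale = TRUE)
      L <- sum(up$partial[up$root, seq_len(space$K)])
      if (L <= 0) -Inf else log(L) + up$logsc[up$root]
    }, error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  lb <- log(1e-8); ub <- log(10)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(log(starts[i, ]), nll, method = "L-BFGS-B",
            lower = c(lb, lb), upper = c(ub, ub),
            control = list(factr = 1e7, maxit = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || best$value >= 1e10)
    stop("likelihood is -Inf over the whole searched surface")
  d <- exp(best$par[1]); e <- exp(best$par[2])
  structure(list(d = d, e = e, lnL = -best$value, k = 2L, model = hypothesis,
                 D = D, aset = aset, max_range_size = max_range_size,
                 tree = tree, tips = tips, convergence = best$convergence),
            class = "dec_fit")
}

#' @export
print.dec_fit <- function(x, ...) {
  cat(sprintf("DEC fit [%s]: d = %.4g, e = %.4g, lnL = %.4f (k = %d)\n",
              x$model, x$d, x$e, x$lnL, x$k))
  invisible(x)
}

#' @export
logLik.dec_fit <- function(object, ...) {
  structure(object$lnL, df = object$k, class = "logLik")
}
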