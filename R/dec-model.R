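#' Dispersal multiplier matrix for a directional hypothesis
#'
#' Three hypotheses about the direction of dispersal involving area `A`
#' (the Indian Subcontinent): `H0` leaves every route open; `HIA`
#' ("dispersal from India to Asia only") forbids range expansion *into* A,
#' zeroing every entry of column A; `HAI` ("dispersal from Asia to India
#' only") forbids expansion *out of* A, zeroing row A. All other entries are
#' 1; the diagonal is ignored by the rate matrix.
#'
#' @param hypothesis One of `"H0"`, `"HIA"`, `"HAI"`.
#' @param aset An `area_set`; the directional area is its first area.
#' @return A square 0/1 matrix `D` with `D[source, target]` multiplying the
#'   dispersal rate from `source` into `target`.
#' @export
build_dispersal_matrix <- function(hypothesis = c("H0", "HIA", "HAI"),
                                   aset = default_area_set()) {
  hypothesis <- match.arg(hypothesis)
  n <- length(aset$areas)
  D <- matrix(1, n, n, dimnames = list(aset$areas, aset$areas))
  diag(D) <- 0
  a <- aset$areas[1]
  if (hypothesis == "HIA") D[setdiff(aset$areas, a), a] <- 0
  if (hypothesis == "HAI") D[a, setdiff(aset$areas, a)] <- 0
  D
}

#' DEC model parameters
#'
#' @param d Dispersal rate (range-expansion events per Ma per source-target
#'   area pair).
#' @param e Extinction rate (area-loss events per Ma per occupied area).
#' @param D Dispersal multiplier matrix (see [build_dispersal_matrix()]);
#'   default all-ones off-diagonal.
#' @param model Optional model name carried into fit tables.
#' @return A `dec_params` object.
#' @export
dec_params <- function(d, e, D = NULL, model = "H0") {
  if (d < 0 || e < 0) stop("rates must be nonnegative")
  structure(list(d = d, e = e, D = D, model = model), class = "dec_params")
}

#' Anagenetic DEC rate matrix
#'
#' Builds the generator of the range-evolution CTMC over the allowed range
#' states plus the absorbing null (extinct) state. The rate from range `R` to
#' `R + {a}` (when the enlarged range is allowed) is
#' `d * sum_{b in R} D[b, a]`; the rate from `R` to `R - {a}` (to null when
#' `R` is a single area) is `e`. Transitions to disallowed (disconnected)
#' ranges are excluded. Rows sum to zero; the null state is absorbing.
#'
#' @param space A `dec_state_space` (internal) or an `area_set`.
#' @param params A `dec_params`.
#' @param max_range_size Optional cap when `space` is an `area_set`.
#' @return Square rate matrix with range labels (null state `"0"` last).
#' @examples
#' q <- build_q(area_set(c("A", "B"), "full"), dec_params(0.1, 0.05))
#' q["A", "AB"]  # 0.1
#' @export
build_q <- function(space, params, max_range_size = NULL) {
  if (inherits(space, "area_set")) space <- dec_state_space(space, max_range_size)
  stopifnot(inherits(space, "dec_state_space"), inherits(params, "dec_params"))
  n_areas <- length(space$aset$areas)
  D <- params$D
  if (is.null(D)) {
    D <- matrix(1, n_areas, n_areas); diag(D) <- 0
  }
  S <- space$n_states
  Q <- matrix(0, S, S, dimnames = list(c(space$labels, "0"), c(space$labels, "0")))
  for (k in seq_len(space$K)) {
    m <- space$masks[k]
    members <- bits_of(m)
    for (a in seq_len(n_areas)) {
      if (a %in% members) next
      tgt <- space$idx_of[m + mask_of(a)]
      if (tgt == 0L) next  # enlarged range disallowed (disconnected or too big)
      Q[k, tgt] <- params$d * sum(D[members, a])
    }
    for (a in members) {
      rem <- m - mask_of(a)
      tgt <- if (rem == 0L) space$null_idx else space$idx_of[rem]
      if (tgt == 0L) next  # remainder disconnected: loss excluded
      Q[k, tgt] <- Q[k, tgt] + params$e
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# internal: returns function(t) -> transition probability matrix exp(Q t),
# using one eigendecomposition of Q when well conditioned, else Matrix::expm
# per branch length.
ctmc_prob_factory <- function(Q) {
  if (any(!is.finite(Q))) stop("non-finite rate matrix")
  n <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  V <- Vi <- ev <- NULL
  if (!is.null(eg)) {
    V <- eg$vectors
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    # 1-norm condition estimate (eigenvectors may be complex)
    cond <- if (is.null(Vi)) Inf else
      max(colSums(Mod(V))) * max(colSums(Mod(Vi)))
    if (is.finite(cond) && cond < 1e10) {
      ev <- eg$values
      use_eigen <- TRUE
    }
  }
  dn <- dimnames(Q)
  function(t) {
    if (t < 0) stop("t must be nonnegative")
    if (t == 0) {
      P <- diag(n)
    } else if (use_eigen) {
      P <- Re(V %*% (exp(ev * t) * Vi))
    } else {
      P <- as.matrix(Matrix::expm(Q * t))
    }
    P[P < 0] <- 0
    dimnames(P) <- dn
    P
  }
}

#' Branch transition probabilities
#'
#' Matrix exponential `exp(Q t)` of the anagenetic rate matrix over a branch
#' of duration `t` Ma, with tiny negative round-off entries clipped to zero.
#'
#' @param Q Rate matrix from [build_q()].
#' @param t Branch duration (Ma, nonnegative).
#' @return Row-stochastic matrix.
#' @export
branch_probs <- function(Q, t) {
  ctmc_prob_factory(Q)(t)
}
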