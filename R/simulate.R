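#' Simulate a Yule (pure-birth) chronogram
#'
#' Draws an ultrametric binary tree with `n_tips` tips under a constant
#' birth rate, optionally rescaled so the root sits at a target age.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per lineage per Ma (> 0).
#' @param seed Integer seed.
#' @param root_age Optional target root age in Ma (the tree is linearly
#'   rescaled).
#' @return A `phylo` chronogram with tips `t1 ... tN`.
#' @export
simulate_yule <- function(n_tips, birth_rate = 0.1, seed = 1L, root_age = NULL) {
  if (n_tips < 2L) stop("need at least 2 tips")
  if (birth_rate <= 0) stop("birth rate must be positive")
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  if (!is.null(root_age)) tr <- rescale_tree_age(tr, root_age)
  tr
}

#' Rescale a chronogram to a target root age
#' @param tree A `phylo` chronogram.
#' @param target Target root age (Ma, > 0).
#' @return The rescaled tree.
#' @export
rescale_tree_age <- function(tree, target) {
  if (target <= 0) stop("target root age must be positive")
  ra <- root_age(tree)
  if (ra <= 0) stop("tree has zero height")
  tree$edge.length <- tree$edge.length * (target / ra)
  tree
}

# internal: simulate a CTMC path of duration t from state s under generator Q;
# returns the end state, or NA if an absorbing `forbidden` state is entered.
sim_ctmc_branch <- function(s, t, Q, forbidden = integer(0)) {
  remaining <- t
  repeat {
    rate <- -Q[s, s]
    if (rate <= 0) return(s)
    dt <- rexp(1, rate)
    if (dt > remaining) return(s)
    remaining <- remaining - dt
    probs <- Q[s, ]; probs[s] <- 0
    s <- sample.int(length(probs), 1L, prob = probs)
    if (s %in% forbidden) return(NA_integer_)
  }
}

#' Forward-simulate DEC tip ranges on a chronogram
#'
#' Gillespie simulation of the same process [dec_loglik()] evaluates: range
#' gains and losses along branches follow the rate matrix of [build_q()],
#' and at every internal node one cladogenetic scenario is drawn with the
#' weights of [cladogenesis_outcomes()]. A branch on which the lineage
#' loses its last area (entering the null range) is conditioned on survival
#' by redrawing it, keeping the tip count fixed; the redraw count is
#' reported so the (small) conditioning bias is visible.
#'
#' @param tree A `phylo` chronogram.
#' @param params A `dec_params` (with the hypothesis `D` matrix if any).
#' @param root_range Range label of the root (must be allowed).
#' @param aset An `area_set`.
#' @param max_range_size Optional state-space cap.
#' @param seed Integer seed.
#' @param max_redraws Redraw budget per branch before erroring.
#' @return A `sim_record`: list with `tree`, `tips` (a `tip_areas` table),
#'   `node_ranges` (true realized range per node), `params`, `seed`,
#'   `n_redraws`.
#' @export
simulate_dec_tips <- function(tree, params, root_range = "A",
                              aset = default_area_set(), max_range_size = NULL,
                              seed = 1L, max_redraws = 1000L) {
  validate_chronogram(tree)
  space <- dec_state_space(aset, max_range_size)
  k0 <- space$idx_of[range_mask(root_range, aset)]
  if (k0 == 0L) stop("root_range is not an allowed state")
  set.seed(seed)
  Q <- build_q(space, params)
  cl <- space$clado
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  state <- integer(nn)          # realized range at each node
  state[ntip + 1L] <- k0
  n_redraws <- 0L
  pre <- ape::reorder.phylo(tree, "postorder")
  kids <- split(seq_len(nrow(pre$edge)), pre$edge[, 1])
  for (p in rev(unique(pre$edge[, 1]))) {   # parents before children
    rows <- kids[[as.character(p)]]
    ch <- pre$edge[rows, 2]
    sel <- which(cl$parent == state[p])
    pick <- sel[sample.int(length(sel), 1L, prob = cl$weight[sel])]
    inherit <- c(cl$left[pick], cl$right[pick])
    for (side in 1:2) {
      tries <- 0L
      repeat {
        end <- sim_ctmc_branch(inherit[side], pre$edge.length[rows[side]], Q,
                               forbidden = space$null_idx)
        if (!is.na(end)) break
        tries <- tries + 1L
        if (tries > max_redraws) stop("branch redraw budget exhausted (lineage keeps going extinct)")
      }
      n_redraws <- n_redraws + tries
      state[ch[side]] <- end
    }
  }
  tips <- tip_areas(setNames(space$labels[state[seq_len(ntip)]], tree$tip.label), aset)
  structure(list(tree = tree, tips = tips,
                 node_ranges = setNames(space$labels[state], c(tree$tip.label, rep("", tree$Nnode))),
                 params = params, root_range = root_range, seed = seed,
                 n_redraws = n_redraws),
            class = "sim_record")
}

# internal: 4-state (or n-state) Mk generator from a vector of off-diagonal
# rates in row-major order (q12, q13, ..., q21, q23, ...).
mk_q_matrix <- function(rates, n_states = 4L) {
  if (length(rates) != n_states * (n_states - 1L)) stop("need ", n_states * (n_states - 1L), " rates")
  if (any(rates < 0)) stop("rates must be nonnegative")
  Q <- matrix(0, n_states, n_states)
  k <- 1L
  for (i in seq_len(n_states)) for (j in seq_len(n_states)) {
    if (i == j) next
    Q[i, j] <- rates[k]; k <- k + 1L
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Forward-simulate single-area (Mk) tip states
#'
#' CTMC simulation of the multistate character along every branch; each tip
#' ends in exactly one area, the data expected by [mk_loglik()].
#'
#' @param tree A `phylo` chronogram.
#' @param rates Vector of off-diagonal rates in row-major order (12 values
#'   for 4 areas).
#' @param root_state Area label of the root state.
#' @param aset An `area_set`.
#' @param seed Integer seed.
#' @return A `sim_record` with single-area `tips` and true `node_states`.
#' @export
simulate_mk_tips <- function(tree, rates, root_state = "A",
                             aset = default_area_set(), seed = 1L) {
  validate_chronogram(tree)
  n_states <- length(aset$areas)
  Q <- mk_q_matrix(rates, n_states)
  s0 <- match(root_state, aset$areas)
  if (is.na(s0)) stop("unknown root state")
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  state <- integer(nn)
  state[ntip + 1L] <- s0
  po <- ape::reorder.phylo(tree, "postorder")
  for (r in rev(seq_len(nrow(po$edge)))) {  # parents before children
    p <- po$edge[r, 1]; c_ <- po$edge[r, 2]
    state[c_] <- sim_ctmc_branch(state[p], po$edge.length[r], Q)
  }
  tips <- tip_areas(setNames(aset$areas[state[seq_len(ntip)]], tree$tip.label), aset)
  structure(list(tree = tree, tips = tips,
                 node_states = setNames(aset$areas[state], c(tree$tip.label, rep("", tree$Nnode))),
                 rates = rates, root_state = root_state, seed = seed),
            class = "sim_record")
}

#' Conjugate normal-normal model for synthetic likelihood traces
#'
#' A latent mean `mu ~ N(prior_mean, prior_sd^2)` with observations
#' `y_i ~ N(mu, obs_sd^2)`: the posterior of `mu` and the marginal
#' likelihood of `y` are available in closed form, making this the
#' validation harness for [harmonic_mean_lnml()] and [bf_matrix()]. The
#' plain harmonic-mean estimator has finite variance here when
#' `prior_sd^2 < obs_sd^2 / n_obs`, which the defaults satisfy.
#'
#' @param prior_mean,prior_sd Prior mean and SD of the latent mean.
#' @param obs_sd Observation SD (known).
#' @param obs Observation vector (may be empty).
#' @return A `trace_model`.
#' @export
trace_model <- function(prior_mean = 0, prior_sd = 0.4, obs_sd = 1,
                        obs = c(0.3, -0.2, 0.5, 0.1)) {
  if (prior_sd <= 0 || obs_sd <= 0) stop("variances must be positive")
  structure(list(prior_mean = prior_mean, prior_sd = prior_sd,
                 obs_sd = obs_sd, obs = obs),
            class = "trace_model")
}

#' Closed-form log marginal likelihood of a `trace_model`
#' @param model A `trace_model`.
#' @return `ln p(y)` in nats (0 when there are no observations).
#' @export
normal_marginal_lnml <- function(model) {
  stopifnot(inherits(model, "trace_model"))
  m <- model$prior_mean; v <- model$prior_sd^2; s2 <- model$obs_sd^2
  ll <- 0
  for (y in model$obs) {  # sequential predictive decomposition
    ll <- ll + dnorm(y, m, sqrt(v + s2), log = TRUE)
    k <- v / (v + s2)
    m <- m + k * (y - m)
    v <- v * s2 / (v + s2)
  }
  ll
}

#' Simulate a likelihood trace with known marginal likelihood
#'
#' Draws exact posterior samples of the latent mean of a [trace_model()] and
#' converts each to its data log-likelihood, mimicking the post-burn-in lnL
#' column of an MCMC log while the true log marginal likelihood is known
#' analytically.
#'
#' @param n_samples Number of samples.
#' @param model A `trace_model`.
#' @param seed Integer seed.
#' @return List with `trace` (an `mcmc_trace`, burn-in 0), `true_lnml`,
#'   `model`, `seed`.
#' @export
simulate_trace <- function(n_samples, model = trace_model(), seed = 1L) {
  stopifnot(inherits(model, "trace_model"))
  set.seed(seed)
  v0 <- model$prior_sd^2; s2 <- model$obs_sd^2; k <- length(model$obs)
  prec <- 1 / v0 + k / s2
  post_mean <- (model$prior_mean / v0 + sum(model$obs) / s2) / prec
  mu <- rnorm(n_samples, post_mean, sqrt(1 / prec))
  lnl <- vapply(mu, function(m) sum(dnorm(model$obs, m, model$obs_sd, log = TRUE)),
                numeric(1))
  tr <- mcmc_trace(data.frame(state = seq_len(n_samples), lnL = lnl), burn_in = 0L)
  list(trace = tr, true_lnml = normal_marginal_lnml(model), model = model,
       seed = seed)
}

#' Synthetic 57-tip gecarcinucid-like data set
#'
#' A fully synthetic stand-in for the crab phylogeny: a 57-tip Yule
#' chronogram rescaled to a 47.23 Ma root, with tip ranges forward-simulated
#' under the India-to-Asia dispersal hypothesis (`HIA`, root range `A`,
#' d = 5e-3, e = 5e-4) on the adjacency-restricted four-area system. The
#' same record regenerates bit-identically from its seed; a copy is shipped
#' as plain-text fixture files (see [load_synthetic_fixture()]).
#'
#' @param seed Integer seed (default 1, the shipped fixture's seed).
#' @param n_tips,root_age,d,e,hypothesis,root_range Generating conditions.
#' @return A `sim_record` (see [simulate_dec_tips()]).
#' @export
synthetic_gecarcinucidae <- function(seed = 1L, n_tips = 57L, root_age = 47.23,
                                     d = 5e-3, e = 5e-4, hypothesis = "HIA",
                                     root_range = "A") {
  tr <- simulate_yule(n_tips, birth_rate = 0.1, seed = seed, root_age = root_age)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  D <- build_dispersal_matrix(hypothesis)
  simulate_dec_tips(tr, dec_params(d, e, D = D, model = hypothesis),
                    root_range = root_range, seed = seed + 1L)
}

#' Load the shipped synthetic fixture
#'
#' Reads the versioned plain-text copy of [synthetic_gecarcinucidae()]
#' (tree + tip areas) from the package's `extdata`.
#'
#' @return List with `tree`, `tips`, and the generating `seed`.
#' @export
load_synthetic_fixture <- function() {
  nwk <- system.file("extdata", "synthetic_gecarcinucidae.nwk", package = "biogeodec")
  tsv <- system.file("extdata", "synthetic_gecarcinucidae_areas.tsv", package = "biogeodec")
  if (!nzchar(nwk) || !nzchar(tsv)) stop("fixture files not installed")
  list(tree = parse_newick(paste(readLines(nwk), collapse = "")),
       tips = read_tip_areas(tsv), seed = 1L)
}
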