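# internal: tree arrays for the compiled pruning code (0-based, postorder)
mk_tree_data <- function(tree, tips, aset) {
  validate_tip_areas(tree, tips)
  st <- match(unname(tips[tree$tip.label]), aset$areas)
  if (anyNA(st))
    stop("multi-area tip not allowed in the multistate model: ",
         paste(tips[tree$tip.label][is.na(st)], collapse = ", "))
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge - 1L, elen = po$edge.length,
       ntip = ape::Ntip(tree), nnode = tree$Nnode, tipstate = st - 1L)
}

# internal: resolve a node given as integer id or "MRCA(tipA,tipB)"
resolve_node <- function(tree, node) {
  if (is.numeric(node)) {
    node <- as.integer(node)
    ntip <- ape::Ntip(tree)
    if (node <= ntip || node > ntip + tree$Nnode) stop("invalid internal node id: ", node)
    return(node)
  }
  m <- regmatches(node, regexec("^MRCA\\(([^,]+),([^)]+)\\)$", node))[[1]]
  if (length(m) != 3L) stop("node must be an internal node id or 'MRCA(tip1,tip2)'")
  t1 <- trimws(m[2]); t2 <- trimws(m[3])
  if (!all(c(t1, t2) %in% tree$tip.label)) stop("MRCA tips not in tree")
  ape::getMRCA(tree, c(t1, t2))
}

#' Mk (multistate) log-likelihood of single-area tips
#'
#' Felsenstein pruning over the fully asymmetric k-state Markov model with
#' uniform root state frequencies. A node may be "fossilized": the pruning
#' pass conditions on that node being in one given area by zeroing its
#' partial likelihood for every other state.
#'
#' @param tree Ultrametric binary `phylo` chronogram.
#' @param tips Single-area `tip_areas` table (multi-area tips are rejected).
#' @param rates Off-diagonal rates in row-major order (12 values for 4
#'   areas), or a full rate matrix.
#' @param aset An `area_set`.
#' @param fossilize Optional `list(node =, state =)` constraint; `node` is
#'   an internal node id or `"MRCA(tip1,tip2)"`, `state` an area label.
#' @return Log-likelihood in nats (possibly `-Inf`).
#' @export
mk_loglik <- function(tree, tips, rates, aset = default_area_set(),
                      fossilize = NULL) {
  validate_chronogram(tree)
  ns <- length(aset$areas)
  if (is.matrix(rates)) rates <- t(rates)[t(row(rates) != col(rates))]
  td <- mk_tree_data(tree, tips, aset)
  fn <- -1L; fs <- -1L
  if (!is.null(fossilize)) {
    fn <- resolve_node(tree, fossilize$node) - 1L
    fs <- match(fossilize$state, aset$areas) - 1L
    if (is.na(fs)) stop("unknown fossilized state")
  }
  cpp_mk_loglik(td$edge, td$elen, td$ntip, td$nnode, td$tipstate,
                as.numeric(rates), ns, fn, fs)
}

#' MCMC configuration for the multistate sampler
#'
#' Desk-scale defaults (1e5 generations, sampling every 100, 100 samples of
#' burn-in) keep runs in seconds at 4 states; the field-scale settings
#' (5e7 generations etc.) can be requested explicitly. `rate_deviation` is
#' the sliding-window width of the rate proposals; the exponential
#' hyperprior mean moves on a uniform window over (0, `m_max`).
#'
#' @param generations Total MH generations (must be at least
#'   `10 * sample_every`).
#' @param sample_every Record a sample every this many generations.
#' @param burn_in_samples Leading recorded samples flagged as burn-in.
#' @param rate_deviation Rate proposal window width (default 0.1).
#' @param m_window Hyperprior-mean proposal window width (default 4).
#' @param m_max Upper bound of the hyperprior mean (default 80).
#' @param seed Integer seed.
#' @param repeats Independent repeat runs used by [node_support()]
#'   (default 5, because harmonic means are unstable).
#' @return An `mcmc_config`.
#' @export
mcmc_config <- function(generations = 1e5, sample_every = 100,
                        burn_in_samples = 100, rate_deviation = 0.1,
                        m_window = 4, m_max = 80, seed = 1L, repeats = 5L) {
  generations <- as.integer(generations)
  sample_every <- as.integer(sample_every)
  if (generations < sample_every * 10L)
    stop("generations must be at least 10 * sample_every")
  if (burn_in_samples >= generations %/% sample_every)
    stop("burn-in discards every sample")
  structure(list(generations = generations, sample_every = sample_every,
                 burn_in_samples = as.integer(burn_in_samples),
                 rate_deviation = rate_deviation, m_window = m_window,
                 m_max = m_max, seed = as.integer(seed),
                 repeats = as.integer(repeats)),
            class = "mcmc_config")
}

#' Posterior sampling of the multistate ancestral-area model
#'
#' Metropolis-Hastings over the 12 transition rates and the mean `m` of
#' their exponential hyperprior (`m ~ uniform(0, m_max)`,
#' `q_ij ~ exponential(mean m)`). Each generation proposes one randomly
#' chosen parameter: a rate moves by a uniform sliding window of width
#' `rate_deviation` reflected at 0, the hyperprior mean by a window of
#' width `m_window` reflected at 0 and `m_max`. At every recorded sample
#' the internal-node states are drawn jointly from their exact conditional
#' distribution given the current rates.
#'
#' @inheritParams mk_loglik
#' @param config An [mcmc_config()].
#' @param fix_rates Optional rate vector: freezes the rates (no proposals),
#'   turning the run into repeated conditional draws of node states.
#' @return An `mk_mcmc` object: `trace` (an `mcmc_trace` with columns
#'   `state`, `lnL`, the 12 rates, `m`), `node_states` (character matrix,
#'   samples x internal nodes), `acceptance_rate`, `config`.
#' @export
sample_posterior <- function(tree, tips, config = mcmc_config(),
                             aset = default_area_set(), fossilize = NULL,
                             fix_rates = NULL) {
  validate_chronogram(tree)
  ns <- length(aset$areas)
  nr <- ns * (ns - 1L)
  td <- mk_tree_data(tree, tips, aset)
  fn <- -1L; fs <- -1L
  if (!is.null(fossilize)) {
    fn <- resolve_node(tree, fossilize$node) - 1L
    fs <- match(fossilize$state, aset$areas) - 1L
    if (is.na(fs)) stop("unknown fossilized state")
  }
  set.seed(config$seed)
  fixed <- !is.null(fix_rates)
  init_rates <- if (fixed) as.numeric(fix_rates) else rep(1 / root_age(tree), nr)
  if (length(init_rates) != nr) stop("need ", nr, " rates")
  res <- cpp_mk_mcmc(td$edge, td$elen, td$ntip, td$nnode, td$tipstate, ns,
                     config$generations, config$sample_every,
                     config$rate_deviation, config$m_window, config$m_max,
                     init_rates, 1.0, !fixed, !fixed, fn, fs)
  pair_names <- outer(aset$areas, aset$areas, paste0)
  rate_names <- paste0("q", t(pair_names)[t(row(pair_names) != col(pair_names))])
  tr <- as.data.frame(res$trace)
  names(tr) <- c("state", "lnL", rate_names, "m")
  node_states <- matrix(aset$areas[res$node_states + 1L], nrow = nrow(res$node_states),
                        dimnames = list(NULL, as.character(td$ntip + seq_len(td$nnode))))
  structure(list(trace = mcmc_trace(tr, burn_in = config$burn_in_samples),
                 node_states = node_states,
                 acceptance_rate = if (res$proposed > 0) res$accepted / res$proposed else NA_real_,
                 config = config, fossilize = fossilize),
            class = "mk_mcmc")
}

#' @export
print.mk_mcmc <- function(x, ...) {
  cat(sprintf("Mk MCMC: %d samples (%d burn-in), acceptance rate %s\n",
              nrow(x$trace), attr(x$trace, "burn_in"),
              if (is.na(x$acceptance_rate)) "n/a"
              else sprintf("%.1f%%", 100 * x$acceptance_rate)))
  invisible(x)
}

#' Posterior frequencies of node states
#'
#' @param fit An `mk_mcmc` from [sample_posterior()].
#' @param node Internal node id or `"MRCA(tip1,tip2)"`; `NULL` for all.
#' @return Matrix of post-burn-in state frequencies (nodes x areas).
#' @export
node_state_freqs <- function(fit, node = NULL) {
  stopifnot(inherits(fit, "mk_mcmc"))
  b <- attr(fit$trace, "burn_in")
  ns <- fit$node_states[seq.int(b + 1L, nrow(fit$node_states)), , drop = FALSE]
  areas <- sort(unique(as.vector(fit$node_states)))
  f <- t(apply(ns, 2, function(col) {
    tab <- table(factor(col, levels = areas))
    as.numeric(tab) / length(col)
  }))
  colnames(f) <- areas
  if (!is.null(node)) f <- f[as.character(node), , drop = FALSE]
  f
}

#' Bayes-factor support for the ancestral area of a node
#'
#' For every candidate area, the node is fossilized to that area and the
#' sampler is run `config$repeats` times; each run's marginal likelihood is
#' estimated by [harmonic_mean_lnml()] and averaged across repeats. The
#' best-supported area is compared with each alternative by log10 Bayes
#' factor; the verdict is `"supported"` only if the best area beats every
#' alternative by more than 0.48, otherwise `"equivocal"`.
#'
#' @inheritParams sample_posterior
#' @param node Internal node id or `"MRCA(tip1,tip2)"`.
#' @return A `node_support` object: data frame `states` (`state`, `lnML`,
#'   `SE`, `log10BF_vs_best`), `best`, `verdict`, `node`.
#' @export
node_support <- function(tree, tips, node, config = mcmc_config(),
                         aset = default_area_set()) {
  nid <- resolve_node(tree, node)
  reps <- config$repeats
  per_state <- lapply(seq_along(aset$areas), function(si) {
    lnmls <- vapply(seq_len(reps), function(r) {
      cfg <- config
      cfg$seed <- config$seed + 997L * si + r
      run <- sample_posterior(tree, tips, cfg, aset = aset,
                              fossilize = list(node = nid, state = aset$areas[si]))
      harmonic_mean_lnml(run$trace)$lnML
    }, numeric(1))
    c(mean(lnmls), sd(lnmls) / sqrt(reps))
  })
  lnml <- vapply(per_state, `[`, numeric(1), 1)
  se <- vapply(per_state, `[`, numeric(1), 2)
  best <- which.max(lnml)
  bf <- (lnml[best] - lnml) / log(10)
  verdict <- if (all(bf[-best] > 0.48)) "supported" else "equivocal"
  df <- data.frame(state = aset$areas, lnML = lnml, SE = se,
                   log10BF_vs_best = -bf, stringsAsFactors = FALSE)
  structure(list(states = df, best = aset$areas[best], verdict = verdict,
                 node = nid, repeats = reps),
            class = "node_support")
}

#' @export
print.node_support <- function(x, ...) {
  cat(sprintf("Node %d ancestral-area support (%d repeats per state): %s\n",
              x$node, x$repeats,
              if (x$verdict == "supported") paste0("area ", x$best, " supported")
              else "equivocal"))
  print(x$states, row.names = FALSE, digits = 4)
  invisible(x)
}
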