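test_that("Yule simulation is seeded, binary, ultrametric and rescalable", {
  tr <- simulate_yule(57, 0.1, seed = 6, root_age = 47.23)
  expect_equal(ape::Ntip(tr), 57)
  expect_equal(tr$Nnode, 56)  # binary-tree identity
  expect_silent(validate_chronogram(tr))
  expect_equal(root_age(tr), 47.23, tolerance = 1e-9)
  expect_identical(write_newick(simulate_yule(57, 0.1, seed = 6, root_age = 47.23)),
                   write_newick(tr))
  t2 <- simulate_yule(2, 0.5, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_error(simulate_yule(1, 0.1), "at least 2")
  expect_error(simulate_yule(5, 0), "positive")
})

test_that("DEC forward simulation reproduces its degenerate limits", {
  tr <- simulate_yule(12, 0.5, seed = 51, root_age = 5)
  sim0 <- simulate_dec_tips(tr, dec_params(0, 0), root_range = "AB", seed = 1)
  expect_true(all(unname(sim0$tips) %in% c("A", "B", "AB")))  # vicariance only
  simA <- simulate_dec_tips(tr, dec_params(0, 0), root_range = "A", seed = 1)
  expect_true(all(unname(simA$tips) == "A"))
  # e = 0: ranges never shrink along a branch, so every tip contains its
  # cladogenetic fragment; with root {A} under HIA all tips contain A or B
  sim2 <- simulate_dec_tips(tr, dec_params(0.1, 0), root_range = "A", seed = 2)
  expect_true(all(nchar(unname(sim2$tips)) >= 1))
  expect_identical(sim2$n_redraws, 0L)
  # seeded determinism
  s1 <- simulate_dec_tips(tr, dec_params(0.05, 0.01), root_range = "A", seed = 9)
  s2 <- simulate_dec_tips(tr, dec_params(0.05, 0.01), root_range = "A", seed = 9)
  expect_identical(s1$tips, s2$tips)
  expect_error(simulate_dec_tips(tr, dec_params(0.1, 0), root_range = "AC"),
               "not an allowed state")
})

test_that("per-branch DEC transition frequencies match the matrix exponential", {
  # single branch of length t from state {A}: compare empirical end-state
  # frequencies with exp(Qt) within 3 binomial SEs
  aset <- aset2()
  p <- dec_params(0.4, 0.25)
  sp <- biogeodec:::dec_state_space(aset, NULL)
  Q <- build_q(sp, p)
  P <- branch_probs(Q, 0.8)
  set.seed(61)
  n <- 4000
  ends <- vapply(seq_len(n), function(i)
    biogeodec:::sim_ctmc_branch(1L, 0.8, Q), integer(1))
  for (s in seq_len(ncol(P))) {
    phat <- mean(ends == s)
    se <- sqrt(P[1, s] * (1 - P[1, s]) / n)
    expect_lt(abs(phat - P[1, s]), 3 * se + 1e-3)
  }
})

test_that("Mk forward simulation matches its 2-state closed form", {
  tr <- simulate_yule(6, 0.5, seed = 71, root_age = 3)
  sim0 <- simulate_mk_tips(tr, rep(0, 12), root_state = "C", seed = 1)
  expect_true(all(unname(sim0$tips) == "C"))
  expect_identical(simulate_mk_tips(tr, rep(0.1, 12), seed = 5)$tips,
                   simulate_mk_tips(tr, rep(0.1, 12), seed = 5)$tips)
  # symmetric 2-state change probability (1 - exp(-2qt)) / 2 on one branch
  q <- 0.6; t <- 0.9
  Q <- biogeodec:::mk_q_matrix(c(q, q), 2L)
  set.seed(81)
  n <- 4000
  flips <- vapply(seq_len(n), function(i)
    biogeodec:::sim_ctmc_branch(1L, t, Q) != 1L, logical(1))
  pth <- (1 - exp(-2 * q * t)) / 2
  expect_lt(abs(mean(flips) - pth), 3 * sqrt(pth * (1 - pth) / n))
})

test_that("conjugate traces are deterministic with analytic marginals", {
  s1 <- simulate_trace(100, seed = 3)
  s2 <- simulate_trace(100, seed = 3)
  expect_identical(trace_lnl(s1$trace), trace_lnl(s2$trace))
  # no observations: the marginal likelihood is exactly 1 and every sample's
  # lnL is 0
  empty <- simulate_trace(50, trace_model(obs = numeric(0)), seed = 4)
  expect_identical(empty$true_lnml, 0)
  expect_true(all(trace_lnl(empty$trace) == 0))
  # a known lnML gap between two model specs is recovered by the BF machinery
  mA <- trace_model(obs = c(0.3, -0.2, 0.5, 0.1))
  mB <- trace_model(prior_mean = 2, obs = c(0.3, -0.2, 0.5, 0.1))
  gap <- normal_marginal_lnml(mA) - normal_marginal_lnml(mB)
  tA <- simulate_trace(4000, mA, seed = 5)
  tB <- simulate_trace(4000, mB, seed = 6)
  hA <- harmonic_mean_lnml(tA$trace); hB <- harmonic_mean_lnml(tB$trace)
  est <- log10_bf(hA$lnML, hB$lnML)
  se <- sqrt(hA$SE^2 + hB$SE^2) / log(10)
  expect_lt(abs(est - gap / log(10)), 3 * se)
})

test_that("the synthetic crab-like fixture regenerates and matches its shipped copy", {
  rec <- synthetic_gecarcinucidae(seed = 1L)
  expect_equal(ape::Ntip(rec$tree), 57)
  expect_equal(root_age(rec$tree), 47.23, tolerance = 1e-9)
  rec2 <- synthetic_gecarcinucidae(seed = 1L)
  expect_identical(rec$tips, rec2$tips)
  expect_identical(write_newick(rec$tree), write_newick(rec2$tree))
  fx <- load_synthetic_fixture()
  expect_true(ape::all.equal.phylo(fx$tree, rec$tree, tolerance = 1e-9))
  expect_identical(as.character(fx$tips[names(rec$tips)]),
                   as.character(rec$tips))
})
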