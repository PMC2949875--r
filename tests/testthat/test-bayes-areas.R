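test_that("Mk likelihood matches closed forms and the enumeration oracle", {
  # 2-state equal rates on a cherry, both tips in state A
  q <- 0.3
  P11 <- 0.5 + 0.5 * exp(-2 * q)
  P21 <- 0.5 - 0.5 * exp(-2 * q)
  ll <- mk_loglik(cherry(), tip_areas(c(a = "A", b = "A"), aset2()),
                  rates = c(q, q), aset = aset2())
  expect_equal(ll, log(0.5 * P11^2 + 0.5 * P21^2), tolerance = 1e-10)
  # all rates zero: only the root prior remains
  ll0 <- mk_loglik(cherry(), tip_areas(c(a = "A", b = "A")), rates = rep(0, 12))
  expect_equal(ll0, log(1 / 4), tolerance = 1e-12)
  # random asymmetric 4-state rates on 4-tip trees vs brute-force enumeration
  set.seed(19)
  for (i in 1:10) {
    tr <- simulate_yule(4, 1, seed = 300 + i, root_age = 2)
    rates <- runif(12, 0, 0.6)
    sim <- simulate_mk_tips(tr, rates, root_state = "A", seed = 400 + i)
    expect_equal(mk_loglik(tr, sim$tips, rates),
                 brute_mk(tr, sim$tips, rates)$lnL, tolerance = 1e-8)
  }
  expect_error(mk_loglik(cherry(), tip_areas(c(a = "AB", b = "A")), rep(0.1, 12)),
               "multi-area")
})

test_that("fossilizing a node never raises the likelihood and conditions it correctly", {
  tr <- parse_newick("((a:1,b:1):1,c:2);")
  tips <- tip_areas(c(a = "A", b = "A", c = "B"))
  set.seed(29)
  for (i in 1:5) {
    rates <- runif(12, 0, 0.5)
    free <- mk_loglik(tr, tips, rates)
    fossil <- vapply(default_area_set()$areas, function(s)
      mk_loglik(tr, tips, rates, fossilize = list(node = 5L, state = s)),
      numeric(1))
    expect_true(all(fossil <= free + 1e-10))
    # the fossilized likelihoods decompose the free one
    expect_equal(biogeodec:::logsumexp(fossil), free, tolerance = 1e-8)
  }
})

test_that("the sampler is seed-deterministic and reports its acceptance rate", {
  tr <- simulate_yule(5, 0.3, seed = 41, root_age = 40)
  sim <- simulate_mk_tips(tr, rep(0.02, 12), root_state = "A", seed = 42)
  cfg <- mcmc_config(generations = 2000, sample_every = 10, burn_in_samples = 20,
                     seed = 7)
  r1 <- sample_posterior(tr, sim$tips, cfg)
  r2 <- sample_posterior(tr, sim$tips, cfg)
  expect_identical(r1$trace$lnL, r2$trace$lnL)
  expect_identical(r1$node_states, r2$node_states)
  expect_true(is.finite(r1$acceptance_rate))
  expect_gt(r1$acceptance_rate, 0)
  # recorded lnL agrees with an independent likelihood evaluation
  last <- nrow(r1$trace)
  rates <- as.numeric(r1$trace[last, paste0("q", c("AB", "AC", "AD", "BA", "BC",
                                                   "BD", "CA", "CB", "CD", "DA",
                                                   "DB", "DC"))])
  expect_equal(r1$trace$lnL[last], mk_loglik(tr, sim$tips, rates), tolerance = 1e-8)
})

test_that("fixed-rate node-state draws match the exact conditional distribution", {
  tr <- parse_newick("((a:1,b:1):1.5,c:2.5);")
  tips <- tip_areas(c(a = "A", b = "B", c = "C"))
  rates <- c(0.25, 0.1, 0.05, 0.2, 0.15, 0.1, 0.05, 0.3, 0.1, 0.1, 0.2, 0.25)
  exact <- brute_mk(tr, tips, rates)$node_probs
  cfg <- mcmc_config(generations = 40000, sample_every = 10, burn_in_samples = 0,
                     seed = 3)
  run <- sample_posterior(tr, tips, cfg, fix_rates = rates)
  expect_identical(unique(run$trace$lnL), mk_loglik(tr, tips, rates))
  freq <- node_state_freqs(run)
  n <- nrow(run$node_states)
  for (nd in rownames(exact)) for (s in colnames(exact)) {
    p <- exact[nd, s]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(freq[nd, s] - p), 3 * se + 1e-9)
  }
})

test_that("MRCA node addressing resolves and rejects bad input", {
  tr <- parse_newick("((a:1,b:1):1,c:2);")
  expect_identical(biogeodec:::resolve_node(tr, "MRCA(a,b)"), 5L)
  expect_identical(biogeodec:::resolve_node(tr, "MRCA(a,c)"), 4L)
  expect_error(biogeodec:::resolve_node(tr, "MRCA(a,z)"), "not in tree")
  expect_error(biogeodec:::resolve_node(tr, 2), "invalid internal node")
})
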