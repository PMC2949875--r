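test_that("degenerate likelihoods have their closed-form values", {
  tr <- cherry()
  expect_equal(dec_loglik(tr, tip_areas(c(a = "A", b = "A")), dec_params(0, 0)), 0)
  # tips A and B, no events possible: only root {A,B} vicariance survives,
  # one of six equally weighted scenarios
  expect_equal(dec_loglik(tr, tip_areas(c(a = "A", b = "B")), dec_params(0, 0)),
               log(1 / 6))
  # under the default adjacency, A and C cannot be vicariance parts of any
  # allowed root: impossible data are flagged as -Inf
  expect_identical(dec_loglik(tr, tip_areas(c(a = "A", b = "C")), dec_params(0, 0)),
                   -Inf)
  expect_error(dec_loglik(tr, tip_areas(c(a = "A")), dec_params(0, 0)), "missing")
})

test_that("pruning equals brute-force scenario enumeration on random instances", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(2:4, 1)
    tr <- simulate_yule(n, 1, seed = 100 + i, root_age = 1)
    p <- dec_params(runif(1, 0, 0.8), runif(1, 0, 0.4))
    tips <- random_tips(tr, aset3(), widespread = TRUE)
    l1 <- dec_loglik(tr, tips, p, aset3())
    l2 <- brute_dec_loglik(tr, tips, p, aset3())
    if (is.finite(l2)) expect_equal(l1, l2, tolerance = 1e-8)
    else expect_identical(l1, -Inf)
  }
})

test_that("fixed-root likelihoods agree with the oracle and sum to the root total", {
  tr <- parse_newick("((a:0.4,b:0.4):0.6,c:1);")
  tips <- tip_areas(c(a = "A", b = "B", c = "C"), aset3())
  p <- dec_params(0.3, 0.1)
  lls <- vapply(as.character(enumerate_ranges(aset3())), function(rr)
    dec_loglik(tr, tips, p, aset3(), root_range = rr), numeric(1))
  expect_equal(biogeodec:::logsumexp(lls), dec_loglik(tr, tips, p, aset3()),
               tolerance = 1e-10)
  expect_equal(dec_loglik(tr, tips, p, aset3(), root_range = "AB"),
               brute_dec_loglik(tr, tips, p, aset3(), root_range = "AB"),
               tolerance = 1e-8)
})

test_that("likelihood is invariant to tip relabeling and area reordering", {
  tr <- simulate_yule(4, 1, seed = 9, root_age = 2)
  p <- dec_params(0.2, 0.05)
  tips <- tip_areas(c(t1 = "A", t2 = "AB", t3 = "B", t4 = "C"), aset3())
  l1 <- dec_loglik(tr, tips, p, aset3())
  # permute tip labels on the tree and the table coherently
  perm <- c(t1 = "x", t2 = "y", t3 = "z", t4 = "w")
  tr2 <- tr; tr2$tip.label <- unname(perm[tr$tip.label])
  tips2 <- tip_areas(setNames(unname(tips), unname(perm[names(tips)])), aset3())
  expect_equal(dec_loglik(tr2, tips2, p, aset3()), l1, tolerance = 1e-12)
  # reorder the area alphabet (C,A,B) and relabel ranges accordingly
  aset_r <- area_set(c("C", "A", "B"), adjacency = "full")
  relab <- c(A = "A", B = "B", C = "C", AB = "AB")  # labels canonicalize per set order
  tips3 <- tip_areas(setNames(unname(tips), names(tips)), aset_r)
  expect_equal(dec_loglik(tr, tips3, p, aset_r), l1, tolerance = 1e-12)
})

test_that("ML fit recovers boundary and informative cases", {
  # d = 0 data: every tip equals the root range; d-hat collapses to the bound
  tr <- simulate_yule(10, 0.5, seed = 21, root_age = 5)
  tips0 <- tip_areas(setNames(rep("A", 10), tr$tip.label))
  f0 <- fit_dec(tr, tips0, "H0")
  expect_lt(f0$d, 1e-6)
  expect_lt(f0$e, 1e-4)
  expect_gte(f0$lnL, dec_loglik(tr, tips0, dec_params(1e-3, 1e-4)))
  # informative simulation: d recovered within a factor of 2
  D <- build_dispersal_matrix("HIA")
  tr2 <- simulate_yule(60, 0.1, seed = 31, root_age = 47.23)
  sim <- simulate_dec_tips(tr2, dec_params(5e-2, 5e-3, D = D, model = "HIA"),
                           root_range = "A", seed = 32)
  f <- fit_dec(tr2, sim$tips, "HIA")
  expect_gt(f$d / 5e-2, 0.5)
  expect_lt(f$d / 5e-2, 2)
  expect_identical(f$k, 2L)
})

test_that("split reconstruction is exact, normalized and consistent with the fit", {
  tr <- simulate_yule(8, 0.5, seed = 3, root_age = 10)
  sim <- simulate_dec_tips(tr, dec_params(0.05, 0.01), root_range = "A", seed = 7)
  fit <- fit_dec(tr, sim$tips, "H0")
  sp <- reconstruct_splits(fit, lnl_window = Inf)
  expect_equal(sp$lnL, fit$lnL, tolerance = 1e-6)
  for (df in sp$nodes) {
    expect_equal(sum(df$rel_prob), 1, tolerance = 1e-9)
    expect_equal(attr(df, "node_total"), exp(sp$lnL), tolerance = 1e-8 * exp(sp$lnL))
    expect_true(all(diff(df$lnL) <= 1e-12))  # best first
  }
  # default window keeps only scenarios within 2 lnL units of the best
  sp2 <- reconstruct_splits(fit)
  for (df in sp2$nodes) expect_true(all(df$lnL >= df$lnL[1] - 2))
})

test_that("a two-tip same-area cherry reconstructs a sympatric root", {
  f <- fit_dec(cherry(), tip_areas(c(a = "A", b = "A")), "H0")
  sp <- reconstruct_splits(f)
  best <- sp$nodes[["3"]]
  expect_identical(best$range[1], "A")
  expect_identical(best$left[1], "A")
  expect_gt(best$rel_prob[1], 0.9)
})

test_that("single-scenario nodes carry relative probability one", {
  # d = e = 0 with identical tips: only the sympatric chain survives
  tr <- parse_newick("((a:1,b:1):1,c:2);")
  tips <- tip_areas(c(a = "A", b = "A", c = "A"))
  fit <- structure(list(d = 1e-12, e = 1e-12, lnL = 0, k = 2L, model = "H0",
                        D = build_dispersal_matrix("H0"),
                        aset = default_area_set(), max_range_size = NULL,
                        tree = tr, tips = tips),
                   class = "dec_fit")
  sp <- reconstruct_splits(fit)
  for (df in sp$nodes) expect_equal(df$rel_prob[1], 1, tolerance = 1e-6)
})
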