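test_that("range enumeration respects adjacency connectivity", {
  expect_length(enumerate_ranges(area_set(adjacency = "full")), 15)
  r <- enumerate_ranges(default_area_set())
  expect_length(r, 12)
  expect_false(any(c("AC", "AD", "ACD") %in% r))
  expect_length(enumerate_ranges(area_set("A")), 1)
  # exhaustive connectivity cross-check over all 15 subsets
  aset <- default_area_set()
  conn <- vapply(1:15, biogeodec:::mask_connected, logical(1), adj = aset$adjacency)
  expect_identical(sort(attr(r, "mask")), sort(which(conn)))
  # max_size caps, deterministic order by size then bitmask
  r2 <- enumerate_ranges(aset, max_size = 2)
  expect_identical(as.character(r2), c("A", "B", "C", "D", "AB", "BC", "BD", "CD"))
})

test_that("dispersal multiplier matrices encode the directional hypotheses", {
  D0 <- build_dispersal_matrix("H0")
  expect_equal(sum(D0), 12)
  DIA <- build_dispersal_matrix("HIA")
  expect_equal(unname(DIA[c("B", "C", "D"), "A"]), c(0, 0, 0))
  expect_equal(DIA["A", "B"], 1)
  DAI <- build_dispersal_matrix("HAI")
  expect_equal(unname(DAI["A", c("B", "C", "D")]), c(0, 0, 0))
  expect_equal(DAI["B", "A"], 1)
  expect_error(build_dispersal_matrix("H2"))
})

test_that("rate matrix has the DEC gain/loss structure and zero row sums", {
  q <- build_q(aset2(), dec_params(0.1, 0.05))
  expect_equal(q["A", "AB"], 0.1)
  expect_equal(q["AB", "A"], 0.05)
  expect_equal(q["A", "0"], 0.05)
  expect_equal(unname(q["0", ]), rep(0, 4))  # null absorbing
  # d = 0: no gains anywhere
  q0 <- build_q(default_area_set(), dec_params(0, 0.05))
  sp <- biogeodec:::dec_state_space(default_area_set())
  sizes <- biogeodec:::bit_count(sp$masks)
  gain <- outer(sizes, sizes, `<`)
  expect_true(all(q0[seq_len(12), seq_len(12)][gain] == 0))
  # property: rows sum to 0 for random parameters
  set.seed(7)
  for (i in 1:20) {
    qq <- build_q(default_area_set(), dec_params(runif(1, 0, 2), runif(1, 0, 2)))
    expect_lt(max(abs(rowSums(qq))), 1e-12)
  }
  expect_error(dec_params(-0.1, 0), "nonnegative")
})

test_that("hypothesis multipliers shape the gain rates into and out of A", {
  spd <- dec_params(0.2, 0, D = build_dispersal_matrix("HIA"))
  q <- build_q(default_area_set(), spd)
  expect_equal(q["B", "AB"], 0)      # expansion into India forbidden
  expect_equal(q["A", "AB"], 0.2)    # expansion out of India open
  spd2 <- dec_params(0.2, 0, D = build_dispersal_matrix("HAI"))
  q2 <- build_q(default_area_set(), spd2)
  expect_equal(q2["A", "AB"], 0)
  expect_equal(q2["B", "AB"], 0.2)
})

test_that("branch probabilities form a stochastic semigroup", {
  q <- build_q(default_area_set(), dec_params(0.3, 0.1))
  expect_equal(branch_probs(q, 0), diag(13), ignore_attr = TRUE)
  P <- branch_probs(q, 1.7)
  expect_true(all(P >= 0))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  # Chapman-Kolmogorov
  expect_lt(max(abs(branch_probs(q, 0.9) %*% branch_probs(q, 0.8) - P)), 1e-8)
  # 2-state closed form: single area decaying to null at rate e
  a1 <- area_set("A")
  q1 <- build_q(a1, dec_params(0, 0.07))
  expect_equal(branch_probs(q1, 3)["A", "A"], exp(-0.07 * 3), tolerance = 1e-12)
  expect_error(branch_probs(matrix(c(NaN, 0, 0, 0), 2), 1), "non-finite")
})

test_that("cladogenesis outcomes follow the DEC scenario set with equal weights", {
  o1 <- cladogenesis_outcomes("A")
  expect_identical(o1, data.frame(left = "A", right = "A", weight = 1))
  o2 <- cladogenesis_outcomes("AB", aset2())
  expect_equal(nrow(o2), 6)
  expect_equal(unique(o2$weight), 1 / 6)
  got <- paste(o2$left, o2$right, sep = "|")
  expect_setequal(got, c("A|AB", "AB|A", "B|AB", "AB|B", "A|B", "B|A"))
  o3 <- cladogenesis_outcomes("ABC", aset3())
  expect_equal(nrow(o3), 12)
  expect_equal(sum(o3$weight), 1)
  # adjacency restriction removes outcomes with disallowed parts
  o4 <- cladogenesis_outcomes("ABCD", default_area_set())
  expect_equal(nrow(o4), 14)  # 8 peripheral + 6 vicariance ({ACD} is disallowed)
  expect_false(any(c(o4$left, o4$right) == "ACD"))
  expect_error(cladogenesis_outcomes("0"), "null")
})
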