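# Exact search, enumeration oracle, and the top-level hybrid-number API.

test_that("the search handles the smallest heads", {
  expect_equal(min_hybrids_strictly_simple(1, 2)$h, 0L)
  r2 <- min_hybrids_strictly_simple(2, 4)
  expect_equal(r2$h, 1L)  # the bead
  r4 <- min_hybrids_strictly_simple(4, 6)
  expect_equal(r4$h, 2L)  # the 2-bead chain
  r5 <- min_hybrids_strictly_simple(5, 8)
  expect_equal(r5$h, 3L)
  expect_true(realizes(r5$network, ploidy_profile(5)))
  expect_error(min_hybrids_strictly_simple(5, 2), "lower bound")
})

test_that("the search certificate always verifies", {
  for (m in c(3, 6, 7, 9, 11, 12, 13, 15, 21, 23)) {
    r <- min_hybrids_strictly_simple(m, 10)
    expect_true(is_binary(r$network))
    expect_true(realizes(r$network, ploidy_profile(m)))
    expect_equal(network_hybrid_number(r$network), r$h)
    expect_counts_agree_with_unfold(r$network)
  }
})

test_that("search minimum for powers of two is exactly the exponent", {
  for (k in 1:8) {
    expect_equal(min_hybrids_strictly_simple(2^k, 12)$h, k)
  }
})

test_that("enumeration oracle agrees with the search up to two hybrids", {
  nets <- enumerate_small_networks(2)
  hs <- vapply(nets, network_hybrid_number, numeric(1))
  pcs <- vapply(nets, function(n) unname(path_count_vector(n)[1]), numeric(1))
  expect_equal(max(pcs[hs == 1]), 2)
  expect_equal(max(pcs[hs == 2]), 4)
  for (m in sort(unique(pcs))) {
    expect_equal(min_hybrids_strictly_simple(m, 6)$h, min(hs[pcs == m]))
  }
  expect_error(enumerate_small_networks(4), "h_max")
})

test_that("attain_simple certifies small heads and hangs free pendants", {
  a <- attain_simple(ploidy_profile(c(2, 1, 1, 1)))
  expect_true(a$certified)
  expect_equal(a$h, 1L)
  expect_true(realizes(a$network, ploidy_profile(c(2, 1, 1, 1))))
  expect_equal(network_hybrid_number(a$network), 1)

  a51 <- attain_simple(ploidy_profile(c(5, 1)))
  expect_true(a51$certified)
  expect_equal(a51$h, 3L)

  tree <- attain_simple(ploidy_profile(c(1, 1, 1)))
  expect_equal(tree$h, 0L)
  expect_equal(network_hybrid_number(tree$network), 0)

  expect_error(attain_simple(ploidy_profile(c(3, 2))), "simple")

  # beyond the search limit the result is an uncertified B/D upper bound
  big <- attain_simple(ploidy_profile(600), search_config(max_head = 512))
  expect_false(big$certified)
  expect_true(realizes(big$network, ploidy_profile(600)))
})

test_that("hybrid_number matches the worked examples", {
  r <- hybrid_number(c(12, 6, 6, 5))
  expect_equal(r$status, "exact")
  expect_equal(r$value, 5L)
  expect_true(realizes(r$certificate, ploidy_profile(c(12, 6, 6, 5))))
  expect_equal(network_hybrid_number(r$certificate), 5)

  v <- hybrid_number(c(9, 7, 7, 4, 4, 4, 2, 2, 2, 2, 2, 1))
  expect_equal(v$status, "exact")
  expect_equal(v$value, 5L)

  # all components powers of two: exact even though line 8 fires for (8,2)
  r82 <- hybrid_number(c(8, 2))
  expect_equal(r82$status, "exact")
  expect_equal(r82$value, 3L)
  expect_equal(network_hybrid_number(r82$certificate), 3)
  r842 <- hybrid_number(c(8, 4, 2))
  expect_equal(r842$value, 3L)

  # line 8 fires and components are not all powers of two: bounds
  r92 <- hybrid_number(c(9, 2))
  expect_equal(r92$status, "bounds")
  expect_true(r92$lower <= r92$upper)
  expect_equal(r92$lower, 4L)  # certified h((9))
  expect_true(realizes(r92$certificate, ploidy_profile(c(9, 2))))
  expect_equal(network_hybrid_number(r92$certificate), r92$upper)
})

test_that("proposition2_upper sums per-component star bounds", {
  expect_equal(proposition2_upper(ploidy_profile(15)), 6L)
  expect_equal(proposition2_upper(ploidy_profile(c(1, 1, 1))), 0L)
  expect_equal(proposition2_upper(ploidy_profile(c(12, 6, 6, 5))), 13L)
})

test_that("bounds bracket the exact value and certificates verify", {
  for (seed in 1:40) {
    p <- seeded_profile(seed, max_entry = 40)
    r <- hybrid_number(p)
    expect_true(r$lower <= r$upper)
    expect_true(realizes(r$certificate, p))
    expect_equal(network_hybrid_number(r$certificate), r$upper)
    if (r$status == "exact") {
      expect_equal(r$lower, r$value)
      expect_equal(r$upper, r$value)
    }
    expect_true(r$lower >= ceil_log2(p$multiplicities[1]))
    expect_true(r$upper <= sum(p$multiplicities - 1) || sum(p$multiplicities - 1) == 0)
  }
})

test_that("power-of-two profiles agree between the shortcut and the pipeline", {
  set.seed(5)
  for (rep in 1:10) {
    es <- sort(sample(0:6, sample(2:4, 1), replace = TRUE), decreasing = TRUE)
    p <- ploidy_profile(2^es)
    r <- hybrid_number(p)
    expect_equal(r$status, "exact")
    expect_equal(r$value, max(es))
    # the general pipeline must agree when its hypothesis holds
    s <- simplification_sequence(p)
    if (!line8_fired(s)) {
      a <- attain_simple(terminal_profile(s))
      expect_true(a$certified)
      expect_equal(a$h + c_of(s), r$value)
    }
  }
})

test_that("pruning predicates are sound on hand-checked states", {
  # the (47) narrative: nothing with <= 7 hybrids, a realization with 8
  r <- min_hybrids_strictly_simple(47, 8)
  expect_equal(r$h, 8L)
  expect_true(realizes(r$network, ploidy_profile(47)))
  # infeasible budget reported as NULL, not an error
  expect_null(min_hybrids_strictly_simple(47, 7))
})
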