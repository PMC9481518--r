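# Explicit realizations of simple profiles.

test_that("beaded trees double the path count per bead", {
  b0 <- beaded_tree(0)
  expect_length(validate_network(b0), 0)
  expect_equal(network_hybrid_number(b0), 0)
  expect_counts(b0, c(x1 = 1))

  b1 <- beaded_tree(1)
  expect_counts(b1, c(x1 = 2))
  expect_equal(network_hybrid_number(b1), 1)

  b3 <- beaded_tree(3)
  expect_counts(b3, c(x1 = 8))
  expect_equal(network_hybrid_number(b3), 3)
  expect_true(is_binary(b3))
})

test_that("build_B realizes simple profiles with the Theorem-1 counts", {
  cases <- list(list(m = 9, h = 4), list(m = 15, h = 6), list(m = 47, h = 9),
                list(m = 265, h = 10))
  for (cs in cases) {
    B <- build_B(ploidy_profile(cs$m))
    expect_true(is_binary(B))
    expect_true(realizes(B, ploidy_profile(cs$m)))
    expect_equal(network_hybrid_number(B), cs$h)
  }

  B51 <- build_B(ploidy_profile(c(5, 1)))
  expect_counts(B51, c(x1 = 5, x2 = 1))
  expect_equal(network_hybrid_number(B51), 3)
  expect_equal(length(B51$vertices), 9)

  expect_error(build_B(ploidy_profile(c(5, 2))), "simple")
})

test_that("theorem1_vertex_count matches the built networks", {
  expect_equal(theorem1_vertex_count(ploidy_profile(2)), 3L)
  expect_equal(theorem1_vertex_count(ploidy_profile(c(5, 1))), 9L)
  set.seed(7)
  for (m1 in c(2, 3, sample(2:512, 25))) {
    for (n in c(1, 3)) {
      p <- ploidy_profile(c(m1, rep(1, n - 1)))
      B <- build_B(p)
      expect_equal(length(B$vertices), theorem1_vertex_count(p))
      rep <- binary_representation(m1)
      expect_equal(network_hybrid_number(B),
                   rep$exponents[1] + length(rep$exponents) - 1L)
      if (n == 1) {
        # single-leaf binary realizations always have 2h+1 vertices
        expect_equal(length(B$vertices), 2 * network_hybrid_number(B) + 1)
      }
    }
  }
})

test_that("build_B and build_D realize random simple profiles", {
  set.seed(11)
  heads <- sample(2:512, 30)
  for (m1 in heads) {
    p <- ploidy_profile(c(m1, rep(1, m1 %% 3)))
    B <- build_B(p)
    expect_true(realizes(B, p))
    D <- build_D(p)
    expect_true(realizes(D, p))
    expect_true(is_binary(D))
  }
})

test_that("build_D stacks prime attainments with additive hybrid counts", {
  D9 <- build_D(ploidy_profile(9))
  expect_equal(network_hybrid_number(D9), 4)  # two stacked copies of A(3)
  D15 <- build_D(ploidy_profile(15))
  expect_equal(network_hybrid_number(D15), 5)

  # supplied attainments are honoured, and bogus ones rejected
  a3 <- min_hybrids_strictly_simple(3, 4)$network
  D9b <- build_D(ploidy_profile(9), prime_attainments = list("3" = a3))
  expect_equal(network_hybrid_number(D9b), 2 * network_hybrid_number(a3))
  expect_error(
    build_D(ploidy_profile(9), prime_attainments = list("3" = beaded_tree(1))),
    "does not realize")
  expect_error(build_D(ploidy_profile(c(3, 2))), "simple")
})

test_that("naive_realization works on any profile with h = sum(m_i - 1)", {
  cherry <- naive_realization(ploidy_profile(c(1, 1)))
  expect_equal(network_hybrid_number(cherry), 0)

  n3 <- naive_realization(ploidy_profile(3))
  expect_equal(network_hybrid_number(n3), 2)
  expect_counts(n3, c(x1 = 3))

  big <- naive_realization(ploidy_profile(c(12, 6, 6, 5)))
  expect_equal(network_hybrid_number(big), 25)
  expect_true(realizes(big, ploidy_profile(c(12, 6, 6, 5))))

  for (seed in 1:20) {
    p <- seeded_profile(seed, max_entry = 12)
    N <- naive_realization(p)
    expect_length(validate_network(N), 0)
    expect_true(realizes(N, p))
    expect_equal(network_hybrid_number(N), sum(p$multiplicities - 1))
    expect_counts_agree_with_unfold(N)
  }
})
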