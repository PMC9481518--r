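# The simplification sequence.

test_that("the printed sequence for (12,6,6,5) is reproduced exactly", {
  s <- simplification_sequence(c(12, 6, 6, 5))
  mats <- lapply(s$profiles, function(p) p$multiplicities)
  expect_equal(mats, list(c(12L, 6L, 6L, 5L), c(6L, 6L, 6L, 5L),
                          c(6L, 6L, 5L), c(6L, 5L), c(5L, 1L)))
  expect_equal(s_of(s), 4L)
  expect_equal(c_of(s), 2L)
  expect_false(line8_fired(s))
  expect_equal(s$steps$kind, c("subtract", "merge", "merge", "subtract"))
  expect_equal(s$steps$line, c(10L, 6L, 6L, 10L))
})

test_that("simple profiles are already terminal", {
  for (p in list(ploidy_profile(7), ploidy_profile(c(4, 1, 1)))) {
    s <- simplification_sequence(p)
    expect_equal(s_of(s), 0L)
    expect_equal(c_of(s), 0L)
    expect_identical(terminal_profile(s)$multiplicities, p$multiplicities)
  }
})

test_that("the Viola profile simplifies to (2,1,1,1) in twelve steps", {
  s <- simplification_sequence(c(9, 7, 7, 4, 4, 4, 2, 2, 2, 2, 2, 1))
  expect_equal(s_of(s), 12L)
  expect_equal(c_of(s), 4L)
  expect_equal(terminal_profile(s)$multiplicities, c(2L, 1L, 1L, 1L))
  expect_false(line8_fired(s))
})

test_that("line 8 fires exactly when some step has alpha > m2", {
  expect_true(line8_fired(simplification_sequence(c(8, 2))))
  expect_false(line8_fired(simplification_sequence(c(12, 6, 6, 5))))
  # equivalent characterization: some non-terminal profile has m1 > 2 m2
  for (seed in 1:40) {
    p <- seeded_profile(seed)
    s <- simplification_sequence(p)
    chr <- any(vapply(head(s$profiles, -1), function(q) {
      length(q) >= 2 && q$multiplicities[1] > 2 * q$multiplicities[2]
    }, logical(1)))
    expect_equal(line8_fired(s), chr)
  }
})

test_that("closed forms: all-equal and arithmetic profiles", {
  # (k,...,k) with q copies plus optional trailing ones: s = q - 1
  for (k in 2:4) {
    for (q in 2:5) {
      s <- simplification_sequence(c(rep(k, q), rep(1, q %% 2)))
      expect_equal(s_of(s), q - 1L)
      expect_equal(c_of(s), 0L)
    }
  }
  # m_i = k(l-i): s = l + q - 3 (k >= 2; k = 1 terminates early)
  for (k in 2:3) {
    for (q in 2:4) {
      for (l in (q + 2):(q + 4)) {
        p <- c(k * (l - seq_len(q)), rep(1, l %% 2))
        s <- simplification_sequence(p)
        expect_equal(s_of(s), l + q - 3L)
      }
    }
  }
})

test_that("the (k^l, k) family has s = k^(l-1)", {
  for (k in 2:4) {
    for (l in 2:4) {
      s <- simplification_sequence(c(k^l, k))
      expect_equal(s_of(s), k^(l - 1))
      expect_length(s$profiles, k^(l - 1) + 1)
    }
  }
})

test_that("each step strictly decreases the profile and replays forward", {
  for (seed in 1:40) {
    p <- seeded_profile(seed, max_entry = 64)
    s <- simplification_sequence(p)
    # strict lexicographic decrease guarantees termination
    key <- vapply(s$profiles, function(q) {
      paste(formatC(c(q$multiplicities, rep(0, 10 - length(q))), width = 4, flag = "0"),
            collapse = "")
    }, character(1))
    expect_equal(key, sort(key, decreasing = TRUE))
    expect_equal(anyDuplicated(key), 0L)
    # replay the recorded steps forward, one profile at a time
    for (i in seq_len(nrow(s$steps))) {
      m <- s$profiles[[i]]$multiplicities
      lab <- s$profiles[[i]]$labels
      if (s$steps$kind[i] == "merge") {
        expect_equal(m[1], m[2])
        expect_equal(s$steps$receiver_label[i], lab[1])
        expect_equal(s$steps$donor_label[i], lab[2])
        expect_equal(s$profiles[[i + 1]]$multiplicities, m[-1])
        expect_equal(s$profiles[[i + 1]]$labels, lab[-1])
      } else {
        alpha <- m[1] - m[2]
        expect_equal(alpha, s$steps$alpha[i])
        expect_equal(s$steps$line[i], if (alpha > m[2]) 8L else 10L)
        expect_equal(s$steps$receiver_label[i], lab[1])
        m[1] <- alpha
        expect_equal(s$profiles[[i + 1]]$multiplicities,
                     sort(m, decreasing = TRUE))
      }
    }
    expect_true(is_simple(terminal_profile(s)))
  }
})
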