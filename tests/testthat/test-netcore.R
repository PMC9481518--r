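# Network model: validation, path counting, hybrid number, surgeries.

test_that("validate_network accepts the bead and flags degree violations", {
  expect_length(validate_network(bead_network()), 0)

  # a degree-(1,1) vertex
  bad <- phylo_network(data.frame(tail = c("r", "r", "a"),
                                  head = c("a", "b", "c")),
                       c(b = "x1", c = "x2"))
  v <- validate_network(bad)
  expect_true(any(grepl("vertex a", v)))

  # two indegree-0 vertices
  bad2 <- phylo_network(data.frame(tail = c("r", "r", "s", "s"),
                                   head = c("a", "b", "a", "b")),
                        c(a = "x1", b = "x2"))
  expect_true(any(grepl("multiple roots", validate_network(bad2))))

  # loops are rejected
  bad3 <- phylo_network(data.frame(tail = c("r", "r", "a"),
                                   head = c("a", "a", "a")),
                        c(a = "x1"))
  expect_true(any(grepl("loop", validate_network(bad3))))
})

test_that("is_binary distinguishes indegree-2 from higher hybrids", {
  expect_true(is_binary(bead_network()))
  # hybrid of indegree three fed by two tree vertices
  triple <- phylo_network(
    data.frame(tail = c("r", "r", "t1", "t1", "t2", "t2", "h"),
               head = c("t1", "t2", "h", "h", "h", "b", "c")),
    c(b = "x2", c = "x1"))
  expect_length(validate_network(triple), 0)
  expect_false(is_binary(triple))
  expect_equal(network_hybrid_number(triple), 2)  # indeg 3 counts twice
})

test_that("path counts: bead chains double, trees stay at one", {
  b3 <- beaded_tree(3)
  expect_counts(b3, c(x1 = 8))
  expect_counts_agree_with_unfold(b3)

  tree <- naive_realization(ploidy_profile(c(1, 1, 1, 1)))
  expect_equal(network_hybrid_number(tree), 0)
  expect_counts(tree, c(x1 = 1, x2 = 1, x3 = 1, x4 = 1))
})

test_that("realizes checks the exact label-to-count mapping", {
  expect_true(realizes(bead_network(), ploidy_profile(2)))
  expect_false(realizes(bead_network(), ploidy_profile(3)))
  expect_true(realizes(build_B(ploidy_profile(9)), ploidy_profile(9)))
  expect_error(realizes(bead_network(), ploidy_profile(2, "y1")),
               "labels")
})

test_that("subdivision and pendant leaves preserve existing counts", {
  b <- bead_network()
  # subdividing the leaf arc keeps the count at 2
  s <- subdivide_arc(b, which(b$arcs$head == names(b$labels)))
  expect_counts(s, c(x1 = 2))
  # subdividing one parallel arc destroys the bead but keeps counts
  s2 <- subdivide_arc(b, 1)
  expect_counts(s2, c(x1 = 2))
  expect_counts_agree_with_unfold(s2)

  # chained subdivisions insert in order below one another
  s3 <- subdivide_arc(s2, nrow(s2$arcs))
  expect_length(validate_network(s3), 2)  # two degree-(1,1) vertices now
  expect_equal(nrow(s3$arcs), nrow(b$arcs) + 2)

  # pendant on a root arc has count 1; below a 3-bead chain, count 8
  b3 <- beaded_tree(3)
  root_arc <- which(b3$arcs$tail == "v1")[1]
  p1 <- add_pendant_leaf(b3, root_arc, "x2")
  expect_counts(p1, c(x1 = 8, x2 = 1))
  leaf_arc3 <- which(b3$arcs$head == names(b3$labels))
  p2 <- add_pendant_leaf(b3, leaf_arc3, "x2")
  expect_counts(p2, c(x1 = 8, x2 = 8))
  expect_equal(length(p2$vertices), length(b3$vertices) + 2)
  expect_error(add_pendant_leaf(b3, leaf_arc3, "x1"), "duplicate")
})

test_that("expand_cherry duplicates a leaf's count and adds two vertices", {
  b <- bead_network()
  e <- expand_cherry(b, "x1", "x2")
  expect_counts(e, c(x1 = 2, x2 = 2))
  expect_equal(length(e$vertices), length(b$vertices) + 2)
  expect_true(is_binary(e))
  expect_error(expand_cherry(e, "x1", "x2"), "duplicate")

  tree <- naive_realization(ploidy_profile(c(1, 1)))
  e2 <- expand_cherry(tree, "x2", "x3")
  expect_equal(network_hybrid_number(e2), 0)
})

test_that("hybridize adds the donor count to the receiver and one hybrid", {
  # B((5,1)) labelled so x2 carries 5 and x1 carries 1, as in the
  # traceback of (6,5) -> (5,1); hybridizing x2 into x1 realizes (6,5)
  B <- build_B(ploidy_profile(c(5, 1), labels = c("x2", "x1")))
  h <- hybridize(B, donor_label = "x2", receiver_label = "x1")
  expect_counts(h, c(x1 = 6, x2 = 5))
  expect_equal(network_hybrid_number(h), network_hybrid_number(B) + 1)
  expect_equal(length(h$vertices), length(B$vertices) + 2)
  expect_true(is_binary(h))
  expect_error(hybridize(B, "x1", "x1"), "distinct")

  cherry <- naive_realization(ploidy_profile(c(1, 1)))
  hc <- hybridize(cherry, donor_label = "x2", receiver_label = "x1")
  expect_counts(hc, c(x1 = 2, x2 = 1))
  expect_counts_agree_with_unfold(hc)
})

test_that("path counts never exceed 2^h on binary networks", {
  for (seed in 1:25) {
    p <- seeded_profile(seed)
    N <- build_N_auto(p)
    h <- network_hybrid_number(N)
    expect_true(all(path_count_vector(N) <= 2^h))
  }
  # and the bead chain attains the ceiling
  expect_equal(unname(path_count_vector(beaded_tree(5))), 2^5)
})
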