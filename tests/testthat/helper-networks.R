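# Shared fixtures built in code.

# the single-bead network: root, two parallel arcs to a hybrid, one leaf
bead_network <- function(label = "x1") beaded_tree(1, label)

# recount a network's path counts and compare against an expectation
expect_counts <- function(net, expected) {
  pc <- path_count_vector(net)
  expect_mapequal(as.list(pc), as.list(expected))
}

# dual-route check: dynamic programming vs explicit path enumeration
expect_counts_agree_with_unfold <- function(net) {
  pc <- path_count_vector(net)
  uf <- table(unfold_leaf_multiset(net))
  expect_setequal(names(pc), names(uf))
  expect_equal(unname(pc[names(uf)]), unname(as.numeric(uf)))
}

# deterministic small profile drawn from a seed (n derived from the seed
# so tests do not consume the ambient RNG)
seeded_profile <- function(seed, max_entry = 32) {
  random_profile(seed, n = 2 + (seed %% 6), max_entry = max_entry)
}
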