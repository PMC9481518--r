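# Explicit realizations of simple profiles: beaded trees, the binary-
# representation construction B, the prime-factorization construction D,
# and the naive realization of arbitrary profiles.

# deterministic renumbering: vertices renamed v1, v2, ... in a depth-first
# preorder from the root with children taken in stored arc order, so
# repeated runs serialize identically.
pn_renumber <- function(net) {
  if (length(net$vertices) == 1 && nrow(net$arcs) == 0) {
    map <- setNames("v1", net$vertices)
  } else {
    root <- pn_root(net)
    seen <- character(0)
    stack <- root
    arcs <- net$arcs
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v %in% seen) next
      seen <- c(seen, v)
      kids <- arcs$head[arcs$tail == v]
      stack <- c(kids[!(kids %in% seen)], stack)
    }
    map <- setNames(paste0("v", seq_along(seen)), seen)
  }
  arcs <- net$arcs
  arcs$tail <- unname(map[arcs$tail])
  arcs$head <- unname(map[arcs$head])
  labels <- setNames(unname(net$labels), unname(map[names(net$labels)]))
  phylo_network(arcs, labels, vertices = unname(map[net$vertices]),
                next_id = length(map) + 1L)
}

# caterpillar phylogenetic tree on the given labels (h = 0)
caterpillar_tree <- function(labels) {
  n <- length(labels)
  if (n == 1) {
    return(phylo_network(NULL, setNames(labels, "v1"), vertices = "v1",
                         next_id = 2L))
  }
  arcs <- data.frame(tail = character(0), head = character(0))
  lab <- character(0)
  vid <- function(k) paste0("v", k)
  k <- 1L
  spine <- vid(1)
  for (i in seq_len(n - 1)) {
    leaf <- vid(k + 1L)
    lab[leaf] <- labels[i]
    if (i < n - 1) {
      nxt <- vid(k + 2L)
      arcs <- rbind(arcs, data.frame(tail = c(spine, spine), head = c(leaf, nxt)))
      spine <- nxt
      k <- k + 2L
    } else {
      last <- vid(k + 2L)
      lab[last] <- labels[n]
      arcs <- rbind(arcs, data.frame(tail = c(spine, spine), head = c(leaf, last)))
      k <- k + 2L
    }
  }
  phylo_network(arcs, lab, next_id = k + 1L)
}

#' Beaded tree with q beads over a single leaf
#'
#' A chain of `q` beads (pairs of parallel arcs) from the root down to one
#' leaf.  Each bead doubles the path count, so the network realizes the
#' strictly simple profile `(2^q)` with exactly `q` hybrid vertices -- the
#' path-count ceiling `2^h` is attained.  For `q = 0` the degenerate
#' single-vertex network (root = leaf) is returned; it lies outside the
#' root-outdegree-two convention and is documented as the only
#' permitted degeneracy.
#'
#' @param q number of beads, `q >= 0`.
#' @param leaf_label taxon label of the unique leaf.
#' @return a `phylo_network`; the hybrid vertex ids in root-to-leaf order
#'   are attached as `attr(, "bead_hybrids")`.
#' @export
beaded_tree <- function(q, leaf_label = "x1") {
  q <- check_count(q, "q", min = 0)
  if (q == 0) {
    net <- phylo_network(NULL, setNames(leaf_label, "v1"), vertices = "v1",
                         next_id = 2L)
    attr(net, "bead_hybrids") <- character(0)
    return(net)
  }
  tails <- heads <- character(0)
  hybs <- character(0)
  k <- 1L
  top <- "v1"
  for (j in seq_len(q)) {
    h <- paste0("v", k + 1L)
    hybs <- c(hybs, h)
    tails <- c(tails, top, top)     # the bead: two parallel arcs
    heads <- c(heads, h, h)
    if (j < q) {
      u <- paste0("v", k + 2L)      # tree vertex between beads
      tails <- c(tails, h); heads <- c(heads, u)
      top <- u
      k <- k + 2L
    } else {
      leaf <- paste0("v", k + 2L)
      tails <- c(tails, h); heads <- c(heads, leaf)
      k <- k + 2L
    }
  }
  leaf <- paste0("v", k)
  net <- phylo_network(data.frame(tail = tails, head = heads),
                       setNames(leaf_label, leaf), next_id = k + 1L)
  attr(net, "bead_hybrids") <- hybs
  net
}

#' The binary-representation realization B of a simple profile
#'
#' For a simple profile with head `m1` and binary representation
#' exponents \eqn{(i_1,\ldots,i_q)}, starts from the beaded tree with
#' \eqn{i_1} beads, subdivides one root arc with a chain
#' \eqn{s_2,\ldots,s_q} and adds, for each lower-order bit \eqn{i_j}, an
#' arc from \eqn{s_j} into a subdivision of the outgoing arc of the bead
#' hybrid that has exactly \eqn{i_j} hybrid vertices strictly below it
#' (for \eqn{i_j = 0}: the leaf's incoming arc).  Unit components hang as
#' pendant leaves \eqn{t_2,\ldots,t_n} off the other root arc.  The
#' result is binary, realizes the profile, and has
#' \eqn{i_1 + q - 1} hybrid vertices and [theorem1_vertex_count()]
#' vertices.
#'
#' The chain arc itself plays the role of the leading bit, so extra arcs
#' exist only for \eqn{j = 2,\ldots,q}; the s-chain sits on the first
#' stored root arc and the pendant chain on the second, nearest the root
#' first.
#'
#' @param profile a simple [ploidy_profile()].
#' @return a `phylo_network` realizing `profile`.
#' @export
build_B <- function(profile) {
  profile <- as_profile(profile)
  if (!is_simple(profile)) stop("build_B() needs a simple profile")
  m1 <- profile$multiplicities[1]
  labels <- profile$labels
  n <- length(profile)
  if (m1 == 1) return(caterpillar_tree(labels))
  rep <- binary_representation(m1)
  exps <- rep$exponents
  q <- length(exps)
  i1 <- exps[1]
  net <- beaded_tree(i1, labels[1])
  hybs <- attr(net, "bead_hybrids")   # root-to-leaf order
  # s-chain down the first root arc (row 1), nearest the root first
  if (q >= 2) {
    s_ids <- character(q - 1)
    cur <- 1L
    for (j in 2:q) {
      net <- subdivide_arc(net, cur)
      s_ids[j - 1] <- attr(net, "new_vertex")
      cur <- nrow(net$arcs)           # the freshly appended lower half
    }
    # jump arcs: s_j -> subdivision of the out-arc of the hybrid with
    # exactly i_j bead hybrids strictly below it
    for (j in 2:q) {
      target <- hybs[i1 - exps[j]]
      out_arc <- which(net$arcs$tail == target)
      net <- subdivide_arc(net, out_arc)
      w <- attr(net, "new_vertex")
      net$arcs <- rbind(net$arcs, data.frame(tail = s_ids[j - 1], head = w))
      rownames(net$arcs) <- NULL
    }
  }
  # pendant unit leaves down the second root arc (row 2)
  if (n >= 2) {
    cur <- 2L
    for (i in 2:n) {
      net <- add_pendant_leaf(net, cur, labels[i])
      cur <- nrow(net$arcs) - 1L      # arc from t_i to the old head
    }
  }
  attr(net, "bead_hybrids") <- NULL
  attr(net, "new_vertex") <- NULL
  pn_renumber(net)
}

#' Closed-form vertex count of B
#'
#' `2 * (i1 + q - 1 + n - 1) + 1` where `(i1, ..., iq)` is the binary
#' representation of the profile head and `n` the number of taxa; equals
#' `length(build_B(profile)$vertices)`.
#'
#' @param profile a simple [ploidy_profile()].
#' @return positive integer.
#' @export
theorem1_vertex_count <- function(profile) {
  profile <- as_profile(profile)
  if (!is_simple(profile)) stop("theorem1_vertex_count() needs a simple profile")
  rep <- binary_representation(profile$multiplicities[1])
  i1 <- rep$exponents[1]
  q <- length(rep$exponents)
  n <- length(profile)
  as.integer(2L * (i1 + q - 1L + n - 1L) + 1L)
}

#' The prime-factorization realization D of a simple profile
#'
#' Writes the profile head as \eqn{p_1^{a_1} \cdots p_k^{a_k}} with
#' primes descending and stacks, for each prime factor in order, a
#' single-leaf attainment of `(p_i)` (identifying the leaf of one block
#' with the root of the next); path counts multiply down the stack, so the
#' result realizes the head with \eqn{\sum_i a_i\, h(A(p_i))} hybrid
#' vertices.  Unit components hang off one root arc as pendant leaves.
#'
#' @param profile a simple [ploidy_profile()] with head `>= 2`.
#' @param prime_attainments optional named list, `"p"` -> single-leaf
#'   binary network realizing `(p)`.  Primes without a supplied network
#'   are attained by the exact search ([min_hybrids_strictly_simple()]);
#'   a supplied network that does not realize `(p)` is an error.
#' @param search_limit exact-search configuration used for missing
#'   primes, see [attain_simple()].
#' @return a `phylo_network` realizing `profile`.
#' @export
build_D <- function(profile, prime_attainments = list(), search_limit = search_config()) {
  profile <- as_profile(profile)
  if (!is_simple(profile)) stop("build_D() needs a simple profile")
  m1 <- profile$multiplicities[1]
  if (m1 < 2) stop("build_D() needs a profile head >= 2")
  labels <- profile$labels
  fac <- prime_factorization_desc(m1)
  blocks <- list()
  for (i in seq_len(nrow(fac))) {
    p <- fac$prime[i]
    key <- as.character(p)
    if (!is.null(prime_attainments[[key]])) {
      A <- prime_attainments[[key]]
      pc <- path_count_vector(A)
      if (length(pc) != 1 || pc[[1]] != p) {
        stop("supplied attainment for prime ", p, " does not realize (", p, ")")
      }
    } else {
      A <- attain_strictly_simple_head(p, search_limit)$network
    }
    for (r in seq_len(fac$exponent[i])) blocks <- c(blocks, list(A))
  }
  # stack: identify the leaf of each block with the root of the next
  arcs <- NULL
  prev_leaf <- NULL
  for (i in seq_along(blocks)) {
    a <- blocks[[i]]$arcs
    pre <- paste0("s", i, "_")
    a$tail <- paste0(pre, a$tail)
    a$head <- paste0(pre, a$head)
    root_i <- paste0(pre, pn_root(blocks[[i]]))
    leaf_i <- paste0(pre, names(blocks[[i]]$labels)[1])
    if (!is.null(prev_leaf)) {
      a$tail[a$tail == root_i] <- prev_leaf
    }
    arcs <- rbind(arcs, a)
    prev_leaf <- if (is.null(prev_leaf) || leaf_i != root_i) leaf_i else prev_leaf
  }
  net <- phylo_network(arcs, setNames(labels[1], prev_leaf))
  net <- pn_renumber(net)
  n <- length(profile)
  if (n >= 2) {
    root <- pn_root(net)
    cur <- which(net$arcs$tail == root)[1]
    for (i in 2:n) {
      net <- add_pendant_leaf(net, cur, labels[i])
      cur <- nrow(net$arcs) - 1L
    }
    attr(net, "new_vertex") <- NULL
    net <- pn_renumber(net)
  }
  net
}

#' Naive realization of an arbitrary profile
#'
#' Hangs the taxa off a caterpillar spine and replaces the pendant arc of
#' each taxon with multiplicity `m >= 2` by a parallel-path gadget: a
#' chain of `m - 2` tree vertices below an entry vertex, every chain
#' vertex (and the entry) sending one extra arc into a single hybrid hub
#' of indegree `m`.  The gadget contributes `m` root-to-leaf paths and
#' `m - 1` to the hybrid number, so the whole network realizes the
#' profile with hybrid number `sum(m_i - 1)`.  Not binary in general
#' (the hub has indegree `m`).
#'
#' @param profile a [ploidy_profile()].
#' @return a `phylo_network` realizing `profile`.
#' @export
naive_realization <- function(profile) {
  profile <- as_profile(profile)
  n <- length(profile)
  mult <- profile$multiplicities
  labels <- profile$labels
  if (n == 1 && mult[1] == 1) return(caterpillar_tree(labels))
  if (n == 1) {
    # the root itself is the gadget entry (outdegree two)
    net <- gadget_arcs("v1", mult[1], labels[1], next_k = 2L)
    return(pn_renumber(phylo_network(net$arcs, net$labels)))
  }
  net <- caterpillar_tree(labels)
  for (i in seq_len(n)) {
    if (mult[i] < 2) next
    v <- names(net$labels)[net$labels == labels[i]]
    arc <- which(net$arcs$head == v)
    net <- subdivide_arc(net, arc)     # entry vertex of the gadget
    e <- attr(net, "new_vertex")
    # drop the old leaf and its incoming arc; the gadget re-creates it
    net$labels <- net$labels[names(net$labels) != v]
    net$arcs <- net$arcs[!(net$arcs$tail == e & net$arcs$head == v), , drop = FALSE]
    net$vertices <- setdiff(net$vertices, v)
    g <- gadget_arcs(e, mult[i], labels[i], next_k = net$next_id)
    net$arcs <- rbind(net$arcs, g$arcs)
    rownames(net$arcs) <- NULL
    net$vertices <- c(net$vertices, setdiff(unique(c(g$arcs$tail, g$arcs$head)), net$vertices))
    net$labels <- c(net$labels, g$labels)
    net$labels <- net$labels[order(names(net$labels))]
    net$next_id <- g$next_k
  }
  attr(net, "new_vertex") <- NULL
  pn_renumber(net)
}

# parallel-path gadget: m directed paths from entry to a hybrid hub of
# indegree m, then one arc to the leaf; m >= 2
gadget_arcs <- function(entry, m, label, next_k) {
  vid <- function(k) paste0("v", k)
  hub <- vid(next_k); next_k <- next_k + 1L
  tails <- heads <- character(0)
  prev <- entry
  if (m > 2) {
    for (j in seq_len(m - 2)) {
      w <- vid(next_k); next_k <- next_k + 1L
      tails <- c(tails, prev, prev)    # chain arc + curved arc into hub
      heads <- c(heads, w, hub)
      prev <- w
    }
  }
  tails <- c(tails, prev, prev)        # last vertex: both arcs reach hub
  heads <- c(heads, hub, hub)
  leaf <- vid(next_k); next_k <- next_k + 1L
  tails <- c(tails, hub); heads <- c(heads, leaf)
  list(arcs = data.frame(tail = tails, head = heads),
       labels = setNames(label, leaf), next_k = next_k)
}
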