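# Exact attainment search for simple profiles, plus the brute-force
# enumeration oracle used to validate it.

#' Search configuration
#'
#' The exact search is exponential, so it is gated: heads above
#' `max_head` or searches that would need more than `max_budget` hybrid
#' vertices fall back to the better of the B/D constructions (certified
#' only as an upper bound).  Ploidy numbers in real datasets are small,
#' so the defaults cover practical inputs.
#'
#' @param max_head largest profile head attacked by exhaustive search.
#' @param max_budget hard cap on the iterative-deepening depth.
#' @return a list used by [attain_simple()], [build_N_auto()] and
#'   [hybrid_number()].
#' @export
search_config <- function(max_head = 512, max_budget = 12) {
  list(max_head = check_count(max_head, "max_head", min = 1),
       max_budget = check_count(max_budget, "max_budget", min = 1))
}

#' Minimum hybrid number of a strictly simple profile, by exhaustive search
#'
#' Iterative-deepening search over multisets of open-arc path counts
#' (see the package vignette): starting from `{1, 1}` (the root's two
#' outgoing arcs), a tree vertex duplicates an open count for free and a
#' hybrid vertex merges two open counts at cost one, until the single
#' count `m` remains.  Every single-leaf binary network induces such a
#' move sequence via a topological order and every move sequence rebuilds
#' a valid network, so the minima coincide; the first solution found is
#' replayed into an explicit certificate network and verified.
#'
#' @param m positive integer (the profile head).
#' @param budget maximum number of hybrid vertices to try; must be at
#'   least `ceil_log2(m)`, the path-count lower bound.
#' @param leaf_label taxon label given to the unique leaf.
#' @return `NULL` if no realization exists within `budget`, else a list
#'   with `h` (the minimum hybrid number within budget), `network` (a
#'   single-leaf binary network realizing `(m)` with `h` hybrid
#'   vertices) and `moves` (the move matrix, for provenance).
#' @export
min_hybrids_strictly_simple <- function(m, budget = 12, leaf_label = "x1") {
  m <- check_count(m, "m", min = 1)
  budget <- check_count(budget, "budget", min = 0)
  lb <- ceil_log2(m)
  if (budget < lb) {
    stop("budget ", budget, " is below the path-count lower bound ", lb)
  }
  if (m == 1) {
    return(list(h = 0L, network = beaded_tree(0, leaf_label), moves = NULL))
  }
  res <- cpp_min_hybrids(m, lb, budget)
  if (is.null(res$h)) return(NULL)
  net <- replay_moves(m, res$moves, leaf_label)
  stopifnot(sum(res$moves[, 1] == 1L) == res$h)
  stopifnot(network_hybrid_number(net) == res$h,
            realizes(net, ploidy_profile(m, leaf_label)))
  list(h = as.integer(res$h), network = net, moves = res$moves)
}

# rebuild a single-leaf binary network from a move sequence
replay_moves <- function(m, moves, leaf_label) {
  tails <- c("v1", "v1")
  counts <- c(1, 1)
  arcs_t <- character(0)
  arcs_h <- character(0)
  k <- 2L
  nr <- if (is.null(moves)) 0L else nrow(moves)
  for (i in seq_len(nr)) {
    w <- paste0("v", k); k <- k + 1L
    if (moves[i, 1] == 0L) {          # duplicate: tree vertex
      j <- which(counts == moves[i, 2])[1]
      arcs_t <- c(arcs_t, tails[j]); arcs_h <- c(arcs_h, w)
      tails <- c(tails[-j], w, w)
      counts <- c(counts[-j], moves[i, 2], moves[i, 2])
    } else {                          # merge: hybrid vertex
      a <- moves[i, 2]; b <- moves[i, 3]
      ja <- which(counts == a)[1]
      jb <- setdiff(which(counts == b), ja)[1]
      arcs_t <- c(arcs_t, tails[ja], tails[jb])
      arcs_h <- c(arcs_h, w, w)
      keep <- setdiff(seq_along(counts), c(ja, jb))
      tails <- c(tails[keep], w)
      counts <- c(counts[keep], a + b)
    }
  }
  stopifnot(length(counts) == 1, counts[1] == m)
  leaf <- paste0("v", k)
  arcs_t <- c(arcs_t, tails[1]); arcs_h <- c(arcs_h, leaf)
  phylo_network(data.frame(tail = arcs_t, head = arcs_h),
                setNames(leaf_label, leaf), next_id = k + 1L)
}

#' Enumerate all single-leaf binary networks with few hybrid vertices
#'
#' Brute-force oracle, independent of the state-space search: for each
#' hybrid count `h <= h_max` the vertex types are forced (one root of
#' outdegree two, `h` hybrids of indegree two, `h - 1` tree vertices, one
#' leaf -- `2h + 1` vertices in all), and every assignment of tails to
#' in-slots respecting out-capacities is generated, filtered for loops
#' and acyclicity, and deduplicated up to isomorphism (permutations
#' within the hybrid and tree classes).
#'
#' @param h_max maximum hybrid count, `h_max <= 3` (the oracle is meant
#'   for validating the search on tiny instances only).
#' @return a list of `phylo_network` objects; the degenerate one-vertex
#'   network represents `h = 0`.
#' @export
enumerate_small_networks <- function(h_max) {
  h_max <- check_count(h_max, "h_max", min = 0)
  if (h_max > 3) stop("enumerate_small_networks() is limited to h_max <= 3")
  out <- list(beaded_tree(0, "x1"))
  for (h in seq_len(h_max)) {
    out <- c(out, enumerate_h(h))
  }
  out
}

enumerate_h <- function(h) {
  # vertices and out-capacities
  hybs <- paste0("H", seq_len(h))
  trees <- if (h >= 2) paste0("T", seq_len(h - 1)) else character(0)
  tails_avail <- c(r = 2L,
                   setNames(rep(1L, h), hybs),
                   setNames(rep(2L, length(trees)), trees))
  # in-slots: each hybrid has an unordered pair, each tree vertex and the
  # leaf one slot
  slot_owner <- c(rep(hybs, each = 2), trees, "x")
  results <- list()
  assign_slot <- function(idx, cap, arcs_t) {
    if (idx > length(slot_owner)) {
      results[[length(results) + 1L]] <<- arcs_t
      return(invisible(NULL))
    }
    owner <- slot_owner[idx]
    # unordered hybrid pair: second slot's tail must be >= the first's
    floor_i <- 1L
    if (idx > 1 && slot_owner[idx - 1] == owner) {
      floor_i <- match(arcs_t[idx - 1], names(cap))
    }
    for (ti in seq_along(cap)) {
      if (ti < floor_i) next
      tl <- names(cap)[ti]
      if (cap[ti] == 0L || tl == owner) next
      cap2 <- cap
      cap2[ti] <- cap2[ti] - 1L
      assign_slot(idx + 1L, cap2, c(arcs_t, tl))
    }
    invisible(NULL)
  }
  assign_slot(1L, tails_avail, character(0))
  nets <- list()
  seen <- character(0)
  for (arcs_t in results) {
    arcs <- data.frame(tail = arcs_t, head = slot_owner)
    net <- phylo_network(arcs, c(x = "x1"),
                         vertices = c("r", hybs, trees, "x"))
    if (length(validate_network(net))) next
    key <- canonical_key(arcs, hybs, trees)
    if (key %in% seen) next
    seen <- c(seen, key)
    nets[[length(nets) + 1L]] <- net
  }
  nets
}

# lexicographically minimal arc list over type-preserving relabellings
canonical_key <- function(arcs, hybs, trees) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL
  for (ph in perms(hybs)) {
    for (pt in perms(trees)) {
      map <- c(setNames(ph, hybs), setNames(pt, trees), r = "r", x = "x")
      a <- paste(map[arcs$tail], map[arcs$head], sep = ">")
      key <- paste(sort(a), collapse = ";")
      if (is.null(best) || key < best) best <- key
    }
  }
  best
}

# cached certified attainment of the strictly simple profile (m):
# iterative deepening up to h(B((m))) - 1; if nothing smaller exists,
# B((m)) itself is optimal, so the result is exact either way.
attain_strictly_simple_head <- function(m, config = search_config()) {
  key <- paste0(m, ":", config$max_head, ":", config$max_budget)
  hit <- .hybnum_cache[[key]]
  if (!is.null(hit)) return(hit)
  hB <- as.integer((theorem1_vertex_count(ploidy_profile(m)) - 1L) / 2L)
  lb <- ceil_log2(m)
  res <- NULL
  certified <- FALSE
  note <- NULL
  if (m <= config$max_head && lb <= config$max_budget) {
    budget <- min(hB - 1L, config$max_budget)
    found <- if (budget >= lb) min_hybrids_strictly_simple(m, budget) else NULL
    if (!is.null(found)) {
      res <- list(h = found$h, network = found$network)
      note <- "exhaustive search"
    } else if (budget == hB - 1L) {
      # search exhausted every depth below h(B): B is optimal
      res <- list(h = hB, network = build_B(ploidy_profile(m)))
      note <- "exhaustive search; optimum met by the binary-representation construction"
    }
    certified <- !is.null(res)
  }
  if (is.null(res)) {
    # uncertified fallback: better of B and D
    B <- build_B(ploidy_profile(m))
    cand <- list(B)
    if (m >= 2 && m <= 1e6) {
      D <- tryCatch(build_D(ploidy_profile(m), search_limit = config),
                    error = function(e) NULL)
      if (!is.null(D)) cand <- c(cand, list(D))
    }
    hs <- vapply(cand, network_hybrid_number, numeric(1))
    best <- which.min(hs)
    res <- list(h = as.integer(hs[best]), network = cand[[best]])
    note <- "upper bound from the better of the B/D constructions"
  }
  out <- list(h = res$h, network = res$network, certified = certified,
              note = note)
  .hybnum_cache[[key]] <- out
  out
}

#' Attainment of a simple profile
#'
#' Finds a minimum-hybrid realization of the strictly simple head `(m1)`
#' (exhaustive search when `m1` is within `search_limit`, else the better
#' of the B and D constructions, uncertified) and then hangs one pendant
#' unit leaf per remaining component off a root arc; pendants sit on
#' arcs of path count one, so they do not disturb any count and add no
#' hybrid vertices.
#'
#' @param profile a simple [ploidy_profile()].
#' @param search_limit a [search_config()].
#' @return list with `network`, `h`, and `certified` (TRUE when the core
#'   came from exhaustive search, so `h` is exactly the hybrid number of
#'   the profile).
#' @export
attain_simple <- function(profile, search_limit = search_config()) {
  profile <- as_profile(profile)
  if (!is_simple(profile)) stop("attain_simple() needs a simple profile")
  m1 <- profile$multiplicities[1]
  labels <- profile$labels
  n <- length(profile)
  if (m1 == 1) {
    # a phylogenetic tree attains the all-ones profile
    return(list(network = caterpillar_tree(labels), h = 0L, certified = TRUE,
                note = "all-ones profile: any phylogenetic tree attains it"))
  }
  core <- attain_strictly_simple_head(m1, search_limit)
  net <- core$network
  net$labels[] <- labels[1]
  if (n >= 2) {
    root <- pn_root(net)
    cur <- which(net$arcs$tail == root)[1]
    for (i in 2:n) {
      net <- add_pendant_leaf(net, cur, labels[i])
      cur <- nrow(net$arcs) - 1L
    }
    attr(net, "new_vertex") <- NULL
  }
  net <- pn_renumber(net)
  list(network = net, h = core$h, certified = core$certified, note = core$note)
}
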