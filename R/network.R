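# Rooted-DAG multigraph model of phylogenetic networks with beads.
#
# A network is a list:
#   vertices: character vector of opaque vertex identifiers
#   arcs:     data.frame(tail, head) -- a multiset, parallel arcs are
#             repeated rows, row index = arc occurrence handle
#   labels:   named character, leaf vertex id -> taxon label
#   next_id:  counter for deterministic fresh vertex identifiers v<k>
#
# Vertex roles are derived from degrees: the root has indegree 0, a leaf
# indegree 1 / outdegree 0, a tree vertex indegree 1 / outdegree 2, a
# hybrid vertex indegree >= 2 / outdegree 1.  The one permitted
# degeneracy is the single-vertex network (root = leaf) realizing the
# profile (1).

#' Construct a phylogenetic network
#'
#' Low-level constructor.  Most users will obtain networks from
#' [build_B()], [build_D()], [naive_realization()], [build_N_auto()] or
#' [read_network()] instead.
#'
#' @param arcs data.frame with character columns `tail` and `head`; one
#'   row per arc occurrence (parallel arcs are repeated rows).
#' @param labels named character vector mapping leaf vertex ids to taxon
#'   labels.
#' @param vertices optional explicit vertex set (needed only for the
#'   degenerate single-vertex network, which has no arcs).
#' @param next_id counter used for fresh vertex names `v<k>`.
#' @return an object of class `phylo_network`.
#' @seealso [validate_network()]
#' @export
phylo_network <- function(arcs, labels, vertices = NULL, next_id = NULL) {
  if (is.null(arcs)) arcs <- data.frame(tail = character(0), head = character(0))
  arcs <- data.frame(tail = as.character(arcs$tail),
                     head = as.character(arcs$head),
                     stringsAsFactors = FALSE)
  if (is.null(vertices)) vertices <- unique(c(arcs$tail, arcs$head))
  vertices <- as.character(vertices)
  labels <- labels[order(names(labels))]  # deterministic storage order
  if (is.null(next_id)) {
    ks <- suppressWarnings(as.integer(sub("^v", "", grep("^v[0-9]+$", vertices, value = TRUE))))
    next_id <- if (length(ks)) max(ks, na.rm = TRUE) + 1L else 1L
  }
  structure(list(vertices = vertices, arcs = arcs,
                 labels = labels, next_id = as.integer(next_id)),
            class = "phylo_network")
}

fresh_vertex <- function(net, k = 1L) {
  ids <- paste0("v", seq.int(net$next_id, length.out = k))
  net$next_id <- net$next_id + as.integer(k)
  list(net = net, ids = ids)
}

pn_indeg <- function(net) {
  d <- setNames(integer(length(net$vertices)), net$vertices)
  t <- table(net$arcs$head)
  d[names(t)] <- as.integer(t)
  d
}

pn_outdeg <- function(net) {
  d <- setNames(integer(length(net$vertices)), net$vertices)
  t <- table(net$arcs$tail)
  d[names(t)] <- as.integer(t)
  d
}

pn_root <- function(net) {
  r <- net$vertices[pn_indeg(net) == 0L]
  if (length(r) != 1) stop("network does not have a unique root")
  r
}

pn_leaves <- function(net) net$vertices[pn_outdeg(net) == 0L]

pn_hybrids <- function(net) {
  ind <- pn_indeg(net)
  net$vertices[ind >= 2L]
}

# Kahn topological order; NULL if cyclic
pn_topo_order <- function(net) {
  ind <- pn_indeg(net)
  order <- character(0)
  avail <- names(ind)[ind == 0L]
  ind2 <- ind
  arcs <- net$arcs
  while (length(avail)) {
    v <- avail[[1]]
    avail <- avail[-1]
    order <- c(order, v)
    heads <- arcs$head[arcs$tail == v]
    for (h in unique(heads)) {
      ind2[h] <- ind2[h] - sum(heads == h)
      if (ind2[h] == 0L) avail <- c(avail, h)
    }
  }
  if (length(order) != length(net$vertices)) NULL else order
}

#' @export
print.phylo_network <- function(x, ...) {
  nh <- tryCatch(length(pn_hybrids(x)), error = function(e) NA)
  cat("phylo_network: ", length(x$vertices), " vertices, ",
      nrow(x$arcs), " arcs, ", nh, " hybrid vertices, leaves {",
      paste(unname(x$labels), collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Validate a phylogenetic network
#'
#' Checks the defining invariants and returns diagnostics rather than
#' throwing: a unique root of outdegree two (or the degenerate
#' single-vertex network), every other vertex a tree vertex, a hybrid
#' vertex or a labelled leaf, no loops, acyclicity, connectedness, and a
#' label for every leaf.
#'
#' @param network a [phylo_network()].
#' @return a character vector of violation descriptions; empty when the
#'   network is valid.
#' @export
validate_network <- function(network) {
  out <- character(0)
  net <- network
  if (!inherits(net, "phylo_network")) return("not a phylo_network object")
  if (length(net$vertices) == 0) return("empty vertex set")
  # degenerate single-vertex network: allowed, must carry a label
  if (length(net$vertices) == 1 && nrow(net$arcs) == 0) {
    if (!identical(names(net$labels), net$vertices)) {
      out <- c(out, "single-vertex network must have its vertex labelled as a leaf")
    }
    return(out)
  }
  loops <- net$arcs$tail == net$arcs$head
  if (any(loops)) {
    out <- c(out, paste0("loop arc at vertex ", net$arcs$tail[loops]))
  }
  dang <- setdiff(c(net$arcs$tail, net$arcs$head), net$vertices)
  if (length(dang)) out <- c(out, paste0("arc references unknown vertex ", dang))
  ind <- pn_indeg(net)
  outd <- pn_outdeg(net)
  roots <- net$vertices[ind == 0L]
  if (length(roots) == 0) out <- c(out, "no root (every vertex has an incoming arc)")
  if (length(roots) > 1) {
    out <- c(out, paste0("multiple roots: ", paste(roots, collapse = ", ")))
  }
  for (r in roots) {
    if (outd[r] != 2L) {
      out <- c(out, paste0("root ", r, " has outdegree ", outd[r], ", expected 2"))
    }
  }
  for (v in setdiff(net$vertices, roots)) {
    iv <- ind[v]; ov <- outd[v]
    ok <- (iv == 1L && ov == 0L) ||            # leaf
          (iv == 1L && ov == 2L) ||            # tree vertex
          (iv >= 2L && ov == 1L)               # hybrid vertex
    if (!ok) {
      out <- c(out, paste0("vertex ", v, " has degree (in=", iv, ", out=", ov,
                           "), not a leaf, tree vertex or hybrid vertex"))
    }
  }
  if (is.null(pn_topo_order(net))) out <- c(out, "arc relation is cyclic")
  leaves <- net$vertices[ind == 1L & outd == 0L]
  unlabelled <- setdiff(leaves, names(net$labels))
  if (length(unlabelled)) out <- c(out, paste0("leaf ", unlabelled, " has no taxon label"))
  extra <- setdiff(names(net$labels), leaves)
  if (length(extra)) out <- c(out, paste0("labelled vertex ", extra, " is not a leaf"))
  if (anyDuplicated(net$labels)) out <- c(out, "duplicate taxon labels")
  # weak connectivity: in a DAG whose non-root vertices all have indegree
  # >= 1, every vertex is reachable from a root, so a unique root plus
  # acyclicity implies connectedness; re-check explicitly all the same.
  if (length(roots) == 1 && is.null(pn_topo_order(net)) == FALSE) {
    reach <- roots
    repeat {
      nxt <- unique(net$arcs$head[net$arcs$tail %in% reach])
      nxt <- setdiff(nxt, reach)
      if (!length(nxt)) break
      reach <- c(reach, nxt)
    }
    unreach <- setdiff(net$vertices, reach)
    if (length(unreach)) {
      out <- c(out, paste0("vertex ", unreach, " unreachable from the root"))
    }
  }
  out
}

stop_if_invalid <- function(net) {
  v <- validate_network(net)
  if (length(v)) stop("invalid network: ", paste(v, collapse = "; "))
  invisible(net)
}

# relaxed structural check for path counting: unique root, no loops, no
# dangling vertex references, acyclic.  Degree-(1,1) subdivision vertices
# are tolerated here because surgeries pass through such intermediate
# states and subdivision is path-count preserving.
pn_check_dag <- function(net) {
  if (length(net$vertices) == 1 && nrow(net$arcs) == 0) return(invisible(net))
  if (any(net$arcs$tail == net$arcs$head)) stop("network has a loop arc")
  dang <- setdiff(c(net$arcs$tail, net$arcs$head), net$vertices)
  if (length(dang)) stop("arc references unknown vertex ", dang[1])
  roots <- net$vertices[!(net$vertices %in% net$arcs$head)]
  if (length(roots) != 1) stop("network does not have a unique root")
  if (is.null(pn_topo_order(net))) stop("cyclic arc relation")
  invisible(net)
}

#' Is a network binary?
#'
#' True iff every hybrid vertex has indegree exactly two (degree sum
#' three).
#'
#' @param network a valid [phylo_network()].
#' @return logical scalar.
#' @export
is_binary <- function(network) {
  stop_if_invalid(network)
  ind <- pn_indeg(network)
  all(ind[ind >= 2L] == 2L)
}

#' Root-to-leaf path counts
#'
#' Counts, for every leaf, the number of directed paths from the root,
#' by dynamic programming over a topological order.  Parallel arcs are
#' counted with multiplicity, so a bead doubles the count.
#'
#' @param network a valid [phylo_network()].
#' @return named numeric vector, taxon label -> path count.
#' @seealso [unfold_leaf_multiset()] for the independent enumeration route.
#' @export
path_count_vector <- function(network) {
  pn_check_dag(network)
  counts <- pn_vertex_path_counts(network)
  leaves <- names(network$labels)
  setNames(counts[leaves], unname(network$labels[leaves]))
}

# path counts from the root to every vertex (internal, skips validation)
pn_vertex_path_counts <- function(net) {
  if (length(net$vertices) == 1 && nrow(net$arcs) == 0) {
    return(setNames(1, net$vertices))
  }
  ord <- pn_topo_order(net)
  if (is.null(ord)) stop("cyclic arc relation; cannot count paths")
  counts <- setNames(numeric(length(net$vertices)), net$vertices)
  counts[ord[1]] <- 1
  arcs <- net$arcs
  for (v in ord[-1]) {
    counts[v] <- sum(counts[arcs$tail[arcs$head == v]])
  }
  counts
}

#' Hybrid number of a network
#'
#' \eqn{h(G)=\sum_{h \in H(G)} (indeg(h)-1)} summed over hybrid vertices;
#' for a binary network this equals the number of hybrid vertices, and a
#' phylogenetic tree has hybrid number zero.
#'
#' @param network a valid [phylo_network()].
#' @return non-negative integer.
#' @export
network_hybrid_number <- function(network) {
  pn_check_dag(network)
  ind <- pn_indeg(network)
  sum(ind[ind >= 2L] - 1L)
}

#' Does a network realize a ploidy profile?
#'
#' True iff the network's path-count vector equals the profile's
#' label-to-multiplicity mapping exactly.  The label sets must agree.
#'
#' @param network a valid [phylo_network()].
#' @param profile a [ploidy_profile()].
#' @return logical scalar.
#' @export
realizes <- function(network, profile) {
  profile <- as_profile(profile)
  pc <- path_count_vector(network)
  if (!setequal(names(pc), profile$labels)) {
    stop("network leaf labels {", paste(sort(names(pc)), collapse = ","),
         "} do not match profile labels {",
         paste(sort(profile$labels), collapse = ","), "}")
  }
  want <- setNames(profile$multiplicities, profile$labels)
  all(pc[names(want)] == want)
}

#' Leaf multiset of the unfolded network
#'
#' Explicitly enumerates every directed root-to-leaf path (the leaves of
#' the multi-labelled tree obtained by unfolding the network) and records
#' the taxon label at each path's end.  This is an independent oracle for
#' [path_count_vector()]: no dynamic programming is shared between the
#' two routes.  Exponential in the hybrid number; intended for small
#' networks.
#'
#' @param network a valid [phylo_network()].
#' @return character vector with one entry per root-to-leaf path.
#' @export
unfold_leaf_multiset <- function(network) {
  pn_check_dag(network)
  if (length(network$vertices) == 1 && nrow(network$arcs) == 0) {
    return(unname(network$labels))
  }
  root <- pn_root(network)
  arcs <- network$arcs
  labels <- network$labels
  walk <- function(v) {
    outs <- arcs$head[arcs$tail == v]
    if (!length(outs)) return(unname(labels[v]))
    unlist(lapply(outs, walk), use.names = FALSE)
  }
  walk(root)
}
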