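# Local surgeries used by the constructions and the traceback.
#
# All four operations return the modified network; the identifier of any
# newly created subdivision vertex is attached as attr(net, "new_vertex")
# so callers can chain subdivisions deterministically.

#' Subdivide an arc occurrence
#'
#' Replaces the arc occurrence `arc` (a row index of `network$arcs`, so a
#' specific member of a parallel pair can be named) by two arcs through a
#' fresh vertex.  Path counts to all pre-existing vertices are unchanged.
#'
#' @param network a valid [phylo_network()].
#' @param arc integer row index into `network$arcs`.
#' @return the updated network, with the fresh vertex id in
#'   `attr(, "new_vertex")`.
#' @export
subdivide_arc <- function(network, arc) {
  arc <- check_count(arc, "arc", min = 1)
  if (arc > nrow(network$arcs)) stop("no arc occurrence ", arc)
  f <- fresh_vertex(network)
  net <- f$net; s <- f$ids
  u <- net$arcs$tail[arc]; v <- net$arcs$head[arc]
  net$arcs$head[arc] <- s
  net$arcs <- rbind(net$arcs, data.frame(tail = s, head = v))
  rownames(net$arcs) <- NULL
  net$vertices <- c(net$vertices, s)
  attr(net, "new_vertex") <- s
  net
}

#' Expand a leaf into a cherry
#'
#' The leaf labelled `leaf_label` becomes a tree vertex with two fresh
#' leaf children labelled `leaf_label` and `new_label`.  Both children
#' inherit the old leaf's path count; the vertex count grows by exactly
#' two.  This reverses a merge step of the simplification sequence.
#'
#' @param network a valid [phylo_network()].
#' @param leaf_label existing taxon label.
#' @param new_label fresh taxon label.
#' @return the updated network.
#' @export
expand_cherry <- function(network, leaf_label, new_label) {
  net <- network
  if (new_label %in% net$labels) stop("duplicate label ", new_label)
  v <- names(net$labels)[net$labels == leaf_label]
  if (length(v) != 1) stop("no leaf labelled ", leaf_label)
  f <- fresh_vertex(net, 2L)
  net <- f$net; kids <- f$ids
  net$vertices <- c(net$vertices, kids)
  net$arcs <- rbind(net$arcs,
                    data.frame(tail = c(v, v), head = kids))
  rownames(net$arcs) <- NULL
  net$labels <- net$labels[names(net$labels) != v]
  net$labels[kids[1]] <- leaf_label
  net$labels[kids[2]] <- new_label
  net$labels <- net$labels[order(names(net$labels))]
  net
}

#' Hybridize: route extra copies from a donor leaf into a receiver leaf
#'
#' Subdivides the donor's incoming arc by a tree vertex `u` and the
#' receiver's incoming arc by a vertex `v`, then adds the arc `(u, v)`,
#' making `v` a binary hybrid vertex.  The receiver's path count becomes
#' old receiver + old donor; all other counts are unchanged; the vertex
#' count grows by two and the hybrid number by one.  This reverses a
#' subtract step of the simplification sequence (both the
#' `alpha > m2` and the `alpha <= m2` case use the same generic surgery).
#'
#' @param network a valid [phylo_network()].
#' @param donor_label,receiver_label distinct existing taxon labels.
#' @return the updated network.
#' @export
hybridize <- function(network, donor_label, receiver_label) {
  if (identical(donor_label, receiver_label)) {
    stop("donor and receiver must be distinct leaves")
  }
  net <- network
  dv <- names(net$labels)[net$labels == donor_label]
  rv <- names(net$labels)[net$labels == receiver_label]
  if (length(dv) != 1) stop("no leaf labelled ", donor_label)
  if (length(rv) != 1) stop("no leaf labelled ", receiver_label)
  darc <- which(net$arcs$head == dv)
  rarc <- which(net$arcs$head == rv)
  if (length(darc) != 1 || length(rarc) != 1) {
    stop("donor and receiver must be leaves with a single incoming arc")
  }
  net <- subdivide_arc(net, darc)
  u <- attr(net, "new_vertex")
  rarc <- which(net$arcs$head == rv)  # index may have moved
  net <- subdivide_arc(net, rarc)
  v <- attr(net, "new_vertex")
  net$arcs <- rbind(net$arcs, data.frame(tail = u, head = v))
  rownames(net$arcs) <- NULL
  attr(net, "new_vertex") <- NULL
  net
}

#' Attach a pendant leaf to an arc
#'
#' Subdivides the arc occurrence by a vertex `t` and hangs a fresh leaf
#' labelled `label` from `t`.  The new leaf's path count equals the
#' root-to-`t` count; all existing counts are unchanged; +2 vertices.
#'
#' @param network a valid [phylo_network()].
#' @param arc integer row index into `network$arcs`.
#' @param label fresh taxon label.
#' @return the updated network, with the subdivision vertex id in
#'   `attr(, "new_vertex")`.
#' @export
add_pendant_leaf <- function(network, arc, label) {
  if (label %in% network$labels) stop("duplicate label ", label)
  net <- subdivide_arc(network, arc)
  t <- attr(net, "new_vertex")
  f <- fresh_vertex(net)
  net <- f$net; leaf <- f$ids
  net$vertices <- c(net$vertices, leaf)
  net$arcs <- rbind(net$arcs, data.frame(tail = t, head = leaf))
  rownames(net$arcs) <- NULL
  net$labels[leaf] <- label
  net$labels <- net$labels[order(names(net$labels))]
  attr(net, "new_vertex") <- t
  net
}
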