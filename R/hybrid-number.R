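# Top-level hybrid-number API: the closed formula h(m) = h(m_t) + c(s(m))
# with certified bounds when its hypothesis fails.

#' Upper bound from per-component binary representations
#'
#' Sums, over the components of the profile, `msb exponent + popcount - 1`
#' -- the hybrid count of the binary-representation realization of each
#' component hung off a common root.  Sharp for simple profiles.
#'
#' @param profile a [ploidy_profile()].
#' @return non-negative integer.
#' @export
proposition2_upper <- function(profile) {
  profile <- as_profile(profile)
  s <- 0L
  for (m in profile$multiplicities) {
    rep <- binary_representation(m)
    s <- s + rep$exponents[1] + length(rep$exponents) - 1L
  }
  as.integer(s)
}

is_pow2 <- function(x) bitwAnd(x, x - 1L) == 0L

# beaded chain attainment for a profile whose components are all powers
# of two: pendant leaves hang off subdivisions at the depth whose path
# count equals each component
power_of_two_attainment <- function(profile) {
  mult <- profile$multiplicities
  labels <- profile$labels
  e1 <- ceil_log2(mult[1])
  if (e1 == 0) return(caterpillar_tree(labels))   # all-ones profile
  net <- beaded_tree(e1, labels[1])
  hybs <- attr(net, "bead_hybrids")
  n <- length(mult)
  if (n >= 2) {
    for (i in 2:n) {
      e <- ceil_log2(mult[i])
      arc <- if (e == 0) {
        which(net$arcs$tail == pn_root(net))[1]
      } else {
        which(net$arcs$tail == hybs[e])[1]        # out-arc: count 2^e
      }
      net <- add_pendant_leaf(net, arc, labels[i])
    }
    attr(net, "new_vertex") <- NULL
  }
  attr(net, "bead_hybrids") <- NULL
  pn_renumber(net)
}

#' Hybrid number of a ploidy profile
#'
#' Runs the full pipeline.  The simplification sequence is computed and
#' its terminal simple profile attained ([attain_simple()]).  When no
#' step fired line 8 (`m1 > 2 m2` never held) and the terminal attainment
#' is certified, the closed formula `h(m) = h(m_t) + c(s(m))` is exact
#' and the traceback network is a verifying certificate.  Profiles whose
#' components are all powers of two short-circuit to the exact value
#' `log2(m1)` with a beaded-chain certificate, valid even when line 8
#' fires.  Otherwise certified lower and upper bounds are reported: the
#' lower bound is the path-count bound `ceil_log2(m1)`, improved to the
#' exact hybrid number of `(m1)` when the search certifies it (deleting
#' the other leaves of any realization cannot increase the hybrid
#' number); the upper bound is the best of the traceback network, the
#' per-component star bound ([proposition2_upper()]) and the naive
#' realization, with the winning network as certificate.
#'
#' @param profile a [ploidy_profile()].
#' @param search_limit a [search_config()].
#' @return an object of class `hybrid_number_result`: list with `status`
#'   ("exact" or "bounds"), `value` (when exact), `lower`, `upper`,
#'   `certificate` (a network realizing `profile` whose hybrid number is
#'   `upper`), and `method_notes`.
#' @examples
#' hybrid_number(c(12, 6, 6, 5))$value  # 5
#' @export
hybrid_number <- function(profile, search_limit = search_config()) {
  profile <- as_profile(profile)
  seq <- simplification_sequence(profile)
  term <- terminal_profile(seq)
  notes <- character(0)

  if (all(vapply(profile$multiplicities, is_pow2, logical(1)))) {
    # exact even when line 8 fires
    h <- ceil_log2(profile$multiplicities[1])
    cert <- power_of_two_attainment(profile)
    stopifnot(realizes(cert, profile), network_hybrid_number(cert) == h)
    return(new_hn_result("exact", value = h, lower = h, upper = h,
                         certificate = cert,
                         notes = "all components are powers of two: h = log2(m1) with a beaded-chain certificate"))
  }

  att <- attain_simple(term, search_limit)
  N <- build_N(seq, att$network)
  hN <- network_hybrid_number(N)

  if (!line8_fired(seq) && att$certified) {
    value <- att$h + c_of(seq)
    stopifnot(hN == value)
    return(new_hn_result("exact", value = value, lower = value, upper = value,
                         certificate = N,
                         notes = c("closed formula h(m) = h(m_t) + c(s(m))",
                                   att$note %||% character(0))))
  }

  if (line8_fired(seq)) {
    notes <- c(notes, "line 8 fired during simplification: the traceback network need not be optimal; reporting bounds")
  }
  if (!att$certified) {
    notes <- c(notes, "terminal attainment not certified (search limit exceeded); reporting bounds")
  }
  m1 <- profile$multiplicities[1]
  lower <- ceil_log2(m1)
  if (m1 <= search_limit$max_head && lower <= search_limit$max_budget) {
    core <- attain_strictly_simple_head(m1, search_limit)
    if (core$certified) {
      lower <- max(lower, core$h)
      notes <- c(notes, "lower bound: exact hybrid number of (m1) by leaf deletion")
    }
  } else {
    notes <- c(notes, "lower bound: path-count bound ceil(log2(m1))")
  }
  cands <- list(traceback = N)
  cands$naive <- naive_realization(profile)
  hs <- vapply(cands, network_hybrid_number, numeric(1))
  p2 <- proposition2_upper(profile)
  if (p2 < min(hs)) {
    cands$star <- star_of_B(profile)
    hs <- c(hs, star = p2)
  }
  best <- names(hs)[which.min(hs)]
  upper <- as.integer(min(hs))
  notes <- c(notes, paste0("upper bound certificate: ", best, " construction"))
  cert <- cands[[best]]
  stopifnot(realizes(cert, profile), network_hybrid_number(cert) == upper)
  new_hn_result("bounds", value = NULL, lower = as.integer(lower),
                upper = upper, certificate = cert, notes = notes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_hn_result <- function(status, value, lower, upper, certificate, notes) {
  stopifnot(lower <= upper)
  structure(list(status = status, value = value,
                 lower = as.integer(lower), upper = as.integer(upper),
                 certificate = certificate,
                 method_notes = notes),
            class = "hybrid_number_result")
}

#' @export
print.hybrid_number_result <- function(x, ...) {
  if (x$status == "exact") {
    cat("hybrid number:", x$value, "(exact)\n")
  } else {
    cat("hybrid number in [", x$lower, ", ", x$upper, "] (bounds)\n", sep = "")
  }
  for (n in x$method_notes) cat("  -", n, "\n")
  invisible(x)
}

# star of per-component B networks (the construction behind
# proposition2_upper): component realizations under a resolved common root
star_of_B <- function(profile) {
  mult <- profile$multiplicities
  labels <- profile$labels
  n <- length(mult)
  if (n == 1) return(build_B(profile))
  blocks <- lapply(seq_len(n), function(k) {
    build_B(ploidy_profile(mult[k], labels[k]))
  })
  # caterpillar root spine with one block per pendant position
  arcs <- NULL
  lab <- character(0)
  attach_points <- character(0)
  for (i in seq_len(n - 1)) {
    sp <- paste0("r", i)
    nxt <- if (i < n - 1) paste0("r", i + 1) else "slot_last"
    arcs <- rbind(arcs, data.frame(tail = c(sp, sp),
                                   head = c(paste0("slot", i), nxt)))
    attach_points <- c(attach_points, paste0("slot", i))
  }
  attach_points <- c(attach_points, "slot_last")
  for (k in seq_len(n)) {
    b <- blocks[[k]]
    if (length(b$vertices) == 1) {
      # unit component: the slot itself becomes the leaf
      lab[attach_points[k]] <- labels[k]
      next
    }
    a <- b$arcs
    pre <- paste0("b", k, "_")
    a$tail <- paste0(pre, a$tail)
    a$head <- paste0(pre, a$head)
    root_k <- paste0(pre, pn_root(b))
    a$tail[a$tail == root_k] <- attach_points[k]
    arcs <- rbind(arcs, a)
    lab[paste0(pre, names(b$labels))] <- unname(b$labels)
  }
  pn_renumber(phylo_network(arcs, lab))
}
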