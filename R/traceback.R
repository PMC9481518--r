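# Traceback: rebuild a realization of the input profile by reversing the
# simplification sequence, starting from an attainment of its terminal
# (simple) profile.

#' Build N(m) from a simplification sequence
#'
#' Reverses the steps of `seq` last-to-first, starting from
#' `terminal_network`: a merge step is undone by [expand_cherry()]
#' (re-introducing the removed taxon next to its survivor) and a subtract
#' step by [hybridize()] (routing the donor's copies back into the
#' receiver).  Each reversal adds exactly two vertices, so the result has
#' `|V(terminal)| + 2 s` vertices; each subtract reversal adds exactly
#' one hybrid vertex, so the hybrid number grows by the number of
#' subtract steps.  The result is binary whenever the terminal network is
#' and realizes the input profile of `seq`.
#'
#' @param seq a [simplification_sequence()].
#' @param terminal_network a binary network realizing
#'   [terminal_profile()] of `seq` (matching labels); checked.
#' @return a `phylo_network` realizing the first profile of `seq`.
#' @export
build_N <- function(seq, terminal_network) {
  stopifnot(inherits(seq, "simplification_sequence"))
  term <- terminal_profile(seq)
  if (!is_binary(terminal_network)) {
    stop("the terminal network must be binary")
  }
  if (!realizes(terminal_network, term)) {
    stop("the terminal network does not realize the terminal profile")
  }
  net <- terminal_network
  steps <- seq$steps
  for (i in rev(seq_len(nrow(steps)))) {
    if (steps$kind[i] == "merge") {
      net <- expand_cherry(net, steps$donor_label[i], steps$receiver_label[i])
    } else {
      net <- hybridize(net, donor_label = steps$donor_label[i],
                       receiver_label = steps$receiver_label[i])
    }
  }
  net <- pn_renumber(net)
  stopifnot(realizes(net, seq$profiles[[1]]))
  net
}

#' Realize a profile end-to-end
#'
#' Computes the simplification sequence, obtains a terminal network from
#' [attain_simple()] (exhaustive search when the terminal head is within
#' `search_limit`, else the better of the B/D constructions), and runs
#' the traceback.  The returned network always realizes `profile`; it is
#' an attainment exactly when the initialization was certified and no
#' step of the sequence fired line 8.
#'
#' @param profile a [ploidy_profile()].
#' @param search_limit a [search_config()].
#' @return a `phylo_network` with attributes `certified_init` (logical:
#'   the terminal network was a certified attainment), `seq` (the
#'   simplification sequence) and `terminal_h` (hybrid number of the
#'   terminal network).
#' @export
build_N_auto <- function(profile, search_limit = search_config()) {
  profile <- as_profile(profile)
  seq <- simplification_sequence(profile)
  att <- attain_simple(terminal_profile(seq), search_limit)
  net <- build_N(seq, att$network)
  attr(net, "certified_init") <- att$certified
  attr(net, "seq") <- seq
  attr(net, "terminal_h") <- att$h
  net
}
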