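# The simplification sequence of a ploidy profile: iteratively reduce a
# profile to a simple terminal profile, recording per-step bookkeeping so
# the traceback can reverse every step.

#' Simplification sequence of a ploidy profile
#'
#' Repeats, until the profile is simple, with `alpha = m1 - m2`:
#' \itemize{
#'   \item `alpha == 0` (merge, "line 6"): delete the first component and
#'     record which taxon was merged into which surviving taxon;
#'   \item `alpha > 0` (subtract, "line 8" when `alpha > m2`, "line 10"
#'     when `alpha <= m2`): replace the first component by `alpha`
#'     (keeping its taxon label), re-sort descending.
#' }
#' Sorting is stable and a replaced component is re-inserted after all
#' components of equal value; when several components tie at the top the
#' merge removes the first and records the second as survivor.  The line
#' number is recorded because the exactness guarantee of the closed
#' formula conditions on line 8 never firing.
#'
#' @param profile a [ploidy_profile()] (or bare numeric vector).
#' @return an object of class `simplification_sequence`: list with
#'   `profiles` (list of [ploidy_profile()], first = input, last =
#'   simple terminal) and `steps` (data.frame with columns `kind`
#'   ("merge"/"subtract"), `alpha`, `line` (6, 8 or 10),
#'   `receiver_label`, `donor_label`).
#' @examples
#' s <- simplification_sequence(c(12, 6, 6, 5))
#' sapply(s$profiles, function(p) paste(p$multiplicities, collapse = ","))
#' @export
simplification_sequence <- function(profile) {
  p <- as_profile(profile)
  profiles <- list(p)
  steps <- data.frame(kind = character(0), alpha = integer(0),
                      line = integer(0), receiver_label = character(0),
                      donor_label = character(0))
  cur <- p
  while (!is_simple(cur)) {
    m <- cur$multiplicities
    lab <- cur$labels
    alpha <- m[1] - m[2]
    if (alpha == 0L) {
      steps <- rbind(steps, data.frame(
        kind = "merge", alpha = 0L, line = 6L,
        receiver_label = lab[1], donor_label = lab[2]))
      cur <- structure(list(labels = lab[-1], multiplicities = m[-1]),
                       class = "ploidy_profile")
    } else {
      line <- if (alpha > m[2]) 8L else 10L
      steps <- rbind(steps, data.frame(
        kind = "subtract", alpha = alpha, line = line,
        receiver_label = lab[1], donor_label = lab[2]))
      # re-insert the shrunk head after all components of equal value
      rest_m <- m[-1]; rest_lab <- lab[-1]
      k <- sum(rest_m >= alpha)
      new_m <- append(rest_m, alpha, after = k)
      new_lab <- append(rest_lab, lab[1], after = k)
      cur <- structure(list(labels = new_lab, multiplicities = as.integer(new_m)),
                       class = "ploidy_profile")
    }
    profiles <- c(profiles, list(cur))
  }
  structure(list(profiles = profiles, steps = steps),
            class = "simplification_sequence")
}

#' @export
print.simplification_sequence <- function(x, ...) {
  cat("simplification sequence, s =", s_of(x), ", c =", c_of(x), "\n")
  for (p in x$profiles) {
    cat("  (", paste(p$multiplicities, collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' Number of simplification steps s(m)
#'
#' The number of profiles in the sequence other than the input; zero for
#' a simple profile.
#'
#' @param seq a [simplification_sequence()].
#' @return non-negative integer.
#' @export
s_of <- function(seq) {
  stopifnot(inherits(seq, "simplification_sequence"))
  length(seq$profiles) - 1L
}

#' Number of subtract steps c(s(m))
#'
#' Counts the steps whose source profile has a strict head,
#' `m1 > m2`; these are exactly the steps that add a hybrid vertex in the
#' traceback, so the closed formula reads `h(m) = h(m_t) + c(s(m))`.
#'
#' @param seq a [simplification_sequence()].
#' @return non-negative integer.
#' @export
c_of <- function(seq) {
  stopifnot(inherits(seq, "simplification_sequence"))
  sum(seq$steps$kind == "subtract")
}

#' Did a subtract step exceed the donor (line 8)?
#'
#' True iff some step has `alpha > m2`, equivalently some non-terminal
#' profile has `m1 > 2 m2`.  When this never happens, the traceback
#' network is an attainment and the closed formula is exact; otherwise
#' only bounds are certified.
#'
#' @param seq a [simplification_sequence()].
#' @return logical scalar.
#' @export
line8_fired <- function(seq) {
  stopifnot(inherits(seq, "simplification_sequence"))
  any(seq$steps$line == 8L)
}

#' Terminal (simple) profile of a simplification sequence
#'
#' @param seq a [simplification_sequence()].
#' @return a [ploidy_profile()].
#' @export
terminal_profile <- function(seq) {
  stopifnot(inherits(seq, "simplification_sequence"))
  seq$profiles[[length(seq$profiles)]]
}
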