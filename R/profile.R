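# Ploidy profiles: descending multiplicity vectors indexed by taxa.

#' Create a ploidy profile
#'
#' A ploidy profile is a vector of positive integers, one per taxon,
#' stored in descending order.  Component `i` is the ploidy number (number
#' of complete chromosome sets, up to the diploid root factor) of taxon
#' `i`.  Sorting is stable, so taxa with equal multiplicities keep their
#' input order.
#'
#' @param multiplicities positive integers.
#' @param labels optional character vector of unique taxon labels; default
#'   `x1, x2, ...` assigned after the descending sort.
#' @return an object of class `ploidy_profile`: a list with `labels`
#'   (character) and `multiplicities` (integer, descending).
#' @examples
#' ploidy_profile(c(12, 6, 6, 5))
#' @export
ploidy_profile <- function(multiplicities, labels = NULL) {
  if (length(multiplicities) < 1) {
    stop("a ploidy profile needs at least one component")
  }
  m <- multiplicities
  if (any(is.na(m)) || !is.numeric(m) || any(m != floor(m)) || any(m < 1)) {
    stop("multiplicities must be positive integers")
  }
  m <- as.integer(m)
  if (!is.null(labels)) {
    if (length(labels) != length(m)) {
      stop("labels and multiplicities differ in length")
    }
    if (anyDuplicated(labels)) stop("taxon labels must be unique")
    labels <- as.character(labels)
  }
  o <- order(m, decreasing = TRUE)  # stable in R
  m <- m[o]
  if (is.null(labels)) {
    labels <- paste0("x", seq_along(m))
  } else {
    labels <- labels[o]
  }
  structure(list(labels = labels, multiplicities = m),
            class = "ploidy_profile")
}

#' @export
print.ploidy_profile <- function(x, ...) {
  cat("ploidy profile (", paste(x$multiplicities, collapse = ", "), ") on {",
      paste(x$labels, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' @export
length.ploidy_profile <- function(x) length(x$multiplicities)

as_profile <- function(x) {
  if (inherits(x, "ploidy_profile")) return(x)
  ploidy_profile(x)
}

#' Is a profile simple / strictly simple?
#'
#' A profile is simple if every component after the first equals one, and
#' strictly simple if it is simple with a single taxon.
#'
#' @param profile a [ploidy_profile()] (or a bare numeric vector).
#' @return logical scalar.
#' @export
is_simple <- function(profile) {
  p <- as_profile(profile)
  length(p) == 1L || all(p$multiplicities[-1] == 1L)
}

#' @rdname is_simple
#' @export
is_strictly_simple <- function(profile) {
  p <- as_profile(profile)
  length(p) == 1L
}

#' Seeded random ploidy profile
#'
#' Draws `n` multiplicities uniformly from `1:max_entry`.  The seed is
#' mandatory so fixtures are reproducible; the caller's RNG state is left
#' untouched.
#'
#' @param seed integer seed (required).
#' @param n number of taxa.
#' @param max_entry largest possible multiplicity.
#' @return a [ploidy_profile()].
#' @export
random_profile <- function(seed, n = 5, max_entry = 32) {
  seed <- check_count(seed, "seed", min = 0)
  n <- check_count(n, "n", min = 1)
  max_entry <- check_count(max_entry, "max_entry", min = 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  ploidy_profile(sample.int(max_entry, n, replace = TRUE))
}
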