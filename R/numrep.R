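# Integer representations underpinning the B and D constructions.

#' Binary representation of a positive integer
#'
#' Returns both the bitwise 0/1 vector (most significant bit first, no
#' leading zeros) and the strictly decreasing exponent vector
#' \eqn{(i_1,\ldots,i_q)} with \eqn{m = \sum_j 2^{i_j}}.  The leading
#' exponent \eqn{i_1} is the position of the most significant bit and
#' \eqn{q} the popcount of `m`.
#'
#' @param m a single integer, `m >= 1`.
#' @return A list of class `binary_representation` with components
#'   `bitwise` (integer 0/1 vector) and `exponents` (decreasing
#'   non-negative integers).
#' @examples
#' binary_representation(11)  # bitwise (1,0,1,1), exponents (3,1,0)
#' @export
binary_representation <- function(m) {
  m <- check_count(m, "m", min = 1)
  bits <- integer(0)
  v <- m
  while (v > 0) {
    bits <- c(v %% 2, bits)
    v <- v %/% 2
  }
  f <- length(bits) - 1L
  exponents <- f - (which(bits == 1L) - 1L)
  structure(list(bitwise = as.integer(bits), exponents = as.integer(exponents)),
            class = "binary_representation")
}

#' Number of non-leading one bits
#'
#' `p_of(m)` is the popcount of `m` minus one, i.e. the number of ones in
#' the bitwise representation of `m` excluding the most significant bit.
#'
#' @param m a single integer, `m >= 1`.
#' @return a non-negative integer.
#' @examples
#' p_of(6)  # 1
#' @export
p_of <- function(m) {
  length(binary_representation(m)$exponents) - 1L
}

#' Prime factorization with descending primes
#'
#' Deterministic trial division.  Primes are returned in strictly
#' descending order, matching the convention used by the `D` construction
#' (largest prime stacked first, nearest the root).
#'
#' @param m a single integer, `2 <= m <= max_m`.
#' @param max_m refusal bound for trial division (profile entries are
#'   biology-scale integers; default `1e6`).
#' @return a data.frame with columns `prime` and `exponent`,
#'   primes strictly descending, such that `prod(prime^exponent) == m`.
#' @examples
#' prime_factorization_desc(265)  # 53^1 * 5^1
#' @export
prime_factorization_desc <- function(m, max_m = 1e6) {
  m <- check_count(m, "m", min = 2)
  if (m > max_m) {
    stop("prime_factorization_desc(): m = ", m, " exceeds the bound ", max_m)
  }
  primes <- integer(0)
  expos <- integer(0)
  v <- m
  d <- 2L
  while (d * d <= v) {
    if (v %% d == 0L) {
      e <- 0L
      while (v %% d == 0L) {
        v <- v %/% d
        e <- e + 1L
      }
      primes <- c(primes, d)
      expos <- c(expos, e)
    }
    d <- d + 1L
  }
  if (v > 1L) {
    primes <- c(primes, as.integer(v))
    expos <- c(expos, 1L)
  }
  o <- order(primes, decreasing = TRUE)
  data.frame(prime = primes[o], exponent = expos[o])
}

#' Smallest h with 2^h >= m
#'
#' The path-count ceiling: a binary single-leaf network with `h` hybrid
#' vertices has at most `2^h` root-to-leaf paths, so any realization of
#' the strictly simple profile `(m)` needs at least `ceil_log2(m)`
#' hybrid vertices.
#'
#' @param m a single integer, `m >= 1`.
#' @return a non-negative integer.
#' @examples
#' ceil_log2(5)  # 3
#' @export
ceil_log2 <- function(m) {
  m <- check_count(m, "m", min = 1)
  h <- 0L
  p <- 1
  while (p < m) {
    p <- p * 2
    h <- h + 1L
  }
  h
}

# shared scalar-count argument check
check_count <- function(x, name, min = 0) {
  if (length(x) != 1 || is.na(x) || !is.numeric(x) || x != floor(x) || x < min) {
    stop(name, " must be a single integer >= ", min)
  }
  as.integer(x)
}
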