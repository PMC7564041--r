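#' Exact hypergeometric probabilities for rule scoring
#'
#' The significance of every SSIR rule rests on the classical urn experiment:
#' an urn holds `a` marbles of which `b` are "of interest"; a rule draws `c`
#' marbles without replacement and `d` of them turn out to be of interest.
#' These functions compute the point probability and both tail p-values of
#' that experiment, either in floating point (log-gamma binomials) or in an
#' exact-rational mode used when printed fractions must be reproduced
#' verbatim.
#'
#' The support of `d` is `max(0, c + b - a) <= d <= min(b, c)`.
#'
#' @name hypergeom
#' @keywords internal
NULL

.check_urn <- function(a, b, c) {
  stopifnot(length(a) == 1, length(b) == 1, length(c) == 1)
  if (!is.finite(a) || a != round(a) || a < 1)
    stop("'a' must be a positive integer", call. = FALSE)
  if (!is.finite(b) || b != round(b) || b < 0 || b > a)
    stop("'b' must be an integer with 0 <= b <= a", call. = FALSE)
  if (!is.finite(c) || c != round(c) || c < 0 || c > a)
    stop("'c' must be an integer with 0 <= c <= a", call. = FALSE)
  invisible(NULL)
}

.d_support <- function(a, b, c) c(max(0, c + b - a), min(b, c))

.check_d <- function(a, b, c, d) {
  s <- .d_support(a, b, c)
  if (!is.finite(d) || d != round(d))
    stop("'d' must be an integer", call. = FALSE)
  if (d < s[1])
    stop(sprintf("d = %d below the support minimum max(0, c + b - a) = %d",
                 as.integer(d), as.integer(s[1])), call. = FALSE)
  if (d > s[2])
    stop(sprintf("d = %d above the support maximum min(b, c) = %d",
                 as.integer(d), as.integer(s[2])), call. = FALSE)
  invisible(NULL)
}

## log pmf via log-gamma binomials; vectorized over d
.log_pmf <- function(a, b, c, d) {
  lchoose(b, d) + lchoose(a - b, c - d) - lchoose(a, c)
}

#' Hypergeometric point probability P(d, c; b, a)
#'
#' Probability that a random draw of `c` samples from a library of `a`
#' (containing `b` samples of interest) contains exactly `d` of interest.
#'
#' @param a library size (positive integer).
#' @param b number of samples of interest, `0 <= b <= a`.
#' @param c number of samples drawn (covered by a rule), `0 <= c <= a`.
#' @param d number of drawn samples of interest; must lie in the support
#'   `max(0, c + b - a) .. min(b, c)`.
#' @param rational if `TRUE`, return an exact fraction (an
#'   [ssir_fraction]) instead of a double. Exact arithmetic requires
#'   `choose(a, c) < 2^53`; larger problems must use the default
#'   floating-point mode.
#' @return A probability in `[0, 1]`, as a double or an `ssir_fraction`.
#' @examples
#' hyper_pmf(9, 5, 4, 3)                   # 20/63
#' hyper_pmf(9, 5, 4, 3, rational = TRUE)
#' @seealso [hyper_upper_tail()], [hyper_lower_tail()], [hyper_moments()]
#' @export
hyper_pmf <- function(a, b, c, d, rational = FALSE) {
  .check_urn(a, b, c)
  .check_d(a, b, c, d)
  if (rational) {
    num <- .exact_choose(b, d) * .exact_choose(a - b, c - d)
    return(ssir_fraction(num, .exact_choose(a, c)))
  }
  exp(.log_pmf(a, b, c, d))
}

## tail over an explicit d range, summed in one go (range is never long
## because callers pick the shorter tail)
.sum_pmf <- function(a, b, c, lo, hi) {
  if (hi < lo) return(0)
  sum(exp(.log_pmf(a, b, c, lo:hi)))
}

#' Upper-tail p-value p(d+, c; b, a)
#'
#' Probability that a random draw of `c` contains `d` *or more* samples of
#' interest: the significance of a positive-vote rule. Values of `d` below
#' the support minimum return 1 and above the support maximum return 0, so
#' the function is total and monotone in `d`.
#'
#' The implementation sums the shorter of the two tails and complements,
#' bounding accumulated rounding.
#'
#' @inheritParams hyper_pmf
#' @return Probability in `[0, 1]`.
#' @examples
#' hyper_upper_tail(9, 5, 4, 3)  # 45/126
#' hyper_upper_tail(100, 20, 30, 2)
#' @export
hyper_upper_tail <- function(a, b, c, d, rational = FALSE) {
  .check_urn(a, b, c)
  s <- .d_support(a, b, c)
  if (!is.finite(d) || d != round(d)) stop("'d' must be an integer", call. = FALSE)
  if (rational) {
    den <- .exact_choose(a, c)
    if (d <= s[1]) return(ssir_fraction(den, den))
    if (d > s[2]) return(ssir_fraction(0, den))
    num <- sum(vapply(d:s[2], function(i)
      .exact_choose(b, i) * .exact_choose(a - b, c - i), numeric(1)))
    if (num > 2^53) stop("exact-rational mode overflow; use rational = FALSE")
    return(ssir_fraction(num, den))
  }
  if (d <= s[1]) return(1)
  if (d > s[2]) return(0)
  n_up <- s[2] - d + 1
  n_lo <- d - s[1]
  if (n_up <= n_lo) .sum_pmf(a, b, c, d, s[2])
  else 1 - .sum_pmf(a, b, c, s[1], d - 1)
}

#' Lower-tail p-value p(d-, c; b, a)
#'
#' Probability that a random draw of `c` contains `d` *or fewer* samples of
#' interest: the significance of a negative-vote rule. Satisfies
#' `lower(d) + upper(d + 1) = 1` and the duality
#' `lower(d, c; b, a) = upper(b - d, a - c; b, a)`.
#'
#' @inheritParams hyper_pmf
#' @return Probability in `[0, 1]`.
#' @examples
#' hyper_lower_tail(100, 20, 30, 2)  # ~0.023
#' @export
hyper_lower_tail <- function(a, b, c, d, rational = FALSE) {
  .check_urn(a, b, c)
  s <- .d_support(a, b, c)
  if (!is.finite(d) || d != round(d)) stop("'d' must be an integer", call. = FALSE)
  if (rational) {
    den <- .exact_choose(a, c)
    if (d >= s[2]) return(ssir_fraction(den, den))
    if (d < s[1]) return(ssir_fraction(0, den))
    num <- sum(vapply(s[1]:d, function(i)
      .exact_choose(b, i) * .exact_choose(a - b, c - i), numeric(1)))
    if (num > 2^53) stop("exact-rational mode overflow; use rational = FALSE")
    return(ssir_fraction(num, den))
  }
  if (d >= s[2]) return(1)
  if (d < s[1]) return(0)
  n_lo <- d - s[1] + 1
  n_up <- s[2] - d
  if (n_lo <= n_up) .sum_pmf(a, b, c, s[1], d)
  else 1 - .sum_pmf(a, b, c, d + 1, s[2])
}

#' Mean and variance of the hypergeometric draw
#'
#' For a draw of `c` from `a` with `b` of interest: mean `cb/a`, variance
#' `bc(a-b)(a-c) / (a^2 (a-1))`.
#'
#' @inheritParams hyper_pmf
#' @param variance compute the variance too? Requires `a >= 2`.
#' @return Named list with `mean` and (if requested) `variance`.
#' @examples
#' hyper_moments(100, 20, 30)  # mean 6
#' @export
hyper_moments <- function(a, b, c, variance = TRUE) {
  .check_urn(a, b, c)
  out <- list(mean = c * b / a)
  if (variance) {
    if (a < 2) stop("variance requires a >= 2", call. = FALSE)
    out$variance <- b * c * (a - b) * (a - c) / (a^2 * (a - 1))
  }
  out
}

## ---- exact-rational support ------------------------------------------------

## binomial coefficients by additive Pascal recursion: every intermediate is
## an exact integer in double precision while < 2^53
.exact_choose <- function(n, k) {
  if (k < 0 || k > n) return(0)
  k <- min(k, n - k)
  if (k == 0) return(1)
  row <- c(1, rep(0, k))        # row for n' = 0 truncated at column k
  for (m in seq_len(n)) {
    hi <- min(m, k)
    # right-to-left in-place: C(m, j) = C(m-1, j) + C(m-1, j-1)
    for (j in seq(hi + 1, 2)) row[j] <- row[j] + row[j - 1]
  }
  if (row[k + 1] > 2^53) stop("exact-rational mode overflow; use rational = FALSE")
  row[k + 1]
}

.gcd <- function(x, y) {
  while (y != 0) { r <- x %% y; x <- y; y <- r }
  x
}

#' Exact fraction
#'
#' Minimal exact-rational value used by the hypergeometric functions'
#' `rational = TRUE` mode. Numerator and denominator are exact integers
#' stored in doubles (valid below 2^53) and reduced by their GCD.
#'
#' @param num,den non-negative integer numerator and positive denominator.
#' @return Object of class `ssir_fraction` with fields `num` and `den`.
#' @examples
#' ssir_fraction(45, 126)  # reduces to 5/14
#' @export
ssir_fraction <- function(num, den) {
  stopifnot(is.finite(num), is.finite(den), den > 0,
            num == round(num), den == round(den), num >= 0)
  if (num > 2^53 || den > 2^53) stop("exact fraction overflow")
  g <- if (num == 0) den else .gcd(num, den)
  structure(list(num = num / g, den = den / g), class = "ssir_fraction")
}

#' @export
print.ssir_fraction <- function(x, ...) {
  cat(sprintf("%d/%d (= %.10g)\n", as.integer(x$num), as.integer(x$den),
              x$num / x$den))
  invisible(x)
}

#' @export
as.double.ssir_fraction <- function(x, ...) x$num / x$den

#' @export
`==.ssir_fraction` <- function(e1, e2) {
  to_frac <- function(e) if (inherits(e, "ssir_fraction")) e else {
    stopifnot(is.numeric(e), length(e) == 1)
    ssir_fraction(e * 1, 1) # only exact integers comparable this way
  }
  a <- to_frac(e1); b <- to_frac(e2)
  a$num * b$den == b$num * a$den
}
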