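## Exact rational scalars, stored as length-2 doubles c(num, den), den > 0,
## always reduced. Numerators/denominators are kept as exactly representable
## integers (|x| < 2^52); operations check this bound so that silent loss of
## exactness is impossible.

.RAT_MAX <- 2^52

#' Construct an exact rational number
#'
#' Rationals are the numeric backbone of the package: branch lengths, depths
#' and interval endpoints are all exact, so the equality tests in the
#' reconciliation algorithms are well posed.
#'
#' @param num integer-valued numerator.
#' @param den integer-valued denominator (non-zero).
#' @return a length-2 numeric vector \code{c(num, den)} in lowest terms with
#'   a positive denominator.
#' @examples
#' rat(6, 4)        # 3/2
#' rat_add(rat(1, 3), rat(1, 6))
#' @export
rat <- function(num, den = 1) {
  if (den == 0) stop("rational with zero denominator")
  if (num != round(num) || den != round(den)) stop("rat() needs integer parts")
  if (den < 0) { num <- -num; den <- -den }
  g <- .rat_gcd(abs(num), den)
  if (g > 1) { num <- num / g; den <- den / g }
  if (abs(num) >= .RAT_MAX || den >= .RAT_MAX)
    stop("rational overflow: numbers too large for exact arithmetic")
  c(num, den)
}

.rat_gcd <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  if (a == 0) 1 else a
}

#' @rdname rat
#' @param a,b rationals.
#' @export
rat_add <- function(a, b) rat(a[1] * b[2] + b[1] * a[2], a[2] * b[2])

#' @rdname rat
#' @export
rat_sub <- function(a, b) rat(a[1] * b[2] - b[1] * a[2], a[2] * b[2])

#' @rdname rat
#' @export
rat_mul <- function(a, b) rat(a[1] * b[1], a[2] * b[2])

#' @rdname rat
#' @export
rat_div <- function(a, b) {
  if (b[1] == 0) stop("division by zero rational")
  rat(a[1] * b[2], a[2] * b[1])
}

rat_neg <- function(a) c(-a[1], a[2])

#' Three-way comparison of rationals
#' @param a,b rationals.
#' @return -1, 0 or 1 as \code{a} is less than, equal to, or greater than
#'   \code{b}.
#' @export
rat_cmp <- function(a, b) {
  x <- a[1] * b[2]
  y <- b[1] * a[2]
  if (abs(x) >= 2^53 || abs(y) >= 2^53)
    stop("rational overflow in comparison")
  if (x < y) -1L else if (x > y) 1L else 0L
}

rat_eq <- function(a, b) a[1] == b[1] && a[2] == b[2]
rat_lt <- function(a, b) rat_cmp(a, b) < 0L
rat_le <- function(a, b) rat_cmp(a, b) <= 0L
rat_sign <- function(a) sign(a[1])
rat_abs <- function(a) c(abs(a[1]), a[2])
rat_min <- function(a, b) if (rat_le(a, b)) a else b
rat_max <- function(a, b) if (rat_le(a, b)) b else a
rat_half <- function(a) rat(a[1], a[2] * 2)

RAT0 <- c(0, 1)
RAT1 <- c(1, 1)

#' Parse a decimal or fractional literal into an exact rational
#'
#' Decimal literals such as \code{"1.25"} are converted exactly (no binary
#' floating point is involved); literals of the form \code{"3/7"} are read
#' as fractions.
#'
#' @param s a character scalar.
#' @return a rational.
#' @export
rat_parse <- function(s) {
  s <- trimws(s)
  if (grepl("/", s, fixed = TRUE)) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed fraction: ", s)
    return(rat_div(rat_parse(parts[1]), rat_parse(parts[2])))
  }
  if (!grepl("^[+-]?[0-9]*\\.?[0-9]+$", s))
    stop("malformed numeric literal: ", s)
  neg <- startsWith(s, "-")
  s2 <- sub("^[+-]", "", s)
  dot <- regexpr(".", s2, fixed = TRUE)
  if (dot < 0) {
    v <- rat(as.numeric(s2), 1)
  } else {
    intpart <- substr(s2, 1, dot - 1)
    frac <- substr(s2, dot + 1, nchar(s2))
    num <- as.numeric(paste0(if (nzchar(intpart)) intpart else "0", frac))
    v <- rat(num, 10^nchar(frac))
  }
  if (neg) rat_neg(v) else v
}

#' Render a rational as a string
#'
#' Rationals with a denominator of the form 2^a 5^b are rendered as exact
#' decimals; all others as \code{"num/den"} fractions. \code{rat_parse()}
#' reads both forms back exactly.
#'
#' @param a a rational.
#' @return a character scalar.
#' @export
rat_format <- function(a) {
  num <- a[1]; den <- a[2]
  d <- den; e2 <- 0; e5 <- 0
  while (d %% 2 == 0) { d <- d / 2; e2 <- e2 + 1 }
  while (d %% 5 == 0) { d <- d / 5; e5 <- e5 + 1 }
  if (d != 1) return(paste0(num, "/", den))
  ## scale to denominator 10^k
  k <- max(e2, e5)
  scaled <- abs(num) * 2^(k - e2) * 5^(k - e5)
  if (scaled >= .RAT_MAX) return(paste0(num, "/", den))
  s <- sprintf("%.0f", scaled)
  if (k > 0) {
    if (nchar(s) <= k) s <- paste0(strrep("0", k - nchar(s) + 1), s)
    s <- paste0(substr(s, 1, nchar(s) - k), ".", substr(s, nchar(s) - k + 1, nchar(s)))
  }
  if (num < 0) s <- paste0("-", s)
  s
}

rat_to_double <- function(a) a[1] / a[2]

## Sum a list of rationals.
rat_sum <- function(lst) {
  acc <- RAT0
  for (x in lst) acc <- rat_add(acc, x)
  acc
}
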