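# Exact nonnegative big integers as little-endian limb vectors, base 2^15.
# The base keeps every intermediate of schoolbook multiplication below 2^53,
# so plain doubles hold each limb product exactly.  Only the handful of
# operations the composition counts need are provided.

BN_BASE <- 32768

#' Construct a big integer
#'
#' Exact arbitrary-precision nonnegative integers used for the composition
#' counts, whose closed form mixes terms far beyond double precision.
#'
#' @param x a single nonnegative integer-valued number below 2^53.
#' @return an object of class `bigint`.
#' @examples
#' bn(12)
#' bn_mul(bn_choose(50, 25), bn(3))
#' @export
bn <- function(x) {
  stopifnot(length(x) == 1, !is.na(x), x >= 0, x == floor(x), x < 2^53)
  v <- numeric(0)
  repeat {
    v <- c(v, x %% BN_BASE)
    x <- x %/% BN_BASE
    if (x == 0) break
  }
  structure(v, class = "bigint")
}

bn_norm <- function(v) {
  v <- unclass(v)
  i <- 1L
  # carry propagation (limbs may temporarily exceed the base)
  while (i <= length(v)) {
    if (v[i] >= BN_BASE) {
      carry <- v[i] %/% BN_BASE
      v[i] <- v[i] %% BN_BASE
      if (i == length(v)) v <- c(v, 0)
      v[i + 1L] <- v[i + 1L] + carry
    }
    i <- i + 1L
  }
  while (length(v) > 1L && v[length(v)] == 0) v <- v[-length(v)]
  structure(v, class = "bigint")
}

bn_is_zero <- function(a) length(unclass(a)) == 1L && unclass(a)[1L] == 0

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint> ", bn_dec(x), " (", bn_bits(x), " bits)\n", sep = "")
  invisible(x)
}

#' Add, subtract, compare and multiply big integers
#'
#' @param a,b `bigint` objects (for `bn_sub`, `a >= b` is required).
#' @return `bn_add`, `bn_sub`, `bn_mul`: a `bigint`; `bn_cmp`: -1, 0 or 1.
#' @rdname bigint-arith
#' @export
bn_add <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  n <- max(length(a), length(b))
  length(a) <- n; length(b) <- n
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  bn_norm(a + b)
}

#' @rdname bigint-arith
#' @export
bn_cmp <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0L
}

#' @rdname bigint-arith
#' @export
bn_sub <- function(a, b) {
  if (bn_cmp(a, b) < 0) stop("bn_sub: negative result")
  a <- unclass(a); b <- unclass(b)
  length(b) <- length(a)
  b[is.na(b)] <- 0
  d <- a - b
  for (i in seq_along(d)) {
    if (d[i] < 0) {
      d[i] <- d[i] + BN_BASE
      d[i + 1L] <- d[i + 1L] - 1
    }
  }
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  structure(d, class = "bigint")
}

#' @rdname bigint-arith
#' @export
bn_mul <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if ((length(a) == 1 && a[1] == 0) || (length(b) == 1 && b[1] == 0)) return(bn(0))
  if (length(b) > length(a)) { tmp <- a; a <- b; b <- tmp }
  res <- numeric(length(a) + length(b))
  for (i in seq_along(b)) {
    if (b[i] == 0) next
    idx <- i:(i + length(a) - 1L)
    res[idx] <- res[idx] + a * b[i]
    # keep partial sums below 2^53: base^2 * nlimbs margin is ample for the
    # sizes used here (< 200 limbs), but normalise periodically to be safe
    if (i %% 64L == 0L) res <- unclass(bn_norm_keep(res))
  }
  bn_norm(res)
}

# normalise without stripping length (internal helper for bn_mul)
bn_norm_keep <- function(v) {
  carry <- 0
  for (i in seq_along(v)) {
    v[i] <- v[i] + carry
    carry <- v[i] %/% BN_BASE
    v[i] <- v[i] %% BN_BASE
  }
  while (carry > 0) {
    v <- c(v, carry %% BN_BASE)
    carry <- carry %/% BN_BASE
  }
  v
}

#' Multiply or divide a big integer by a small integer
#'
#' @param a a `bigint`.
#' @param m a nonnegative integer below 2^22.
#' @param d a positive integer below 2^31.
#' @return `bn_mul_small`: a `bigint`; `bn_divmod_small`: list with `q`
#'   (`bigint` quotient) and `r` (numeric remainder).
#' @rdname bigint-small
#' @export
bn_mul_small <- function(a, m) {
  stopifnot(m >= 0, m < 2^22)
  if (m == 0) return(bn(0))
  bn_norm(unclass(a) * m)
}

#' @rdname bigint-small
#' @export
bn_divmod_small <- function(a, d) {
  stopifnot(d >= 1, d < 2^31) # remainder * base stays well below 2^53
  v <- unclass(a)
  q <- numeric(length(v))
  r <- 0
  for (i in rev(seq_along(v))) {
    cur <- r * BN_BASE + v[i]
    q[i] <- cur %/% d
    r <- cur %% d
  }
  while (length(q) > 1L && q[length(q)] == 0) q <- q[-length(q)]
  list(q = structure(q, class = "bigint"), r = r)
}

#' Exact binomial coefficient as a big integer
#'
#' @param n,k nonnegative integers, `k <= n` (otherwise the result is 0).
#' @return a `bigint` equal to choose(n, k).
#' @export
bn_choose <- function(n, k) {
  if (k < 0 || k > n) return(bn(0))
  k <- min(k, n - k)
  res <- bn(1)
  if (k == 0) return(res)
  for (i in seq_len(k)) {
    res <- bn_mul_small(res, n - k + i)
    res <- bn_divmod_small(res, i)$q # exact at every step
  }
  res
}

#' Size and conversion helpers for big integers
#'
#' `bn_bits` is the bit length (`floor(log2(x)) + 1`, 0 for zero);
#' `bn_double` the closest double (`Inf` on overflow); `bn_ratio` the
#' double-precision value of `a/b`; `bn_dec` the exact decimal string.
#'
#' @param a,b `bigint` objects (`b` nonzero for `bn_ratio`).
#' @rdname bigint-convert
#' @export
bn_bits <- function(a) {
  v <- unclass(a)
  top <- v[length(v)]
  if (top == 0) return(0L)
  as.integer((length(v) - 1L) * 15L + floor(log2(top)) + 1)
}

#' @rdname bigint-convert
#' @export
bn_double <- function(a) {
  v <- unclass(a)
  x <- 0
  for (i in rev(seq_along(v))) x <- x * BN_BASE + v[i]
  x
}

#' @rdname bigint-convert
#' @export
bn_ratio <- function(a, b) {
  if (bn_is_zero(b)) stop("division by zero")
  if (bn_is_zero(a)) return(0)
  va <- unclass(a); vb <- unclass(b)
  k <- 5L # top limbs carry > 60 significant bits
  ta <- tail(va, k); tb <- tail(vb, k)
  da <- 0; for (i in rev(seq_along(ta))) da <- da * BN_BASE + ta[i]
  db <- 0; for (i in rev(seq_along(tb))) db <- db * BN_BASE + tb[i]
  ea <- max(length(va) - k, 0L); eb <- max(length(vb) - k, 0L)
  (da / db) * 2^(15 * (ea - eb))
}

#' @rdname bigint-convert
#' @export
bn_dec <- function(a) {
  if (bn_is_zero(a)) return("0")
  chunks <- character(0)
  while (!bn_is_zero(a)) {
    dm <- bn_divmod_small(a, 1e7)
    chunks <- c(chunks, formatC(dm$r, width = 7, flag = "0", format = "d"))
    a <- dm$q
  }
  chunks[length(chunks)] <- sub("^0+", "", chunks[length(chunks)])
  paste(rev(chunks), collapse = "")
}

#' @rdname bigint-arith
#' @export
bn_eq <- function(a, b) bn_cmp(a, b) == 0L

# Signed accumulator for alternating sums: list(sign, mag).
bn_signed_add <- function(acc, sign, mag) {
  if (bn_is_zero(mag)) return(acc)
  if (bn_is_zero(acc$mag)) return(list(sign = sign, mag = mag))
  if (acc$sign == sign) return(list(sign = sign, mag = bn_add(acc$mag, mag)))
  cmp <- bn_cmp(acc$mag, mag)
  if (cmp == 0) return(list(sign = 1L, mag = bn(0)))
  if (cmp > 0) list(sign = acc$sign, mag = bn_sub(acc$mag, mag))
  else list(sign = sign, mag = bn_sub(mag, acc$mag))
}
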