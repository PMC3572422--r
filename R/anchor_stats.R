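# Combinatorics of anchors in error-corrupted reads.
#
# A read of length L with M single-base errors is split into M+1 parts; the
# part sizes form a strict composition of L+1 into M+1 positive parts.
# Parts of size > K are anchors (error-free words of length >= K).
# c_{M,N,K}(L) counts error placements yielding exactly N anchors.

#' Waiting length until an anchor-length error-free word appears
#'
#' Under the geometric run model (each base errs independently with
#' probability `rho`), computes the number of error-free words `t` that must
#' be sequenced so that with probability `1 - epsilon` at least one has
#' length `>= K`, and the expected number of bases those `t` words span
#' (each word is followed by one erroneous base).
#'
#' @param rho per-base error rate, strictly inside (0, 1).
#' @param K minimum anchor length (integer, >= 1).
#' @param epsilon allowed failure probability, inside (0, 1).
#' @return list with `t` (words) and `bases` (expected bases).
#' @examples
#' waiting_length(0.15, 15, 0.05)
#' @export
waiting_length <- function(rho, K, epsilon = 0.05) {
  stopifnot(K >= 1, epsilon > 0, epsilon < 1)
  if (rho <= 0 || rho >= 1) stop("rho must be strictly inside (0, 1)")
  pK <- (1 - rho)^K
  t <- log(epsilon) / log(1 - pK)
  bases <- t * (1 / rho - K * pK / (1 - pK))
  list(t = t, bases = bases)
}

#' Geometric model of error-free run lengths
#'
#' With per-base error rate `rho`, the length W of an error-free run
#' satisfies Pr(W >= K) = (1 - rho)^K, with mean run length 1/rho - 1.
#' `mean_run_length` returns that mean; `prun_length` the probability that a
#' run has length at most `l` when the per-base success probability is `p`
#' (i.e. 1 - p^(l + 1)).
#'
#' @param rho per-base error rate in (0, 1).
#' @param l run length (vector allowed).
#' @param p per-base success probability (e.g. `1 - rho`, or a fitted
#'   geometric parameter).
#' @rdname run-model
#' @export
mean_run_length <- function(rho) {
  stopifnot(rho > 0, rho < 1)
  1 / rho - 1
}

#' @rdname run-model
#' @export
prun_length <- function(l, p) {
  stopifnot(p > 0, p < 1, all(l >= 0))
  1 - p^(l + 1)
}

#' Validate a composition query
#'
#' Derived quantities for counting compositions of `L + 1` into `M + 1`
#' parts with `N` anchors (parts exceeding `K`): `D = L - N*K - M` and
#' `imax = min(ceiling(D / K), M + 1 - N)` (for `K >= 1`).
#'
#' @param M number of errors (0 <= M <= L).
#' @param N number of anchors (0 <= N <= M + 1).
#' @param K anchor threshold: parts of size > K are anchors.
#' @param L read length.
#' @return list `(M, N, K, L, D, imax)`.
#' @export
composition_query <- function(M, N, K, L) {
  stopifnot(L >= 1, M >= 0, M <= L, N >= 0, N <= M + 1, K >= 0)
  D <- L - N * K - M
  imax <- if (K >= 1) min(ceiling(D / K), M + 1 - N) else NA_integer_
  list(M = M, N = N, K = K, L = L, D = D, imax = imax)
}

# truncated polynomial product; a, b indexed by degree 0..maxdeg
polymul_trunc <- function(a, b, maxdeg) {
  res <- numeric(maxdeg + 1)
  nz <- which(a != 0)
  for (i in nz) {
    d <- i - 1L
    jmax <- maxdeg - d + 1L
    if (jmax < 1L) next
    idx <- seq_len(min(jmax, length(b)))
    res[d + idx] <- res[d + idx] + a[i] * b[idx]
  }
  res
}

polypow_trunc <- function(a, n, maxdeg) {
  res <- c(1, numeric(maxdeg))
  while (n > 0) {
    if (n %% 2 == 1) res <- polymul_trunc(res, a, maxdeg)
    a <- polymul_trunc(a, a, maxdeg)
    n <- n %/% 2
  }
  res
}

#' Composition counts by truncated polynomial multiplication
#'
#' Computes `c_{M,N,K}(L)`, the number of placements of `M` errors in a
#' length-`L` read yielding exactly `N` anchors, as the coefficient of
#' `t^(L+1)` in `choose(M+1, N) * A(t)^N * S(t)^(M+1-N)` with
#' `S(t) = t + ... + t^K` (short parts) and `A(t) = t^(K+1) + t^(K+2) + ...`
#' (anchors), truncating every intermediate at degree `L + 1`.  All
#' intermediates are nonnegative and bounded by `choose(L, M)`, so exact
#' double-precision integers suffice whenever `choose(L, M) < 2^53`; larger
#' problems must use [compositions_closed()].
#'
#' @inheritParams composition_query
#' @return the exact count as a double.
#' @examples
#' compositions_poly(2, 1, 3, 7) # 18
#' @export
compositions_poly <- function(M, N, K, L) {
  q <- composition_query(M, N, K, L)
  if (choose(L, M) >= 2^53)
    stop("choose(L, M) exceeds exact double range; use compositions_closed()")
  maxdeg <- L + 1L
  S <- numeric(maxdeg + 1)
  if (K >= 1) {
    dmax <- min(K, maxdeg)
    S[1 + seq_len(dmax)] <- 1 # degrees 1..K
  }
  A <- numeric(maxdeg + 1)
  if (K + 1 <= maxdeg) A[(K + 2):(maxdeg + 1)] <- 1 # degrees K+1..L+1
  p <- polymul_trunc(polypow_trunc(A, N, maxdeg),
                     polypow_trunc(S, M + 1 - N, maxdeg), maxdeg)
  choose(M + 1, N) * p[maxdeg + 1]
}

#' Composition counts by the exact closed form
#'
#' Evaluates the alternating closed form
#' `c_{M,N,K}(L) = choose(M+1, N) * sum_{i=0}^{imax} (-1)^i
#' choose(M+1-N, i) * choose(M+D-i*K, M)` in exact big-integer arithmetic
#' (the alternating terms vastly exceed the result in magnitude, so fixed
#' precision would lose all significant digits).  For `K = 0` every part is
#' an anchor and the count is `choose(L, M)` when `N = M + 1`, else 0.
#'
#' @inheritParams composition_query
#' @param diagnostics if `TRUE`, also report, over the unprefixed terms
#'   `choose(M+1-N, i) * choose(M+D-i*K, M)`, how many are nonzero and the
#'   bit lengths of the extreme terms and of the absolute sum.
#' @return a [bn()] big integer, or (with `diagnostics`) a list with
#'   `count` (`bigint`), `n_terms`, `n_nonzero`, `max_term_bits`,
#'   `min_term_bits`, `sum_bits`.
#' @examples
#' bn_double(compositions_closed(2, 1, 3, 7)) # 18
#' @export
compositions_closed <- function(M, N, K, L, diagnostics = FALSE) {
  q <- composition_query(M, N, K, L)
  empty <- list(count = bn(0), n_terms = 0L, n_nonzero = 0L,
                max_term_bits = NA_integer_, min_term_bits = NA_integer_,
                sum_bits = 0L)
  if (K == 0) {
    cnt <- if (N == M + 1) bn_choose(L, M) else bn(0)
    if (!diagnostics) return(cnt)
    empty$count <- cnt
    return(empty)
  }
  D <- q$D; imax <- q$imax
  if (D < 0 || imax < 0) {
    if (!diagnostics) return(bn(0))
    return(empty)
  }
  acc <- list(sign = 1L, mag = bn(0))
  b1 <- bn(1) # choose(M+1-N, i), updated incrementally
  n_nonzero <- 0L
  max_bits <- 0L
  min_bits <- NA_integer_
  for (i in 0:imax) {
    if (i > 0) {
      b1 <- bn_divmod_small(bn_mul_small(b1, M + 1 - N - i + 1), i)$q
    }
    b2 <- bn_choose(M + D - i * K, M)
    term <- bn_mul(b1, b2)
    if (!bn_is_zero(term)) {
      n_nonzero <- n_nonzero + 1L
      bits <- bn_bits(term)
      max_bits <- max(max_bits, bits)
      min_bits <- if (is.na(min_bits)) bits else min(min_bits, bits)
    }
    acc <- bn_signed_add(acc, if (i %% 2 == 0) 1L else -1L, term)
  }
  if (acc$sign < 0 && !bn_is_zero(acc$mag))
    stop("internal error: negative composition count")
  cnt <- bn_mul(bn_choose(M + 1, N), acc$mag)
  if (!diagnostics) return(cnt)
  list(count = cnt, n_terms = imax + 1L, n_nonzero = n_nonzero,
       max_term_bits = max_bits, min_term_bits = min_bits,
       sum_bits = bn_bits(acc$mag))
}

#' Number of configurations with at least N anchors
#'
#' Suffix sum of the exact composition counts over `N' = N .. M + 1`, and
#' the corresponding probability under uniformly random error placements
#' (total `choose(L, M)`).
#'
#' @inheritParams composition_query
#' @return list with `count` (`bigint`) and `probability` (double in
#'   `[0, 1]`).
#' @examples
#' num_configurations(2, 1, 3, 7) # count 18, probability 18/21
#' @export
num_configurations <- function(M, N, K, L) {
  total <- bn(0)
  for (Np in N:(M + 1)) total <- bn_add(total, compositions_closed(M, Np, K, L))
  tot <- bn_choose(L, M)
  p <- if (bn_is_zero(total)) 0 else bn_ratio(total, tot)
  list(count = total, probability = min(max(p, 0), 1))
}

#' Mean and variance of the number of anchors
#'
#' Under the uniform distribution on compositions of `L + 1` into `M + 1`
#' parts: `mu = (M+1) choose(L-K, M) / choose(L, M)` and
#' `sigma2 = M(M+1) choose(L-2K, M)/choose(L, M) + mu - mu^2`, evaluated
#' from exact integer binomials before conversion to double.
#'
#' @inheritParams composition_query
#' @return list with `mu` and `sigma2`.
#' @examples
#' composition_moments(2, 3, 7) # mu = 6/7, sigma2 = 6/49
#' @export
composition_moments <- function(M, K, L) {
  stopifnot(L >= 1, M >= 0, M <= L, K >= 0)
  tot <- bn_choose(L, M)
  mu <- (M + 1) * bn_ratio_or_zero(bn_choose(L - K, M), tot)
  ex2f <- M * (M + 1) * bn_ratio_or_zero(bn_choose(L - 2 * K, M), tot)
  sigma2 <- ex2f + mu - mu^2
  list(mu = mu, sigma2 = max(sigma2, 0))
}

bn_ratio_or_zero <- function(a, b) if (bn_is_zero(a)) 0 else bn_ratio(a, b)

#' Normal approximation to the anchor-count distribution
#'
#' Central-limit approximation for large `M`: the pmf of the number of
#' anchors is approximated by the normal density with the exact moments,
#' and the survival function (probability of at least `N` anchors) by the
#' normal survival with a -1/2 continuity correction.  Values are on the
#' probability scale; multiply by `choose(L, M)` for counts.
#'
#' @inheritParams composition_query
#' @param N vector of anchor counts.
#' @return data.frame with columns `N`, `pmf`, `survival`.
#' @export
normal_approx <- function(M, N, K, L) {
  mom <- composition_moments(M, K, L)
  if (mom$sigma2 <= 0) {
    pmf <- as.numeric(N == round(mom$mu))
    surv <- as.numeric(N <= round(mom$mu))
    return(data.frame(N = N, pmf = pmf, survival = surv))
  }
  s <- sqrt(mom$sigma2)
  data.frame(N = N,
             pmf = dnorm((N - mom$mu) / s) / s,
             survival = 1 - pnorm((N - 0.5 - mom$mu) / s))
}

#' Exhaustive distribution of the number of anchors
#'
#' Test oracle: enumerates every placement of `M` errors in `L` positions,
#' counts the maximal error-free runs of length `>= K` in each, and returns
#' the histogram over `N = 0 .. M + 1`.
#'
#' @inheritParams composition_query
#' @param budget maximum `choose(L, M)` allowed (default 1e6).
#' @return named integer vector of counts, names `0 .. M + 1`.
#' @examples
#' enumerate_anchor_counts(2, 3, 7) # N = 0: 3, N = 1: 18
#' @export
enumerate_anchor_counts <- function(M, K, L, budget = 1e6) {
  stopifnot(L >= 1, M >= 0, M <= L)
  if (choose(L, M) > budget) stop("enumeration budget exceeded")
  counts <- integer(M + 2)
  names(counts) <- 0:(M + 1)
  if (M == 0) {
    counts[as.character(as.integer(L >= K))] <- 1L
    return(counts)
  }
  combos <- utils::combn(L, M)
  # part sizes are the gaps between consecutive error positions
  # (with x_0 = 0, x_{M+1} = L + 1); a part > K is an anchor
  parts <- rbind(combos, L + 1) - rbind(0, combos)
  n_anchors <- colSums(parts > K)
  tab <- table(n_anchors)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Compositions with all anchors first
#'
#' Enumerates the compositions of `L + 1` into `M + 1` positive parts whose
#' first `N` parts exceed `K` (anchors) and whose remaining parts are at
#' most `K`; their number is `c'_{M,N,K}(L) = c_{M,N,K}(L) / choose(M+1,N)`.
#'
#' @inheritParams composition_query
#' @return matrix with `M + 1` columns, one composition per row.
#' @examples
#' anchors_first_compositions(2, 1, 3, 7)
#' @export
anchors_first_compositions <- function(M, N, K, L) {
  q <- composition_query(M, N, K, L)
  nparts <- M + 1
  out <- list()
  rec <- function(prefix, remaining, idx) {
    if (idx > nparts) {
      if (remaining == 0) out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    lo <- if (idx <= N) K + 1 else 1
    hi <- if (idx <= N) remaining else min(K, remaining)
    if (hi < lo) return(invisible())
    for (v in lo:hi) rec(c(prefix, v), remaining - v, idx + 1)
  }
  rec(integer(0), L + 1, 1)
  if (length(out) == 0) return(matrix(integer(0), ncol = nparts))
  do.call(rbind, out)
}
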