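# Mapping quality: posterior probability of the best candidate location,
# with significance-based scaling of the denominator for repetitive reads.

#' Moments of total anchor bases under the composition model
#'
#' For a read of length `L` sequenced at the given accuracy, the number of
#' errors is `M = round((1 - accuracy) * L)` and the total anchor bases
#' (sum of error-free bases over all parts exceeding `K`) has mean
#' `(M+1) * sum_{v > K} (v - 1) * choose(L - v, M - 1) / choose(L, M)`
#' (computed from the exact part-size distribution) and a variance
#' estimated by seeded Monte Carlo over uniformly random compositions.
#' The result is genome-independent.
#'
#' @param lengths vector of read lengths (one bin each).
#' @param accuracies vector of accuracies in `[0.6, 1]` (one bin each).
#' @param K minimum anchor length.
#' @param seed integer seed for the Monte Carlo variance.
#' @param n_mc Monte Carlo draws per bin (default 1e4).
#' @return object of class `anchor_bases_moments`: arrays `mean` and `var`
#'   indexed `[length bin, accuracy bin]`, plus the bin values.
#' @export
anchor_bases_moments <- function(lengths, accuracies, K, seed = 1L,
                                 n_mc = 1e4) {
  mean_arr <- matrix(0, length(lengths), length(accuracies))
  var_arr <- matrix(0, length(lengths), length(accuracies))
  for (li in seq_along(lengths)) {
    for (ai in seq_along(accuracies)) {
      mom <- anchor_bases_bin(lengths[li], accuracies[ai], K,
                              seed + 1000L * li + ai, n_mc)
      mean_arr[li, ai] <- mom$mean
      var_arr[li, ai] <- mom$var
    }
  }
  structure(list(mean = mean_arr, var = var_arr, lengths = lengths,
                 accuracies = accuracies, K = K),
            class = "anchor_bases_moments")
}

anchor_bases_bin <- function(L, acc, K, seed, n_mc) {
  M <- round((1 - acc) * L)
  if (M >= L) return(list(mean = 0, var = 0))
  if (M == 0) {
    ab <- if (L >= K) L else 0 # single part of size L + 1
    return(list(mean = ab, var = 0))
  }
  # exact mean from the marginal part-size distribution; parts larger than
  # L - M + 1 are impossible (the other M parts need one base each)
  mean_ab <- 0
  if (L - M + 1 > K) {
    v <- (K + 1):(L - M + 1)
    mean_ab <- (M + 1) *
      sum((v - 1) * exp(lchoose(L - v, M - 1) - lchoose(L, M)))
  }
  # Monte Carlo variance over uniform compositions
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  ab <- vapply(seq_len(n_mc), function(i) {
    errs <- sort.int(sample.int(L, M))
    parts <- diff(c(0L, errs, L + 1L))
    sum(parts[parts > K] - 1L)
  }, 0)
  list(mean = mean_ab, var = stats::var(ab))
}

# Lazily-filled per-bin cache used by the mapper: length binned to powers
# of two, accuracy to steps of 0.01 within [0.6, 1].
moments_cache <- function(K, seed = 1L, n_mc = 1e4) {
  env <- new.env(parent = emptyenv())
  lookup <- function(L, acc) {
    Lb <- 2^max(5, round(log2(max(L, 1))))
    ab <- min(max(round(acc, 2), 0.6), 1)
    key <- paste0(Lb, "_", format(ab, nsmall = 2))
    if (is.null(env[[key]])) {
      env[[key]] <- anchor_bases_bin(Lb, ab, K,
                                     seed + round(Lb + 1000 * ab), n_mc)
    }
    env[[key]]
  }
  structure(list(lookup = lookup, K = K), class = "moments_cache")
}

#' Count significant clusters
#'
#' A cluster is significant when its anchor bases exceed `mu - 2*sigma`,
#' where the moments come from the composition model at the read's length
#' bin and the best alignment's accuracy (matches / alignment columns),
#' used as a proxy for the read's true accuracy.
#'
#' @param anchor_bases numeric vector: anchor bases of all pre-truncation
#'   clusters.
#' @param L aligned read length.
#' @param accuracy best alignment's accuracy in `[0, 1]`.
#' @param table an `anchor_bases_moments` object or a `moments_cache`.
#' @return integer count of significant clusters.
#' @export
cluster_significance <- function(anchor_bases, L, accuracy, table) {
  mom <- lookup_moments(table, L, accuracy)
  thr <- mom$mean - 2 * sqrt(mom$var)
  sum(anchor_bases > thr)
}

lookup_moments <- function(table, L, accuracy) {
  if (inherits(table, "moments_cache")) return(table$lookup(L, accuracy))
  stopifnot(inherits(table, "anchor_bases_moments"))
  li <- which.min(abs(log(table$lengths) - log(max(L, 1))))
  ai <- which.min(abs(table$accuracies - accuracy))
  if (abs(table$lengths[li] - L) / max(L, 1) > 0.5)
    warning("no close length bin for L = ", L, "; using nearest")
  list(mean = table$mean[li, ai], var = table$var[li, ai])
}

#' Mapping quality from candidate alignment costs
#'
#' The probability of the read given a candidate interval is approximated
#' by the phred-scaled alignment cost, `Pr(r|g) ~ 10^(-cost / 10)`, with a
#' uniform location prior.  The posterior of the best candidate is its
#' probability over the sum across the (at most `max_candidates`)
#' candidates; when more than `max_candidates` significant clusters exist
#' the denominator is scaled by `nu = n_sig / max_candidates` to reflect
#' the truncated sample of locations.  `Q = round(-10*log10(1 -
#' posterior))`, capped at 254 (the cap also absorbs underflow of
#' `1 - posterior`).
#'
#' @param costs numeric vector of candidate phred costs (best candidate =
#'   smallest cost; must be nonempty and finite).
#' @param n_sig number of significant clusters (see
#'   [cluster_significance()]).
#' @param cfg a [mapper_config()].
#' @return list of class `mapqv_result`: `posterior`, `Q`, `n_sig`, `nu`.
#' @export
compute_mapqv <- function(costs, n_sig = 1L, cfg = mapper_config()) {
  stopifnot(length(costs) >= 1, all(is.finite(costs)))
  costs <- sort(costs)[seq_len(min(length(costs), cfg$max_candidates))]
  w <- 10^(-(costs - costs[1]) / 10) # relative likelihoods, best = 1
  nu <- if (n_sig > cfg$max_candidates) n_sig / cfg$max_candidates else 1
  posterior <- w[1] / (sum(w) * nu)
  q <- if (posterior >= 1 || (1 - posterior) < 1e-26) 254L
       else min(254L, as.integer(round(-10 * log10(1 - posterior))))
  structure(list(posterior = min(posterior, 1), Q = q,
                 n_sig = n_sig, nu = nu), class = "mapqv_result")
}
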