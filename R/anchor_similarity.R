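# Anchor similarity: the maximum number of fixed-length, non-overlapping,
# ordered anchors shared between two sequences, with gap-length ratios
# bounded by the indel rate.

#' Anchor similarity of two sequences
#'
#' Over all shared exact `K`-mers (one at position `a` in `seq1`, `a'` in
#' `seq2`), finds the longest chain ordered and non-overlapping in both
#' sequences (consecutive anchors at least `K` apart) such that every
#' consecutive pair `(a, b)` / `(a', b')` satisfies
#' `1 - delta <= (b - a) / (b' - a') <= 1 + delta`, and returns its length
#' `S` (the two sequences are then S-similar).  Computed by chaining
#' dynamic programming over the match set.
#'
#' @param seq1,seq2 nucleotide strings (or [seq_record()]s), each of length
#'   at least `K`.
#' @param K fixed anchor length (>= 1).
#' @param delta indel rate in `[0, 1)` bounding gap ratios.
#' @param max_matches guard on the size of the shared K-mer match set.
#' @return integer `S` (0 when no K-mer is shared).
#' @examples
#' anchor_similarity(strrep("ACGT", 15), strrep("ACGT", 15), K = 15)
#' @export
anchor_similarity <- function(seq1, seq2, K = 15, delta = 0.15,
                              max_matches = 1e5) {
  s1 <- if (inherits(seq1, "seq_record")) seq1$seq else toupper(seq1)
  s2 <- if (inherits(seq2, "seq_record")) seq2$seq else toupper(seq2)
  stopifnot(K >= 1, delta >= 0, delta < 1,
            nchar(s1) >= K, nchar(s2) >= K)
  m <- kmer_matches(s1, s2, K)
  if (nrow(m) > max_matches) stop("match set exceeds max_matches")
  n <- nrow(m)
  if (n == 0) return(0L)
  ord <- order(m$read_pos, m$ivl_pos)
  a <- m$read_pos[ord]
  b <- m$ivl_pos[ord]
  best <- rep(1L, n)
  for (i in seq_len(n)) {
    if (i == 1) next
    j <- seq_len(i - 1L)
    ga <- a[i] - a[j]
    gb <- b[i] - b[j]
    ok <- ga >= K & gb >= K &
      (ga / gb) >= (1 - delta) & (ga / gb) <= (1 + delta)
    if (any(ok)) best[i] <- 1L + max(best[j][ok])
  }
  max(best)
}

#' Pairwise anchor similarity between two sequence sets
#'
#' Desk-scale census: computes `S` for every pair from two lists of
#' records.
#'
#' @param set1,set2 lists of [seq_record()]s.
#' @inheritParams anchor_similarity
#' @return data.frame with `id1`, `id2`, `S`.
#' @export
similarity_table <- function(set1, set2, K = 15, delta = 0.15) {
  grid <- expand.grid(i = seq_along(set1), j = seq_along(set2))
  data.frame(
    id1 = vapply(set1[grid$i], function(r) r$id, ""),
    id2 = vapply(set2[grid$j], function(r) r$id, ""),
    S = mapply(function(i, j)
      anchor_similarity(set1[[i]], set2[[j]], K, delta), grid$i, grid$j))
}
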