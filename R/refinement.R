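# Cluster -> candidate genome interval -> sparse-dynamic-programming chain
# of short fixed-length matches inside the interval.

#' Candidate genome interval for a cluster
#'
#' The chained anchors rarely reach the read's ends, so the interval is
#' extended by `(1 + delta)` times the unanchored read flanks (`delta`
#' being the maximum insertion rate), rounded outward and clamped to the
#' reference:
#' `s = Genome(a_first) - (1 + delta) * Read(a_first)` and
#' `f = Genome(a_last) + l(a_last) + (1 + delta) * (R - Read(a_last) - l(a_last))`.
#'
#' @param cluster an `anchor_cluster`.
#' @param R read length.
#' @param G reference length (upper clamp).
#' @param cfg a [mapper_config()].
#' @return list of class `candidate_interval`: `s`, `f` (0-based
#'   half-open), `l_C = f - s`, `strand`, `cluster`.
#' @export
candidate_interval <- function(cluster, R, G, cfg = mapper_config()) {
  stopifnot(inherits(cluster, "anchor_cluster"))
  d <- 1 + cfg$delta
  af <- cluster$a_first; al <- cluster$a_last
  s <- floor(af$genome_pos - d * af$read_pos)
  f <- ceiling(al$genome_pos + al$length +
               d * (R - (al$read_pos + al$length)))
  s <- max(0, s)
  f <- min(G, f)
  structure(list(s = s, f = f, l_C = f - s, strand = cluster$strand,
                 cluster = cluster),
            class = "candidate_interval")
}

#' Sparse-dynamic-programming refinement
#'
#' Enumerates all exact matches of length `k_sdp` between the read and the
#' candidate interval sequence, then extracts a maximum-cardinality subset
#' strictly increasing in both coordinates (patience longest-increasing
#' chain, O(n log n)).  Ties among equal-cardinality chains are broken
#' toward small diagonal drift between consecutive matches.
#'
#' @param read a [seq_record()] (or plain sequence string).
#' @param interval_seq the interval's nucleotide sequence.
#' @param cfg a [mapper_config()].
#' @return data.frame (`read_pos`, `ivl_pos`; 0-based) — the chain, empty
#'   when there are no matches.
#' @export
sdp_refine <- function(read, interval_seq, cfg = mapper_config()) {
  rseq <- if (inherits(read, "seq_record")) read$seq else read
  k <- cfg$k_sdp
  if (nchar(interval_seq) < k || nchar(rseq) < k)
    return(data.frame(read_pos = integer(0), ivl_pos = integer(0)))
  m <- kmer_matches(rseq, interval_seq, k)
  if (nrow(m) == 0) return(m)
  lis_chain(m)
}

kmer_matches <- function(rseq, iseq, k) {
  ni <- nchar(iseq) - k + 1L
  nr <- nchar(rseq) - k + 1L
  ik <- substring(iseq, 1:ni, k:(ni + k - 1L))
  rk <- substring(rseq, 1:nr, k:(nr + k - 1L))
  pos_by_kmer <- split(0:(ni - 1L), ik)
  hit <- pos_by_kmer[rk]
  nhit <- lengths(hit)
  data.frame(read_pos = rep(0:(nr - 1L), nhit),
             ivl_pos = unlist(hit, use.names = FALSE))
}

# maximum-cardinality chain strictly increasing in both coordinates
lis_chain <- function(m) {
  ord <- order(m$read_pos, -m$ivl_pos)
  rp <- m$read_pos[ord]; ip <- m$ivl_pos[ord]
  n <- length(rp)
  tails <- integer(0)       # index (into ord'd vecs) of smallest tail per length
  pred <- integer(n)
  lenof <- integer(n)
  for (i in seq_len(n)) {
    # binary search: first pile whose tail ivl_pos >= ip[i]
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (ip[tails[mid]] >= ip[i]) hi <- mid else lo <- mid + 1L
    }
    lenof[i] <- lo
    pred[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  L <- length(tails)
  # reconstruct, preferring predecessors with small diagonal drift
  idx_by_len <- split(seq_len(n), lenof)
  cur <- tails[L]
  path <- cur
  for (len in rev(seq_len(L - 1L))) {
    cands <- idx_by_len[[as.character(len)]]
    cands <- cands[rp[cands] < rp[cur] & ip[cands] < ip[cur]]
    drift <- abs((ip[cur] - rp[cur]) - (ip[cands] - rp[cands]))
    cur <- cands[which.min(drift)]
    path <- c(cur, path)
  }
  data.frame(read_pos = rp[path], ivl_pos = ip[path])
}
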