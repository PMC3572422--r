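# Independent brute-force oracles used across the suite.

# lexicographic suffix sort by materialising all suffixes
naive_suffix_array <- function(text) {
  n <- nchar(text)
  sufs <- substring(text, 1:n, n)
  order(sufs, method = "radix") - 1L
}

# longest prefix of q occurring in text, with overlapping occurrences,
# by scanning every start position
naive_count_lcp <- function(text, q) {
  n <- nchar(text)
  for (l in seq(min(nchar(q), n), 1)) {
    pat <- substr(q, 1, l)
    starts <- which(vapply(0:(n - l), function(p)
      substr(text, p + 1, p + l) == pat, NA))
    if (length(starts) > 0)
      return(list(count = length(starts), lcp = l, hits = starts - 1L))
  }
  list(count = 0L, lcp = 0L, hits = integer(0))
}

# forward-strand anchors by direct enumeration: at each read position the
# longest match anywhere in the genome, shortened per the lcp rule
naive_anchors_fwd <- function(read, genome, K, shorten, max_count = Inf) {
  out <- NULL
  R <- nchar(read)
  for (i in 0:(R - K)) {
    res <- naive_count_lcp(genome, substr(read, i + 1, R))
    if (res$lcp < K) next
    el <- max(K, res$lcp - shorten)
    sub <- substr(read, i + 1, i + el)
    if (grepl("[^ACGT]", sub)) next
    res2 <- naive_count_lcp(genome, sub)
    if (res2$lcp < el || res2$count > max_count) next
    out <- rbind(out, data.frame(read_pos = i, genome_pos = res2$hits,
                                 length = el, freq = res2$count))
  }
  if (is.null(out)) data.frame(read_pos = integer(0), genome_pos = integer(0),
                               length = integer(0), freq = integer(0))
  else out[order(out$genome_pos, out$read_pos), , drop = FALSE]
}

# best chain (max total anchor bases, strictly increasing, non-overlapping)
# by enumeration over all subsets
brute_best_chain <- function(a) {
  m <- nrow(a)
  stopifnot(m <= 14)
  best <- 0
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(sel) == 0) next
    sel <- sel[order(a$genome_pos[sel], a$read_pos[sel])]
    ok <- TRUE
    if (length(sel) > 1) {
      for (t in 2:length(sel)) {
        p <- sel[t - 1]; q <- sel[t]
        if (a$read_pos[p] + a$length[p] > a$read_pos[q] ||
            a$genome_pos[p] + a$length[p] > a$genome_pos[q]) { ok <- FALSE; break }
      }
    }
    if (ok) best <- max(best, sum(a$length[sel]))
  }
  best
}

# quadratic longest chain strictly increasing in both coordinates
lis_oracle <- function(m) {
  n <- nrow(m)
  if (n == 0) return(0L)
  m <- m[order(m$read_pos, m$ivl_pos), , drop = FALSE]
  best <- rep(1L, n)
  for (i in seq_len(n)) {
    ok <- which(m$read_pos[seq_len(i - 1)] < m$read_pos[i] &
                m$ivl_pos[seq_len(i - 1)] < m$ivl_pos[i])
    if (length(ok)) best[i] <- 1L + max(best[ok])
  }
  max(best)
}

# full dynamic programming cost oracle, flat penalties, global in the read
# and free at both interval ends (vectorised per row; the within-row
# deletion recursion min_k (m_k + del*(j-k)) is a running minimum)
dp_cost_oracle <- function(rseq, iseq, mismatch = 20, ins = 15, del = 15) {
  r <- strsplit(rseq, "")[[1]]
  g <- strsplit(iseq, "")[[1]]
  R <- length(r); Lc <- length(g)
  prev <- numeric(Lc + 1) # row 0: free leading interval
  j <- 0:Lc
  for (i in seq_len(R)) {
    dc <- ifelse(r[i] == g, 0, mismatch)
    m <- c(prev[1] + ins,
           pmin(prev[2:(Lc + 1)] + ins, prev[1:Lc] + dc))
    cur <- del * j + cummin(m - del * j)
    prev <- cur
  }
  min(prev)
}

# slow cell-by-cell oracle honouring the quality-value recurrence
dp_cost_oracle_qv <- function(rseq, iseq, qv, mismatch_prior = 20,
                              deletion_prior = 15) {
  r <- strsplit(rseq, "")[[1]]
  g <- strsplit(iseq, "")[[1]]
  R <- length(r); Lc <- length(g)
  s <- matrix(Inf, R + 1, Lc + 1)
  s[1, ] <- 0
  for (i in seq_len(R)) {
    for (j in 0:Lc) {
      v <- s[i, j + 1] + qv$ins[i]
      if (j >= 1) {
        dc <- if (r[i] == g[j]) 0
              else if (qv$sub_alt[i] == g[j]) qv$sub[i]
              else mismatch_prior
        v <- min(v, s[i, j] + dc)
        hc <- if (j >= 2 && qv$del_alt[i] == g[j - 1]) qv$del[i]
              else deletion_prior
        v <- min(v, s[i + 1, j] + hc)
      }
      s[i + 1, j + 1] <- v
    }
  }
  min(s[R + 1, ])
}

# exhaustive anchor-similarity chain search over all match subsets
brute_similarity <- function(s1, s2, K, delta) {
  m <- anchoralign:::kmer_matches(s1, s2, K)
  n <- nrow(m)
  if (n == 0) return(0L)
  stopifnot(n <= 20)
  best <- 0L
  for (mask in 1:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sel <- sel[order(m$read_pos[sel])]
    ok <- TRUE
    if (length(sel) > 1) {
      for (t in 2:length(sel)) {
        ga <- m$read_pos[sel[t]] - m$read_pos[sel[t - 1]]
        gb <- m$ivl_pos[sel[t]] - m$ivl_pos[sel[t - 1]]
        if (ga < K || gb < K || ga / gb < 1 - delta || ga / gb > 1 + delta) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) best <- max(best, length(sel))
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
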