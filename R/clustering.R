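# Anchor clustering: read-length genome windows, maximum-anchor-bases
# global chaining inside each window, frequency-weighted ranking.

#' Chain anchors into clusters
#'
#' Anchors are sorted by genome then read position.  For every anchor a_i
#' the window A_i holds the anchors whose genome end lies within `R` bases
#' downstream of a_i's start; each distinct maximal window is chained
#' globally (maximising total anchor bases over chains strictly increasing
#' and non-overlapping in both read and genome), and duplicate or contained
#' chains are removed so each surviving cluster is maximal.  Strands are
#' never mixed within a cluster.
#'
#' @param anchors data.frame from [find_anchors()].
#' @param R read length.
#' @return list of `anchor_cluster` objects: `anchors` (data.frame),
#'   `anchor_bases`, `fw_score`, `strand`, `a_first`, `a_last`.
#' @export
cluster_anchors <- function(anchors, R) {
  if (is.null(anchors) || nrow(anchors) == 0) return(list())
  out <- list()
  for (st in unique(anchors$strand)) {
    a <- anchors[anchors$strand == st, , drop = FALSE]
    a <- a[order(a$genome_pos, a$read_pos), , drop = FALSE]
    ends <- a$genome_pos + a$length
    chains <- list()
    prev_last <- -1L
    for (i in seq_len(nrow(a))) {
      sel <- which(ends - a$genome_pos[i] >= 0 & ends - a$genome_pos[i] <= R)
      if (length(sel) == 0) next
      # windows whose membership is a subset of the previous window's
      # produce contained chains; only chain windows that add new anchors
      if (max(sel) <= prev_last) next
      prev_last <- max(sel)
      chains[[length(chains) + 1L]] <- chain_window(a[sel, , drop = FALSE])
    }
    chains <- dedupe_chains(chains)
    out <- c(out, chains)
  }
  out
}

# maximum-anchor-bases global chain within one window (O(m^2) DP)
chain_window <- function(a) {
  m <- nrow(a)
  ord <- order(a$genome_pos, a$read_pos)
  a <- a[ord, , drop = FALSE]
  best <- numeric(m)
  prev <- integer(m)
  for (k in seq_len(m)) {
    best[k] <- a$length[k]
    prev[k] <- 0L
    if (k > 1) {
      ok <- which(a$read_pos[1:(k - 1)] + a$length[1:(k - 1)] <= a$read_pos[k] &
                  a$genome_pos[1:(k - 1)] + a$length[1:(k - 1)] <= a$genome_pos[k])
      if (length(ok) > 0) {
        j <- ok[which.max(best[ok])]
        best[k] <- a$length[k] + best[j]
        prev[k] <- j
      }
    }
  }
  k <- which.max(best)
  path <- integer(0)
  while (k > 0) { path <- c(k, path); k <- prev[k] }
  chain <- a[path, , drop = FALSE]
  new_cluster(chain)
}

new_cluster <- function(chain) {
  structure(list(anchors = chain,
                 anchor_bases = sum(chain$length),
                 fw_score = sum(log(1 / chain$freq)),
                 strand = chain$strand[1],
                 a_first = chain[1, , drop = FALSE],
                 a_last = chain[nrow(chain), , drop = FALSE]),
            class = "anchor_cluster")
}

dedupe_chains <- function(chains) {
  if (length(chains) <= 1) return(chains)
  keys <- vapply(chains, function(cl)
    paste(cl$anchors$read_pos, cl$anchors$genome_pos, collapse = ";"), "")
  chains <- chains[!duplicated(keys)]
  # drop chains whose anchor set is contained in another chain's
  sets <- lapply(chains, function(cl)
    paste(cl$anchors$read_pos, cl$anchors$genome_pos))
  keep <- rep(TRUE, length(chains))
  for (i in seq_along(chains)) {
    for (j in seq_along(chains)) {
      if (i == j || !keep[j]) next
      if (length(sets[[i]]) < length(sets[[j]]) &&
          all(sets[[i]] %in% sets[[j]])) { keep[i] <- FALSE; break }
    }
  }
  chains[keep]
}

#' Rank clusters by frequency-weighted score
#'
#' Each cluster's score is `sum(log(1 / Freq(a)))` over its chained
#' anchors (0 for unique anchors, negative for repetitive ones).  Clusters
#' are sorted by descending score, ties broken by larger anchor bases then
#' smaller genome start, and at most `max_candidates` are returned with
#' ranks 1..n.  The pre-truncation anchor-bases of all clusters are kept in
#' the `"all_anchor_bases"` attribute for the significance count used by
#' mapping quality.
#'
#' @param clusters list from [cluster_anchors()].
#' @param cfg a [mapper_config()].
#' @param G genome length.  When supplied, anchor frequencies are taken
#'   relative to the genome (`sum(log(G / count))`, so that every anchor
#'   contributes positively and repetitive anchors contribute less); when
#'   `NULL`, raw occurrence counts are used (`sum(log(1 / count))`).
#'   Ranking against a genome should always supply `G`: under raw counts a
#'   large cluster containing one repeated anchor would rank below a
#'   trivial all-unique cluster, which defeats the score's purpose of
#'   discriminating dense clusters.
#' @return ranked, truncated list of clusters.
#' @export
rank_clusters <- function(clusters, cfg = mapper_config(), G = NULL) {
  if (length(clusters) == 0) return(clusters)
  fw <- vapply(clusters, function(cl) cl$fw_score, 0)
  if (!is.null(G)) {
    n_anchors <- vapply(clusters, function(cl) nrow(cl$anchors), 0)
    fw <- fw + n_anchors * log(G)
  }
  ab <- vapply(clusters, function(cl) cl$anchor_bases, 0)
  gs <- vapply(clusters, function(cl) cl$a_first$genome_pos, 0)
  ord <- order(-fw, -ab, gs)
  kept <- clusters[head(ord, cfg$max_candidates)]
  for (i in seq_along(kept)) kept[[i]]$rank <- i
  attr(kept, "n_total") <- length(clusters)
  attr(kept, "all_anchor_bases") <- ab
  kept
}
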