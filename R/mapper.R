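# End-to-end successive-refinement mapper: anchors -> clusters -> candidate
# intervals -> SDP chains -> guided banded alignment -> mapping quality.

#' Mapper configuration
#'
#' Tunable parameters with their field-standard defaults: minimum anchor
#' length `K = 12`; matches emitted `lcp_shorten = 1` base shorter than the
#' LCP; anchors occurring more than `max_count = 10000` times skipped; at
#' most `max_candidates = 10` clusters aligned in detail; maximum indel
#' rate `delta = 0.15` for interval flanks; SDP match length `k_sdp = 11`;
#' guide-band half width `b_sdp = 15`; phred penalties `mismatch_prior =
#' 20` and `deletion_prior = 15` (with flat fallbacks mismatch 20,
#' insertion 15, deletion 15 when no quality tracks are present).
#'
#' @param K,lcp_shorten,max_count,max_candidates,delta,k_sdp,b_sdp,mismatch_prior,deletion_prior,flat_ins,flat_del,flat_mismatch see description.
#' @param seed integer seed for the Monte Carlo in the anchor-bases moments.
#' @return list of class `mapper_config`.
#' @export
mapper_config <- function(K = 12, lcp_shorten = 1, max_count = 10000,
                          max_candidates = 10, delta = 0.15, k_sdp = 11,
                          b_sdp = 15, mismatch_prior = 20,
                          deletion_prior = 15, flat_ins = 15, flat_del = 15,
                          flat_mismatch = 20, seed = 1L) {
  stopifnot(K >= 1, lcp_shorten >= 0, max_count >= 1, max_candidates >= 1,
            delta >= 0, delta < 1, k_sdp >= 1, b_sdp >= 1)
  structure(list(K = K, lcp_shorten = lcp_shorten, max_count = max_count,
                 max_candidates = max_candidates, delta = delta,
                 k_sdp = k_sdp, b_sdp = b_sdp,
                 mismatch_prior = mismatch_prior,
                 deletion_prior = deletion_prior, flat_ins = flat_ins,
                 flat_del = flat_del, flat_mismatch = flat_mismatch,
                 seed = as.integer(seed)),
            class = "mapper_config")
}

#' Map reads to an indexed reference
#'
#' Runs the full successive-refinement pipeline for each read and fills in
#' mapping quality values.  Reads that produce no anchors, no cluster or no
#' complete alignment are reported unmapped.
#'
#' @param reads list of [seq_record()]s.
#' @param index a [build_index()] result (or reference [seq_record()]s,
#'   which are indexed on the fly).
#' @param cfg a [mapper_config()].
#' @param verbose report progress to stderr.
#' @return list of mapping results, one per read, in input order: each is a
#'   list with `read_id`, `mapped`, and for mapped reads `ref_id`,
#'   `strand`, `genome_start`, `genome_end` (0-based half-open on the
#'   forward reference), `cigar`, `cost`, `n_match`, `n_mismatch`,
#'   `n_ins`, `n_del`, `mapq`, `seq_out` (the sequence as aligned, reverse
#'   complemented for minus-strand hits).
#' @export
map_reads <- function(reads, index, cfg = mapper_config(), verbose = FALSE) {
  if (!inherits(index, "ref_index")) index <- build_index(index)
  moments <- moments_cache(cfg$K, seed = cfg$seed)
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    out[[i]] <- map_one(reads[[i]], index, cfg, moments)
    if (verbose && i %% 50 == 0)
      message("mapped ", i, "/", length(reads), " reads")
  }
  out
}

map_one <- function(read, index, cfg, moments) {
  unmapped <- list(read_id = read$id, mapped = FALSE, seq_out = read$seq)
  R <- nchar(read$seq)
  if (R < cfg$K) return(unmapped)
  anchors <- find_anchors(read, index, cfg)
  if (nrow(anchors) == 0) return(unmapped)
  clusters <- cluster_anchors(anchors, R)
  ranked <- rank_clusters(clusters, cfg, G = nchar(index$text))
  if (length(ranked) == 0) return(unmapped)
  all_ab <- attr(ranked, "all_anchor_bases")

  rc_read <- read_revcomp(read)
  cands <- list()
  for (cl in ranked) {
    seq_i <- text_to_ref(cl$a_first$genome_pos, index)$seq_index
    off <- index$offsets[seq_i]
    G_i <- index$lengths[seq_i]
    cl_local <- cl
    cl_local$a_first$genome_pos <- cl$a_first$genome_pos - off
    cl_local$a_last$genome_pos <- cl$a_last$genome_pos - off
    ci <- candidate_interval(cl_local, R, G_i, cfg)
    if (ci$l_C < cfg$k_sdp) next
    ivl <- substr(index$text, off + ci$s + 1L, off + ci$f)
    rd <- if (cl$strand == "-") rc_read else read
    chain <- sdp_refine(rd, ivl, cfg)
    if (nrow(chain) == 0) next
    band <- build_guide_band(chain, R, ci$l_C, cfg)
    aln <- banded_align(rd, ivl, band, cfg)
    if (is.null(aln)) next
    cands[[length(cands) + 1L]] <- list(
      aln = aln, ref_id = index$ids[seq_i], strand = cl$strand,
      start = ci$s + aln$g_start, end = ci$s + aln$g_end)
  }
  if (length(cands) == 0) return(unmapped)
  # candidates from overlapping windows describe the same location; keep
  # the cheapest of each overlapping group so Eq. 1's denominator counts
  # distinct locations
  cands <- dedupe_candidates(cands)
  costs <- vapply(cands, function(cd) cd$aln$cost, 0)
  best <- cands[[which.min(costs)]]
  cols <- with(best$aln, n_match + n_mismatch + n_ins + n_del)
  acc <- if (cols > 0) best$aln$n_match / cols else 0
  n_sig <- cluster_significance(all_ab, R, acc, moments)
  mq <- compute_mapqv(costs, n_sig, cfg)
  seq_out <- if (best$strand == "-") rc_read$seq else read$seq
  list(read_id = read$id, mapped = TRUE, ref_id = best$ref_id,
       strand = best$strand, genome_start = best$start,
       genome_end = best$end, cigar = best$aln$cigar,
       cost = best$aln$cost, n_match = best$aln$n_match,
       n_mismatch = best$aln$n_mismatch, n_ins = best$aln$n_ins,
       n_del = best$aln$n_del, mapq = mq$Q, posterior = mq$posterior,
       n_sig = mq$n_sig, n_candidates = length(cands), seq_out = seq_out)
}

read_revcomp <- function(read) {
  qv <- read$qv
  if (!is.null(qv)) {
    qv <- quality_arrays(rev(qv$ins), rev(qv$sub), rev(qv$del),
                         revcomp(rev(qv$sub_alt)), revcomp(rev(qv$del_alt)))
  }
  seq_record(read$id, revcomp(read$seq), qv)
}

dedupe_candidates <- function(cands) {
  if (length(cands) <= 1) return(cands)
  costs <- vapply(cands, function(cd) cd$aln$cost, 0)
  ord <- order(costs)
  kept <- list()
  for (i in ord) {
    cd <- cands[[i]]
    dup <- FALSE
    for (k in kept) {
      if (cd$ref_id != k$ref_id || cd$strand != k$strand) next
      ov <- min(cd$end, k$end) - max(cd$start, k$start)
      if (ov > 0.5 * min(cd$end - cd$start, k$end - k$start)) {
        dup <- TRUE; break
      }
    }
    if (!dup) kept[[length(kept) + 1L]] <- cd
  }
  kept
}
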