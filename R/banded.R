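# Final base-level alignment: dynamic programming restricted to a band that
# follows the SDP chain's diagonals, scored with per-base quality values
# (or flat penalties when no tracks are available).

#' Build the guide band around an SDP chain
#'
#' Rows (read positions) covered by a chain match get a band of half-width
#' `b_sdp` about that match's diagonal; rows between consecutive matches
#' get half-width `b_drift = |diagonal difference| + b_sdp` about the
#' midpoint diagonal; rows before the first and after the last match extend
#' the nearest diagonal.  The band is then widened minimally so both
#' endpoints are monotone non-decreasing and consecutive rows overlap or
#' are adjacent.  An empty chain yields the full rectangle.
#'
#' @param chain data.frame from [sdp_refine()] (may be empty).
#' @param R read length.
#' @param l_C interval length.
#' @param cfg a [mapper_config()].
#' @return matrix with `R` rows and columns `lo`, `hi`: admissible column
#'   range (0..l_C) for each read row 1..R.
#' @export
build_guide_band <- function(chain, R, l_C, cfg = mapper_config()) {
  if (is.null(chain) || nrow(chain) == 0) {
    return(cbind(lo = rep(0L, R), hi = rep(l_C, R)))
  }
  k <- cfg$k_sdp
  b <- cfg$b_sdp
  diag_ <- chain$ivl_pos - chain$read_pos
  lo_d <- rep(NA_real_, R)
  hi_d <- rep(NA_real_, R)
  # rows covered by matches
  for (t in seq_len(nrow(chain))) {
    rows <- (chain$read_pos[t] + 1L):min(chain$read_pos[t] + k, R)
    lo_d[rows] <- pmin(lo_d[rows], diag_[t] - b, na.rm = TRUE)
    hi_d[rows] <- pmax(hi_d[rows], diag_[t] + b, na.rm = TRUE)
  }
  # rows between consecutive matches
  if (nrow(chain) > 1) {
    for (t in seq_len(nrow(chain) - 1L)) {
      from <- chain$read_pos[t] + k + 1L
      to <- chain$read_pos[t + 1L]
      if (from > to) next
      drift <- abs(diag_[t + 1L] - diag_[t])
      mid <- (diag_[t] + diag_[t + 1L]) / 2
      rows <- from:to
      lo_d[rows] <- pmin(lo_d[rows], mid - (drift + b), na.rm = TRUE)
      hi_d[rows] <- pmax(hi_d[rows], mid + (drift + b), na.rm = TRUE)
    }
  }
  # flanks extend the nearest diagonal
  first_row <- chain$read_pos[1] + 1L
  last_row <- min(chain$read_pos[nrow(chain)] + k, R)
  if (first_row > 1) {
    rows <- 1:(first_row - 1L)
    lo_d[rows] <- diag_[1] - b
    hi_d[rows] <- diag_[1] + b
  }
  if (last_row < R) {
    rows <- (last_row + 1L):R
    lo_d[rows] <- ifelse(is.na(lo_d[rows]), diag_[nrow(chain)] - b, lo_d[rows])
    hi_d[rows] <- ifelse(is.na(hi_d[rows]), diag_[nrow(chain)] + b, hi_d[rows])
  }
  # interior rows not covered (short chains): interpolate nearest
  if (anyNA(lo_d)) {
    na <- which(is.na(lo_d))
    flt <- which(!is.na(lo_d))
    near <- flt[pmax(findInterval(na, flt), 1L)]
    lo_d[na] <- lo_d[near]; hi_d[na] <- hi_d[near]
  }
  i <- seq_len(R)
  lo <- floor(i + lo_d)
  hi <- ceiling(i + hi_d)
  lo <- pmax(pmin(lo, l_C), 0)
  hi <- pmin(pmax(hi, 0), l_C)
  # widen minimally: monotone endpoints, consecutive overlap
  hi <- cummax(hi)
  lo <- rev(cummin(rev(lo)))
  if (R > 1) {
    for (r in 2:R) if (lo[r] > hi[r - 1L] + 1L) lo[r] <- hi[r - 1L] + 1L
  }
  cbind(lo = as.integer(lo), hi = as.integer(hi))
}

#' Banded alignment with quality-value scoring
#'
#' Minimises total phred-scaled cost over paths inside the band.  Moves
#' into a cell: diagonal costs 0 on a base match, the substitution quality
#' `S_i` when the alternative substitution call matches the interval base,
#' and `MISMATCHPRIOR` otherwise; vertical (an inserted read base) costs
#' `I_i`; horizontal (a deleted interval base) costs `D_i` when the
#' alternative deleted call matches the preceding interval base and
#' `DELETIONPRIOR` otherwise.  Without quality tracks, flat penalties
#' (mismatch 20, insertion 15, deletion 15) substitute.  The alignment is
#' global in the read with free end gaps on the interval (its `(1+delta)`
#' flanks must not be charged); tie-breaking in the traceback prefers
#' diagonal, then deletion, then insertion.
#'
#' @param read a [seq_record()] (its `qv` tracks are used when present).
#' @param interval_seq interval nucleotide sequence.
#' @param band matrix from [build_guide_band()] (`NULL` for a full band).
#' @param cfg a [mapper_config()].
#' @return list of class `alignment_result`: `cost`, `cigar`, `g_start`,
#'   `g_end` (0-based, interval coordinates), `n_match`, `n_mismatch`,
#'   `n_ins`, `n_del`; or `NULL` when the band excludes every complete
#'   path even after one widening.
#' @export
banded_align <- function(read, interval_seq, band = NULL,
                         cfg = mapper_config()) {
  rseq <- if (inherits(read, "seq_record")) read$seq else read
  qv <- if (inherits(read, "seq_record")) read$qv else NULL
  R <- nchar(rseq)
  l_C <- nchar(interval_seq)
  if (is.null(band)) band <- cbind(lo = rep(0L, R), hi = rep(l_C, R))
  res <- run_banded(rseq, interval_seq, band, qv, cfg)
  if (is.null(res)) {
    # widen once, then give up (caller demotes the candidate)
    full <- cbind(lo = rep(0L, R), hi = rep(l_C, R))
    res <- run_banded(rseq, interval_seq, full, qv, cfg)
  }
  res
}

run_banded <- function(rseq, iseq, band, qv, cfg) {
  has_qv <- !is.null(qv)
  z <- numeric(0); zc <- ""
  out <- banded_dp_cpp(rseq, iseq, band[, "lo"], band[, "hi"],
                       if (has_qv) qv$ins else z,
                       if (has_qv) qv$sub else z,
                       if (has_qv) qv$del else z,
                       if (has_qv) paste(qv$sub_alt, collapse = "") else zc,
                       if (has_qv) paste(qv$del_alt, collapse = "") else zc,
                       has_qv,
                       cfg$mismatch_prior, cfg$deletion_prior,
                       cfg$flat_ins, cfg$flat_del, cfg$flat_mismatch)
  if (!isTRUE(out$ok)) return(NULL)
  structure(out[-1], class = "alignment_result")
}
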