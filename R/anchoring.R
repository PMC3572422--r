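# Anchor generation: exact matches of length >= K between read and genome,
# on both strands.

#' Find anchors between a read and an indexed genome
#'
#' For each read position the longest common prefix with the genome is
#' computed; matches are emitted 'lcp_shorten' bases shorter than the LCP
#' (never below `K`) at every located genome position, to avoid anchoring
#' through a base-call error at the LCP's end.  Positions whose match
#' occurs more than `max_count` times, or is shorter than `K`, or contains
#' an N, contribute nothing.  The scan is repeated on the reverse
#' complement of the read; minus-strand anchors carry coordinates on the
#' forward genome with `read_pos` expressed in the reverse-complemented
#' read.
#'
#' @param read a [seq_record()].
#' @param idx a [build_index()] result.
#' @param cfg a [mapper_config()].
#' @return data.frame with columns `read_pos`, `genome_pos` (both 0-based,
#'   in concatenated-text coordinates), `length`, `strand`, `freq`.
#' @export
find_anchors <- function(read, idx, cfg = mapper_config()) {
  stopifnot(inherits(read, "seq_record"), inherits(idx, "ref_index"))
  if (nchar(read$seq) < cfg$K) {
    message("read ", read$id, " shorter than K = ", cfg$K, "; skipped")
    return(empty_anchors())
  }
  fwd <- scan_anchors_cpp(idx$text, idx$sa, read$seq, cfg$K,
                          cfg$lcp_shorten, cfg$max_count)
  rev <- scan_anchors_cpp(idx$text, idx$sa, revcomp(read$seq), cfg$K,
                          cfg$lcp_shorten, cfg$max_count)
  rbind(anchor_frame(fwd, "+"), anchor_frame(rev, "-"))
}

empty_anchors <- function() {
  data.frame(read_pos = integer(0), genome_pos = integer(0),
             length = integer(0), strand = character(0), freq = integer(0))
}

anchor_frame <- function(m, strand) {
  if (nrow(m) == 0) return(empty_anchors())
  data.frame(read_pos = m[, "read_pos"], genome_pos = m[, "text_pos"],
             length = m[, "length"], strand = strand, freq = m[, "freq"])
}
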