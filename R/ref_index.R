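# Suffix-array index over the (concatenated) genome, answering
# count / locate / longest-common-prefix queries.

#' Build a suffix-array index over a genome
#'
#' Concatenates the reference sequences (separated by a sentinel byte so no
#' query can match across two sequences) and builds a suffix array by
#' prefix doubling.  Construction is deterministic.
#'
#' @param genome a single [seq_record()] or a list of them.
#' @return object of class `ref_index` with the concatenated `text`, the
#'   0-based suffix array `sa`, and per-sequence `ids`, `offsets`,
#'   `lengths`.
#' @examples
#' idx <- build_index(seq_record("chr", "ACGACGA"))
#' count_lcp("ACGT", idx)
#' @export
build_index <- function(genome) {
  if (inherits(genome, "seq_record")) genome <- list(genome)
  stopifnot(length(genome) >= 1)
  seqs <- vapply(genome, function(g) g$seq, "")
  ids <- vapply(genome, function(g) g$id, "")
  if (sum(nchar(seqs)) < 1) stop("empty genome")
  text <- paste(seqs, collapse = "#")
  offsets <- c(0, cumsum(nchar(seqs) + 1L))[seq_along(seqs)]
  idx <- structure(
    list(text = text, sa = sa_build_cpp(text), ids = ids,
         offsets = offsets, lengths = nchar(seqs)),
    class = "ref_index")
  idx
}

#' @export
print.ref_index <- function(x, ...) {
  cat("<ref_index> ", length(x$ids), " sequence(s), ",
      sum(x$lengths), " bases\n", sep = "")
  invisible(x)
}

#' Count/locate the longest common prefix of a query in the index
#'
#' Finds the length `l` of the longest prefix of `q` occurring in the
#' indexed text and its occurrence count `c`.  Matching positions are
#' returned only when `c <= max_hits`; otherwise they are withheld and only
#' the pair `(c, l)` is reported.  When even the first query base is absent
#' the result is `c = 0, l = 0`.
#'
#' @param q nonempty nucleotide query string.
#' @param idx a [build_index()] result.
#' @param max_hits cap on the number of positions to locate.
#' @return list with `count`, `lcp`, and `hits` (0-based positions in the
#'   concatenated text, sorted).
#' @export
count_lcp <- function(q, idx, max_hits = Inf) {
  stopifnot(inherits(idx, "ref_index"), nchar(q) >= 1)
  sa_count_lcp_cpp(idx$text, idx$sa, toupper(q), max_hits)
}

# map a 0-based position in the concatenated text to (ref id, local pos)
text_to_ref <- function(pos, idx) {
  i <- findInterval(pos, idx$offsets)
  list(ref = idx$ids[i], pos = pos - idx$offsets[i], seq_index = i)
}
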