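# Sequence input/output.  Reads are plain records (id, uppercase sequence,
# optional per-base quality tracks); alignments are emitted as SAM v1 text.
# Internal coordinates are 0-based half-open throughout the package; the
# single conversion to SAM's 1-based closed convention happens at emission.

#' Construct a sequence record
#'
#' @param id record identifier.
#' @param seq nucleotide string over A, C, G, T, N (uppercased).
#' @param qv optional quality tracks, see [quality_arrays()].
#' @return list of class `seq_record`.
#' @export
seq_record <- function(id, seq, qv = NULL) {
  seq <- toupper(seq)
  stopifnot(nchar(seq) >= 1)
  if (!is.null(qv)) {
    stopifnot(inherits(qv, "quality_arrays"),
              length(qv$ins) == nchar(seq))
  }
  structure(list(id = id, seq = seq, qv = qv), class = "seq_record")
}

#' Per-base quality tracks
#'
#' Phred-scaled insertion (`ins`), substitution (`sub`) and deletion
#' (`del`) quality values plus the alternative substitution (`sub_alt`) and
#' deletion (`del_alt`) base calls, one entry per read base.
#'
#' @param ins,sub,del integer phred vectors in `[0, 93]`.
#' @param sub_alt,del_alt character vectors of single bases.
#' @return list of class `quality_arrays`.
#' @export
quality_arrays <- function(ins, sub, del, sub_alt, del_alt) {
  n <- length(ins)
  stopifnot(length(sub) == n, length(del) == n,
            length(sub_alt) == n, length(del_alt) == n,
            all(ins >= 0 & ins <= 93), all(sub >= 0 & sub <= 93),
            all(del >= 0 & del <= 93))
  structure(list(ins = as.numeric(ins), sub = as.numeric(sub),
                 del = as.numeric(del), sub_alt = sub_alt,
                 del_alt = del_alt), class = "quality_arrays")
}

#' Read sequences from FASTA or FASTQ
#'
#' One record per entry, in file order, with sequences uppercased (N is
#' permitted).  FASTQ base qualities (Sanger phred+33) are stored as the
#' substitution track of a [quality_arrays()] with uninformative insertion
#' and deletion tracks, unless richer tracks are attached later via
#' [read_qv_table()].
#'
#' @param path file path.
#' @param format `"fasta"` or `"fastq"`; guessed from the extension when
#'   missing.
#' @return list of [seq_record()]s (empty for an empty file).
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (file.exists(path) && file.size(path) == 0) return(list())
  if (format == "fasta") {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    qual <- NULL
  } else {
    # metadata-column drop warnings from the quality container are benign
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    qual <- as.character(Biostrings::quality(x))
  }
  ids <- sub("\\s.*$", "", names(x))
  seqs <- unname(toupper(as.character(x)))
  lapply(seq_along(x), function(i) {
    qv <- NULL
    if (!is.null(qual)) {
      phred <- utf8ToInt(qual[i]) - 33L
      n <- length(phred)
      qv <- quality_arrays(ins = rep(0, n), sub = pmin(phred, 93),
                          del = rep(0, n), sub_alt = rep("N", n),
                          del_alt = rep("N", n))
    }
    seq_record(ids[i], seqs[i], qv)
  })
}

#' Read a sidecar quality-value table
#'
#' Tab-separated table with columns `id`, `I`, `S`, `D`, `Shat`, `Dhat`;
#' the numeric columns hold comma-separated per-base phred values and the
#' alternative-call columns comma-separated bases.  Tracks are attached to
#' the matching records by id.
#'
#' @param path table path.
#' @param reads list of [seq_record()]s to attach tracks to.
#' @return the read list with `qv` filled for matched ids.
#' @export
read_qv_table <- function(path, reads) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "I", "S", "D", "Shat", "Dhat")
  if (!all(need %in% names(tab)))
    stop("QV table must have columns: ", paste(need, collapse = ", "))
  split_num <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  split_chr <- function(s) strsplit(s, ",", fixed = TRUE)[[1]]
  byid <- stats::setNames(seq_len(nrow(tab)), tab$id)
  lapply(reads, function(r) {
    i <- byid[r$id]
    if (is.na(i)) return(r)
    qv <- quality_arrays(split_num(tab$I[i]), split_num(tab$S[i]),
                         split_num(tab$D[i]), split_chr(tab$Shat[i]),
                         split_chr(tab$Dhat[i]))
    if (length(qv$ins) != nchar(r$seq))
      stop("QV track length mismatch for read ", r$id)
    r$qv <- qv
    r
  })
}

#' Write alignments as SAM
#'
#' Emits a SAM v1 plain-text file: `@HD`, one `@SQ` per reference, then one
#' record per result.  Mapped records carry 1-based `POS`, a CIGAR over
#' M/I/D and `MAPQ = min(Q, 254)`; unmapped reads carry flag 4; reverse
#' strand hits carry flag 16 with the stored (already reverse-complemented)
#' sequence.
#'
#' @param results list of alignment results from [map_reads()] (elements
#'   with `mapped = FALSE` become unmapped records).
#' @param refs list of reference [seq_record()]s (for `@SQ` lines).
#' @param out output path.
#' @return invisibly, the output path.
#' @export
write_alignments <- function(results, refs, out) {
  ref_ids <- vapply(refs, function(r) r$id, "")
  ref_len <- vapply(refs, function(r) nchar(r$seq), 0)
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", ref_ids, as.integer(ref_len)),
             "@PG\tID:anchoralign\tPN:anchoralign")
  for (res in results) {
    if (!isTRUE(res$mapped)) {
      lines <- c(lines, paste(res$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                              res$seq_out, "*", sep = "\t"))
      next
    }
    if (!(res$ref_id %in% ref_ids))
      stop("unknown reference id: ", res$ref_id)
    flag <- if (res$strand == "-") 16L else 0L
    lines <- c(lines, paste(res$read_id, flag, res$ref_id,
                            res$genome_start + 1L, # 0-based -> SAM 1-based
                            min(res$mapq, 254L), res$cigar, "*", 0L, 0L,
                            res$seq_out, "*", sep = "\t"))
  }
  writeLines(lines, out)
  invisible(out)
}

#' Write FASTA / FASTQ / QV sidecar / truth files
#'
#' Writers for the simulator's outputs: plain FASTA, Sanger FASTQ, the
#' sidecar quality table read back by [read_qv_table()], and a BED-like
#' truth table (`ref`, `start`, `end`, `strand`, `read_id`; 0-based
#' half-open).
#'
#' @param reads list of [seq_record()]s (for truth: of simulated reads
#'   carrying a `truth` attribute as produced by [simulate_reads()]).
#' @param path output path.
#' @rdname sim-writers
#' @export
write_fasta <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in reads) writeLines(c(paste0(">", r$id), r$seq), con)
  invisible(path)
}

#' @rdname sim-writers
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in reads) {
    q <- if (!is.null(r$qv)) intToUtf8(pmin(r$qv$sub, 93) + 33L)
         else strrep("I", nchar(r$seq))
    writeLines(c(paste0("@", r$id), r$seq, "+", q), con)
  }
  invisible(path)
}

#' @rdname sim-writers
#' @export
write_qv_table <- function(reads, path) {
  rows <- vapply(reads, function(r) {
    qv <- r$qv
    if (is.null(qv)) return(NA_character_)
    paste(r$id,
          paste(qv$ins, collapse = ","), paste(qv$sub, collapse = ","),
          paste(qv$del, collapse = ","), paste(qv$sub_alt, collapse = ","),
          paste(qv$del_alt, collapse = ","), sep = "\t")
  }, "")
  writeLines(c(paste("id", "I", "S", "D", "Shat", "Dhat", sep = "\t"),
               rows[!is.na(rows)]), path)
  invisible(path)
}

#' @rdname sim-writers
#' @export
write_truth <- function(reads, path) {
  rows <- vapply(reads, function(r) {
    tr <- r$truth
    paste(tr$ref, tr$start, tr$end, tr$strand, r$record$id, sep = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}

# reverse complement of a plain character sequence (N maps to N)
revcomp <- function(s) {
  unname(chartr("ACGTN", "TGCAN",
                vapply(s, function(x)
                  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""),
                  "")))
}
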