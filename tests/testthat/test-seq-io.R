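test_that("FASTA parsing normalises case and preserves order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt", ">y desc", "NNAC"), f)
  recs <- read_seqs(f)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$id, "x")
  expect_equal(recs[[1]]$seq, "ACGT")
  expect_equal(recs[[2]]$id, "y")
  expect_equal(recs[[2]]$seq, "NNAC")
  expect_null(recs[[1]]$qv)
})

test_that("FASTQ base qualities land in the substitution track", {
  f <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@x", "ACGT", "+", "II!5"), f)
  recs <- read_seqs(f)
  expect_equal(recs[[1]]$seq, "ACGT")
  expect_equal(recs[[1]]$qv$sub, c(40, 40, 0, 20)) # 'I'=40, '!'=0, '5'=20
})

test_that("sidecar QV tables attach full tracks by read id", {
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
  tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tI\tS\tD\tShat\tDhat",
               "r1\t5,6,7,8\t1,2,3,4\t9,9,9,9\tA,C,G,T\tT,G,C,A"), tab)
  recs <- read_qv_table(tab, read_seqs(fq))
  qv <- recs[[1]]$qv
  expect_equal(qv$ins, c(5, 6, 7, 8))
  expect_equal(qv$sub, c(1, 2, 3, 4))
  expect_equal(qv$del_alt, c("T", "G", "C", "A"))
})

test_that("SAM output follows the format conventions", {
  refs <- list(seq_record("chr1", "ACGTACGTAC"))
  hit <- list(read_id = "r1", mapped = TRUE, ref_id = "chr1", strand = "+",
              genome_start = 0L, genome_end = 8L, cigar = "8M", mapq = 254L,
              seq_out = "ACGTACGT")
  un <- list(read_id = "r2", mapped = FALSE, seq_out = "TTTT")
  out <- withr::local_tempfile(fileext = ".sam")
  write_alignments(list(hit, un), refs, out)
  lines <- readLines(out)
  expect_true(any(grepl("^@SQ\tSN:chr1\tLN:10$", lines)))
  rec <- strsplit(grep("^r1\t", lines, value = TRUE), "\t")[[1]]
  expect_equal(rec[2:6], c("0", "chr1", "1", "254", "8M"))
  rec2 <- strsplit(grep("^r2\t", lines, value = TRUE), "\t")[[1]]
  expect_equal(rec2[c(2, 4, 6)], c("4", "0", "*"))
  # header-only when there is nothing to report
  write_alignments(list(), refs, out)
  expect_true(all(grepl("^@", readLines(out))))
  expect_error(write_alignments(list(modifyList(hit, list(ref_id = "nope"))),
                                refs, out), "unknown reference")
})

test_that("written SAM round-trips through a standards-conforming reader", {
  skip_if_not_installed("Rsamtools")
  set.seed(3)
  gseq <- random_seq(400)
  genome <- seq_record("ref", gseq)
  reads <- list(seq_record("a", substr(gseq, 51, 150)),
                seq_record("b", revcomp(substr(gseq, 201, 290))))
  res <- map_reads(reads, build_index(genome))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_alignments(res, list(genome), sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  b <- Rsamtools::scanBam(bam)[[1]]
  expect_equal(sort(as.character(b$qname)), c("a", "b"))
  i_a <- which(b$qname == "a"); i_b <- which(b$qname == "b")
  expect_equal(as.integer(b$pos[i_a]), 51L)
  expect_equal(as.character(b$strand[i_b]), "-")
  expect_equal(as.integer(b$pos[i_b]), 201L)
  # M+I consume the read
  for (i in c(i_a, i_b)) {
    cig <- as.character(b$cigar[i])
    ops <- regmatches(cig, gregexpr("[0-9]+[MID]", cig))[[1]]
    n <- as.integer(sub("[MID]", "", ops))
    type <- sub("[0-9]+", "", ops)
    expect_equal(sum(n[type %in% c("M", "I")]), 100 - 10 * (i %in% i_b))
  }
})
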