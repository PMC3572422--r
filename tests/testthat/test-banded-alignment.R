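test_that("guide band covers chain diagonals and stays monotone", {
  cfg <- mapper_config(k_sdp = 11, b_sdp = 15)
  # identity chain on equal-length sequences: band [i-15, i+15] clipped
  ch <- data.frame(read_pos = 0:29, ivl_pos = 0:29)
  band <- build_guide_band(ch, R = 40, l_C = 40, cfg)
  i <- 1:40
  expect_equal(band[, "lo"], pmax(pmin(i - 15, 40), 0))
  expect_equal(band[, "hi"], pmin(pmax(i + 15, 0), 40))
  # two matches on diagonals 0 and 8: inter-match rows half-width 23
  ch2 <- data.frame(read_pos = c(0, 40), ivl_pos = c(0, 48))
  band2 <- build_guide_band(ch2, R = 60, l_C = 80, cfg)
  mid_rows <- 20:40 # between the matches, far enough in to avoid clipping
  expect_true(all(band2[mid_rows, "hi"] - (mid_rows + 4) >= 23))
  expect_true(all((mid_rows + 4) - band2[mid_rows, "lo"] >= 23))
  # empty chain: full rectangle
  band3 <- build_guide_band(data.frame(), R = 50, l_C = 50, cfg)
  expect_true(all(band3[, "lo"] == 0 & band3[, "hi"] == 50))
  # invariants on a drifting chain
  ch4 <- data.frame(read_pos = c(0, 20, 45), ivl_pos = c(5, 32, 50))
  band4 <- build_guide_band(ch4, R = 70, l_C = 80, cfg)
  expect_true(all(diff(band4[, "lo"]) >= 0))
  expect_true(all(diff(band4[, "hi"]) >= 0))
  expect_true(all(band4[, "hi"] >= band4[, "lo"]))
  expect_true(all(band4[-1, "lo"] <= band4[-nrow(band4), "hi"] + 1))
})

test_that("alignment reproduces the documented scoring cases", {
  cfg <- mapper_config()
  a1 <- banded_align("ACGTACGT", "ACGTACGT", NULL, cfg)
  expect_equal(a1$cost, 0)
  expect_equal(a1$cigar, "8M")
  # substitution whose alternative call matches costs the sub quality
  qv <- quality_arrays(rep(30, 4), c(30, 30, 30, 5), rep(30, 4),
                       c("N", "N", "N", "T"), rep("N", 4))
  a2 <- banded_align(seq_record("r", "ACGA", qv), "ACGT", NULL, cfg)
  expect_equal(a2$cost, 5)
  expect_equal(a2$cigar, "4M")
  # flat penalties: one deletion at the deletion prior
  a3 <- banded_align("ACGT", "ACAGT", NULL, cfg)
  expect_equal(a3$cost, 15)
  expect_equal(a3$cigar, "2M1D2M")
})

test_that("full-band cost equals the dynamic-programming oracle", {
  set.seed(17)
  cfg <- mapper_config()
  for (rep in 1:120) {
    R <- sample(5:80, 1)
    rseq <- random_seq(R)
    iseq <- if (rep %% 2 == 0) random_seq(sample(5:80, 1))
            else paste0(random_seq(5), rseq, random_seq(5))
    a <- banded_align(rseq, iseq, NULL, cfg)
    expect_equal(a$cost, dp_cost_oracle(rseq, iseq))
    # path consumes exactly the read and the reported interval span
    ops <- regmatches(a$cigar, gregexpr("[0-9]+[MID]", a$cigar))[[1]]
    n <- as.integer(sub("[MID]", "", ops)); ty <- sub("[0-9]+", "", ops)
    expect_equal(sum(n[ty %in% c("M", "I")]), R)
    expect_equal(sum(n[ty %in% c("M", "D")]), a$g_end - a$g_start)
    # reported cost equals recomputation from the path counts (flat mode)
    expect_equal(a$cost, 20 * a$n_mismatch + 15 * a$n_ins + 15 * a$n_del)
  }
})

test_that("quality-aware cost equals a cell-by-cell oracle", {
  set.seed(18)
  cfg <- mapper_config()
  bases <- c("A", "C", "G", "T")
  for (rep in 1:40) {
    R <- sample(4:40, 1)
    rseq <- random_seq(R)
    iseq <- random_seq(sample(4:40, 1))
    qv <- quality_arrays(sample(3:25, R, TRUE), sample(3:25, R, TRUE),
                         sample(3:25, R, TRUE), sample(bases, R, TRUE),
                         sample(bases, R, TRUE))
    rd <- seq_record("r", rseq, qv)
    a <- banded_align(rd, iseq, NULL, cfg)
    expect_equal(a$cost, dp_cost_oracle_qv(rseq, iseq, qv))
  }
})

test_that("cost is invariant under joint reverse complement", {
  set.seed(19)
  cfg <- mapper_config()
  for (rep in 1:20) {
    rseq <- random_seq(30)
    iseq <- random_seq(40)
    a <- banded_align(rseq, iseq, NULL, cfg)
    b <- banded_align(revcomp(rseq), revcomp(iseq), NULL, cfg)
    expect_equal(a$cost, b$cost)
  }
})

test_that("a band excluding every complete path triggers one widening", {
  cfg <- mapper_config()
  rseq <- strrep("ACGT", 10)
  iseq <- paste0(strrep("T", 10), rseq)
  # disconnected band: no admissible path from the top half to the bottom
  band <- cbind(lo = c(rep(0L, 20), rep(30L, 20)),
                hi = c(rep(5L, 20), rep(40L, 20)))
  a <- banded_align(rseq, iseq, band, cfg)
  expect_false(is.null(a))
  expect_equal(a$cost, dp_cost_oracle(rseq, iseq)) # widened to the full grid
  expect_equal(a$cost, 0) # free leading interval gap absorbs the shift
})
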