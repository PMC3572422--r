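mk_anchors <- function(rp, gp, len = 12, strand = "+", freq = 1) {
  data.frame(read_pos = rp, genome_pos = gp, length = len, strand = strand,
             freq = freq)
}

test_that("collinear anchors chain into one cluster", {
  cl <- cluster_anchors(mk_anchors(c(0, 20, 40), c(0, 20, 40)), R = 100)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$anchor_bases, 36)
  expect_equal(nrow(cl[[1]]$anchors), 3)
})

test_that("distant anchors split into separate windows", {
  cl <- cluster_anchors(mk_anchors(c(0, 5), c(0, 5000)), R = 100)
  expect_length(cl, 2)
  empty <- mk_anchors(0, 0)[0, ]
  expect_equal(cluster_anchors(empty, 100), list())
})

test_that("crossing anchors are excluded; chain equals brute force", {
  a <- mk_anchors(c(0, 12, 24), c(0, 40, 20))
  cl <- cluster_anchors(a, R = 100)
  best <- max(vapply(cl, function(c) c$anchor_bases, 0))
  expect_equal(best, brute_best_chain(a))
  expect_equal(best, 24) # the crossing anchor cannot join
})

test_that("chaining equals the exhaustive oracle on random anchor sets", {
  set.seed(10)
  for (rep in 1:40) {
    m <- sample(2:10, 1)
    a <- mk_anchors(sample(0:80, m), sample(0:80, m),
                    len = sample(4:10, m, TRUE))
    cl <- cluster_anchors(a, R = 200)
    best <- max(vapply(cl, function(c) c$anchor_bases, 0))
    expect_equal(best, brute_best_chain(a))
  }
})

test_that("cluster invariants hold: monotone, non-overlapping, consistent sums", {
  set.seed(12)
  a <- mk_anchors(sample(0:150, 25), sample(0:150, 25), len = 8)
  for (cl in cluster_anchors(a, R = 200)) {
    an <- cl$anchors
    if (nrow(an) > 1) {
      expect_true(all(diff(an$read_pos) > 0))
      expect_true(all(diff(an$genome_pos) > 0))
      expect_true(all(an$read_pos[-1] >= head(an$read_pos + an$length, -1)))
      expect_true(all(an$genome_pos[-1] >= head(an$genome_pos + an$length, -1)))
    }
    expect_equal(cl$anchor_bases, sum(an$length))
  }
})

test_that("ranking follows frequency-weighted score with documented ties", {
  c1 <- cluster_anchors(mk_anchors(c(0, 20, 40), c(0, 20, 40), freq = 10),
                        R = 100)[[1]]
  c2 <- cluster_anchors(mk_anchors(c(0, 20), c(500, 520), freq = 1),
                        R = 100)[[1]]
  rk <- rank_clusters(list(c1, c2), mapper_config())
  # 3 * log(1/10) < 0: the all-unique cluster ranks first under raw counts
  expect_equal(rk[[1]]$anchor_bases, 24)
  expect_equal(rk[[1]]$rank, 1)
  expect_equal(rk[[1]]$fw_score, 0)
  expect_equal(rk[[2]]$fw_score, 3 * log(1 / 10))
  # with genome-relative frequencies the dense cluster wins
  rkG <- rank_clusters(list(c1, c2), mapper_config(), G = 1e6)
  expect_equal(rkG[[1]]$anchor_bases, 36)
  # equal scores: ties broken by anchor bases then leftmost genome start
  t1 <- cluster_anchors(mk_anchors(c(0, 20), c(700, 720)), R = 100)[[1]]
  t2 <- cluster_anchors(mk_anchors(c(0, 20), c(100, 120)), R = 100)[[1]]
  rkt <- rank_clusters(list(t1, t2), mapper_config())
  expect_equal(rkt[[1]]$a_first$genome_pos, 100)
})

test_that("truncation keeps max_candidates but remembers the full set", {
  cls <- lapply(0:14, function(i)
    cluster_anchors(mk_anchors(i, 1000 * i, len = 12 + i), R = 100)[[1]])
  rk <- rank_clusters(cls, mapper_config(max_candidates = 10))
  expect_length(rk, 10)
  expect_equal(attr(rk, "n_total"), 15)
  expect_length(attr(rk, "all_anchor_bases"), 15)
  expect_equal(vapply(rk, function(c) c$rank, 0), 1:10)
  fw <- vapply(rk, function(c) c$fw_score, 0)
  expect_true(all(diff(fw) <= 0))
})
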