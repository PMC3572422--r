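test_that("random genomes are deterministic with the requested composition", {
  g1 <- random_genome(1000, seed = 5)
  g2 <- random_genome(1000, seed = 5)
  expect_equal(nchar(g1$seq), 1000)
  expect_identical(g1$seq, g2$seq)
  gc_only <- random_genome(500, gc = 1, seed = 5)
  expect_true(grepl("^[GC]+$", gc_only$seq))
})

test_that("error-free reads are exact genomic substrings with correct truth", {
  g <- random_genome(5000, seed = 6)
  sim <- simulate_reads(g, sim_config(rho = 0, read_length = 300,
                                      n_reads = 12, seed = 8))
  for (s in sim) {
    tr <- s$truth
    expect_equal(tr$end - tr$start, 300)
    frag <- substr(g$seq, tr$start + 1, tr$end)
    want <- if (tr$strand == "+") s$record$seq else revcomp(s$record$seq)
    expect_identical(want, frag)
  }
})

test_that("error mix and per-base rate match the configuration", {
  g <- random_genome(3000, seed = 7)
  cfg <- sim_config(rho = 0.15, read_length = 900, n_reads = 120, seed = 9)
  sim <- simulate_reads(g, cfg)
  ev <- Reduce(`+`, lapply(sim, `[[`, "events"))
  n_err <- sum(ev)
  expect_gt(n_err, 1e4)
  expect_equal(unname(ev["sub"] / n_err), 0.10, tolerance = 0.02 / 0.10)
  expect_equal(unname(ev["ins"] / n_err), 0.62, tolerance = 0.02 / 0.62)
  expect_equal(unname(ev["del"] / n_err), 0.28, tolerance = 0.02 / 0.28)
  # per-template-base error rate within 2 binomial sd of rho
  n_tmpl <- sum(vapply(sim, function(s) s$truth$end - s$truth$start, 0)) +
    ev["ins"] # insertions occupy draws without consuming template
  p_hat <- n_err / n_tmpl
  expect_lt(abs(p_hat - 0.15), 2 * sqrt(0.15 * 0.85 / n_tmpl) + 0.005)
})

test_that("error-free run lengths follow a geometric law", {
  g <- random_genome(2000, seed = 10)
  cfg <- sim_config(rho = 0.15, read_length = 1000, n_reads = 100, seed = 11)
  sim <- simulate_reads(g, cfg)
  mc <- mapper_config()
  runs <- integer(0)
  for (s in sim[1:30]) {
    tr <- s$truth
    frag <- substr(g$seq, tr$start + 1, tr$end)
    tmpl <- if (tr$strand == "+") frag else revcomp(frag)
    a <- banded_align(s$record$seq, tmpl, NULL, mc)
    ops <- regmatches(a$cigar, gregexpr("[0-9]+[MID]", a$cigar))[[1]]
    # expand to per-column error indicator and measure error-free runs
    n <- as.integer(sub("[MID]", "", ops)); ty <- sub("[0-9]+", "", ops)
    err <- rep(ty != "M", n) # M columns may still mismatch; close enough
    r <- rle(err)
    runs <- c(runs, r$lengths[!r$values])
  }
  # regression of log10 frequency on run length is linear with negative
  # slope close to log10(1 - rho_eff)
  tab <- table(runs[runs <= 25])
  len <- as.integer(names(tab))
  fit <- stats::lm(log10(as.integer(tab)) ~ len)
  slope <- unname(stats::coef(fit)[2])
  expect_lt(slope, -0.04)
  expect_gt(slope, -0.12) # log10(0.85) = -0.071 up to mismatch inflation
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("phred mapping accuracy arithmetic and its cap", {
  res_ok <- list(mapped = TRUE, ref_id = "r", strand = "+", genome_start = 5)
  res_bad <- list(mapped = TRUE, ref_id = "r", strand = "+",
                  genome_start = 900)
  tr <- list(ref = "r", strand = "+", start = 0, end = 100)
  results <- c(rep(list(res_ok), 999), list(res_bad))
  m <- mapability_phred(results, rep(list(tr), 1000))
  expect_equal(m$phred, 30)
  all_bad <- mapability_phred(rep(list(res_bad), 10), rep(list(tr), 10))
  expect_equal(all_bad$phred, 0)
  all_ok <- mapability_phred(rep(list(res_ok), 100), rep(list(tr), 100))
  expect_equal(all_ok$phred, -10 * log10(0.5 / 100))
  expect_error(mapability_phred(list(), list()))
})
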