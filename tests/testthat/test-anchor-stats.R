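test_that("waiting length matches the closed form and a word-process MC", {
  w <- waiting_length(0.5, 1, 0.05)
  expect_equal(w$t, log(0.05) / log(0.5), tolerance = 1e-12)
  w2 <- waiting_length(0.15, 15, 0.05)
  expect_equal(w2$t, 32.77, tolerance = 1e-3)
  expect_equal(w2$bases, 171.4, tolerance = 1e-3)
  # epsilon -> 1 gives t -> 0
  expect_lt(waiting_length(0.15, 15, 0.999)$t, 0.05)
  expect_lt(waiting_length(0.15, 15, 0.9999)$t,
            waiting_length(0.15, 15, 0.999)$t)
  expect_error(waiting_length(0, 15), "rho")
  # Monte Carlo of the word process: count words until the first of
  # length >= K; P(T <= t) should be 1 - epsilon
  set.seed(21)
  rho <- 0.15; K <- 15
  Tn <- stats::rgeom(2e5, (1 - rho)^K) + 1 # words until first anchor
  expect_equal(mean(Tn <= w2$t), 0.95, tolerance = 0.01)
  # bases per failed word: 1 + E[W | W < K]
  W <- stats::rgeom(5e5, rho)
  Wc <- W[W < K]
  expect_equal(w2$bases, w2$t * (1 + mean(Wc)), tolerance = 0.01)
})

test_that("composition counts: polynomial, closed form and enumeration agree", {
  for (L in c(5, 9, 14)) {
    for (M in 0:min(5, L)) {
      for (K in 0:4) {
        hist <- enumerate_anchor_counts(M, K, L)
        for (N in 0:(M + 1)) {
          cp <- compositions_poly(M, N, K, L)
          cc <- bn_double(compositions_closed(M, N, K, L))
          expect_equal(cp, cc)
          expect_equal(cp, unname(hist[as.character(N)]))
        }
        expect_equal(sum(hist), choose(L, M))
      }
    }
  }
})

test_that("counts sum to choose(L, M) and configurations are suffix sums", {
  tot <- sum(vapply(0:3, function(N) compositions_poly(2, N, 3, 7), 0))
  expect_equal(tot, choose(7, 2))
  expect_equal(bn_double(num_configurations(2, 0, 3, 7)$count), choose(7, 2))
  expect_equal(num_configurations(2, 0, 3, 7)$probability, 1)
  nc <- num_configurations(2, 1, 3, 7)
  expect_equal(bn_double(nc$count), 18)
  expect_equal(nc$probability, 18 / 21)
})

test_that("polynomial-method intermediates stay within exact double range", {
  expect_error(compositions_poly(150, 10, 15, 1000), "exact double")
  # near the documented guard the method still works
  expect_equal(compositions_poly(9, 2, 5, 60),
               bn_double(compositions_closed(9, 2, 5, 60)))
})

test_that("moments match the exact distribution and documented small case", {
  mom <- composition_moments(2, 3, 7)
  expect_equal(mom$mu, 6 / 7, tolerance = 1e-12)
  expect_equal(mom$sigma2, 6 / 49, tolerance = 1e-12)
  expect_equal(composition_moments(4, 0, 9), list(mu = 5, sigma2 = 0))
  # empirical moments of the exact c table for L = 60, M = 9, K = 5
  L <- 60; M <- 9; K <- 5
  cN <- vapply(0:(M + 1), function(N) compositions_poly(M, N, K, L), 0)
  tot <- choose(L, M)
  mu_emp <- sum((0:(M + 1)) * cN) / tot
  var_emp <- sum((0:(M + 1))^2 * cN) / tot - mu_emp^2
  momL <- composition_moments(M, K, L)
  expect_equal(momL$mu, mu_emp, tolerance = 1e-10)
  expect_equal(momL$sigma2, var_emp, tolerance = 1e-10)
})

test_that("normal approximation behaves like a distribution", {
  na <- normal_approx(9, 0:10, 5, 60)
  expect_true(all(diff(na$survival) <= 0))
  # at the rounded mean the survival sits near 1/2, within the slack the
  # -1/2 continuity correction introduces (about phi(0)/sigma)
  mom <- composition_moments(150, 15, 1000)
  at_mean <- normal_approx(150, round(mom$mu), 15, 1000)
  expect_lt(abs(at_mean$survival - 0.5),
            0.5 / sqrt(mom$sigma2) * dnorm(0) + 0.02)
})

test_that("geometric run model: mean and tail behave as documented", {
  expect_equal(mean_run_length(0.15), 5.666667, tolerance = 1e-6)
  expect_equal(prun_length(20, 0.848), 1 - 0.848^21)
  # Pr(W >= K) = (1 - rho)^K
  rho <- 0.2
  expect_equal(1 - prun_length(9, 1 - rho), (1 - rho)^10)
})

test_that("anchors-first compositions enumerate the constrained set", {
  m <- anchors_first_compositions(2, 1, 3, 7)
  expect_equal(nrow(m), 6)
  expect_true(all(rowSums(m) == 8))
  expect_true(all(m[, 1] > 3) && all(m[, 2:3] <= 3))
  # c' relates to c through the choose(M+1, N) positional factor
  expect_equal(nrow(m) * choose(3, 1), compositions_poly(2, 1, 3, 7))
})
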