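test_that("stationary law matches the generator eigen-problem oracle", {
  for (ab in list(c(0, 0), c(0, 1), c(-1, 0), c(-1, 1))) {
    for (kappa in c(0.0022, 1)) {
      N <- 30
      p <- feedback_params(ab[1], ab[2], k_plus = kappa, k_minus = 1)
      d <- stationary_single(p, N)
      oracle <- bd_stationary_oracle(ab[1], ab[2], kappa, N)
      expect_lt(max(abs(d$probs - oracle)), 1e-10)
    }
  }
})

test_that("detailed balance holds on the computed distribution", {
  cases <- list(c(0, 0), c(0, 1), c(1, 0), c(-0.2, 0), c(-2, 1))
  for (ab in cases) {
    p <- feedback_params(ab[1], ab[2], k_plus = 0.5, k_minus = 1)
    V <- 1.5
    N <- 40
    d <- stationary_single(p, N, V)
    n <- 1:N
    lhs <- p$k_minus * n^p$beta * d$probs[n + 1]
    rhs <- (p$k_plus / V) * (N - n + 1) * n^(-p$alpha) * d$probs[n]
    scale <- pmax(abs(lhs), abs(rhs))
    ok <- scale > 0
    expect_lt(max(abs(lhs - rhs)[ok] / scale[ok]), 1e-10)
  }
})

test_that("small-pool edge cases have the enumerable stationary law", {
  # N = 1: weights 1 and kappa regardless of the exponents
  for (ab in list(c(0, 0), c(2, -1), c(-3, 1))) {
    d <- stationary_single(feedback_params(ab[1], ab[2], 1, 1), N = 1)
    expect_equal(d$probs, c(0.5, 0.5))
  }
  # canonical limiting pool concentrates at the deterministic steady state
  d <- stationary_single(feedback_params(0, 0, 1, 1), N = 50)
  expect_lt(abs(d$mean - 49), 1)
  expect_equal(sum(d$probs), 1, tolerance = 1e-12)
})

test_that("distributions normalize for extreme parameters without overflow", {
  for (N in c(0, 1, 200, 1000)) {
    for (kappa in c(1e-4, 1, 50)) {
      d <- stationary_single(feedback_params(-1, 0, kappa, 1), N)
      expect_equal(sum(d$probs), 1, tolerance = 1e-12)
      expect_true(all(d$probs >= 0))
    }
  }
})

test_that("two-structure joint law is exchange-symmetric and conserves mass", {
  p <- feedback_params(0, 1, 1, 1)
  j <- stationary_joint_two(p, p, N = 50)
  expect_equal(sum(j$probs), 1, tolerance = 1e-12)
  expect_identical(j$probs, t(j$probs))
  m1 <- marginalize(j, 1); m2 <- marginalize(j, 2)
  expect_equal(m1$probs, m2$probs)
  # conservation in expectation: E n1 + E n2 + E Nav = N
  n <- 0:50
  e_nav <- sum(outer(n, n, function(a, b) 50 - a - b) * j$probs)
  expect_equal(m1$mean + m2$mean + e_nav, 50, tolerance = 1e-10)
})

test_that("toy joint distribution equals a hand enumeration", {
  # N = 2, kappa1 = 2, kappa2 = 3, alpha + beta = 1: weights
  # kappa1^n1 kappa2^n2 N! / (n1! n2! (N-n1-n2)!)
  j <- stationary_joint_two(feedback_params(0, 1, 2, 1),
                            feedback_params(0, 1, 3, 1), N = 2)
  w <- matrix(0, 3, 3)
  for (n1 in 0:2) for (n2 in 0:2) {
    if (n1 + n2 > 2) next
    w[n1 + 1, n2 + 1] <- 2^n1 * 3^n2 * factorial(2) /
      (factorial(n1) * factorial(n2) * factorial(2 - n1 - n2))
  }
  expect_equal(j$probs, w / sum(w), tolerance = 1e-12)
  m <- marginalize(j, 1)
  expect_equal(m$probs, rowSums(w) / sum(w), tolerance = 1e-12)
})

test_that("identical competitors on the degenerate line spread almost uniformly", {
  p <- feedback_params(0, 0, 1, 1)
  m <- marginalize(stationary_joint_two(p, p, N = 50), 1)
  expect_lt(tv_distance(m, manual_dist(rep(1, 51))), 0.05)
  # while net negative feedback concentrates both marginals (cv < 1)
  pn <- feedback_params(0, 1, 1, 1)
  mn <- marginalize(stationary_joint_two(pn, pn, N = 50), 1)
  expect_lt(mn$cv, 1)
  expect_equal(count_modes(mn), 1L)
  expect_gt(mn$mean - mn$sd, 0)
})

test_that("constant-concentration marginals have the closed Poisson form", {
  p <- feedback_params(0, 1, 1, 1)
  r <- stationary_const_conc(p, p, rho = 3)
  expect_true(all(r$normalizable))
  expect_equal(r$marginal1$mean, 3, tolerance = 1e-10)
  expect_lt(tv_distance(r$marginal1,
                        manual_dist(stats::dpois(0:r$n_max[1], 3))), 1e-12)
  # independence: the joint factorizes, so the marginals ignore the partner
  r2 <- stationary_const_conc(p, feedback_params(0, 1, 9, 1), rho = 3)
  expect_equal(r2$marginal1$probs, r$marginal1$probs)
})

test_that("non-normalizable constant-concentration regimes are certified", {
  p0 <- feedback_params(0, 0, 1, 1)
  r <- stationary_const_conc(p0, p0, rho = 2)  # kappa rho >= 1: unbounded
  expect_false(any(r$normalizable))
  expect_null(r$marginal1)
  rsub <- stationary_const_conc(p0, p0, rho = 0.5)  # below critical density
  expect_true(all(rsub$normalizable))
  rpos <- stationary_const_conc(feedback_params(-1, 0, 1, 1), p0, rho = 0.1)
  expect_false(rpos$normalizable[1])  # positive feedback never normalizes
  expect_true(rpos$normalizable[2])
  expect_error(stationary_const_conc(p0, p0, rho = 0.999, n_max = 4),
               "truncation")
})

test_that("moments handle degenerate distributions", {
  d <- manual_dist(c(0, 0, 0, 1))
  expect_equal(moments(d), list(mean = 3, sd = 0, cv = 0))
  d2 <- manual_dist(c(0.5, 0, 0.5))
  expect_equal(moments(d2), list(mean = 1, sd = 1, cv = 1))
  d0 <- manual_dist(c(1, 0))
  expect_identical(moments(d0)$cv, Inf)
})

test_that("mode counting merges plateaus and sees endpoint modes", {
  expect_equal(count_modes(manual_dist(c(5, 4, 3, 2, 1))), 1L)  # mode at 0
  expect_equal(count_modes(manual_dist(c(1, 3, 1, 4, 2))), 2L)
  expect_equal(count_modes(manual_dist(c(1, 2, 2, 2, 1))), 1L)  # plateau once
  expect_equal(count_modes(manual_dist(c(2, 1, 1, 2))), 2L)     # both ends
  expect_equal(count_modes(manual_dist(c(1, 1, 1))), 1L)
  # exact bistable law is bimodal; robust control is unimodal
  expect_equal(count_modes(stationary_single(
    feedback_params(-1, 0, 0.0022, 1), 50)), 2L)
  expect_equal(count_modes(stationary_single(
    feedback_params(0, 1, 1, 1), 50)), 1L)
})

test_that("kappa0 is the CV = 1 crossing and brackets behave as expected", {
  p <- feedback_params(0, 1, 1, 1)
  k0 <- find_kappa0(p, N = 50)
  cv_at <- function(k) stationary_single(
    feedback_params(0, 1, k, 1), 50)$cv
  expect_lt(abs(cv_at(k0) - 1), 1e-6)
  expect_gt(cv_at(k0 / 50), 1)   # far below threshold: fluctuation-dominated
  expect_lt(cv_at(k0 * 50), 1)   # far above: robust control
  expect_error(find_kappa0(p, N = 50, bracket = c(10, 100)), "sign")
})

test_that("the bistable window exists only for net positive feedback", {
  w <- bistable_window(-1, 0, N = 50)
  expect_false(w$empty)
  expect_lt(w$kappa_star, 0.0022)
  expect_gt(w$kappa_c, 0.0022)
  expect_lt(w$kappa_star, w$kappa_c)
  # bisection certificate at the lower edge
  modes_at <- function(k) count_modes(stationary_single(
    feedback_params(-1, 0, k, 1), 50))
  expect_equal(modes_at(w$kappa_star * 0.99), 1L)
  expect_equal(modes_at(w$kappa_star * 1.01), 2L)
  expect_true(bistable_window(0, 1, N = 50)$empty)
  expect_true(bistable_window(0, 0, N = 50)$empty)
})

test_that("volume enters the stationary law through kappa / V", {
  p <- feedback_params(0, 1, 2, 1)
  d1 <- stationary_single(p, 40, V = 2)
  d2 <- stationary_single(feedback_params(0, 1, 1, 1), 40, V = 1)
  expect_equal(d1$probs, d2$probs, tolerance = 1e-12)
})
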