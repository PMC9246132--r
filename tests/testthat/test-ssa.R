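canonical_spec <- function(t_max = 2000, seed = 1, M = 1, N = 50, ...) {
  simulation_spec(pool_config(N_total = N, V = 1, M = M),
                  feedback_params(0, 0, 1, 1),
                  t_max = t_max, seed = seed, ...)
}

test_that("identical seeds give identical trajectories", {
  tr1 <- gillespie_run(canonical_spec(seed = 99))
  tr2 <- gillespie_run(canonical_spec(seed = 99))
  expect_identical(tr1$times, tr2$times)
  expect_identical(tr1$sizes, tr2$sizes)
  tr3 <- gillespie_run(canonical_spec(seed = 100))
  expect_false(identical(tr1$times, tr3$times))
})

test_that("subunit conservation holds at every recorded event", {
  spec <- simulation_spec(pool_config(N_total = 40, V = 2, M = 2),
                          feedback_params(-0.5, 1, 1, 1),
                          t_max = 500, seed = 5)
  tr <- gillespie_run(spec)
  expect_true(all(tr$N_total - rowSums(tr$sizes) - tr$N_av == 0))
  expect_true(all(tr$sizes >= 0))
  expect_true(all(diff(tr$times) >= 0))
})

test_that("canonical limiting pool reaches the predicted steady size", {
  tr <- gillespie_run(canonical_spec(t_max = 20000))
  h <- stationary_histogram(tr)
  expect_lt(abs(h$mean / 49 - 1), 0.05)
})

test_that("occupancy-weighted histogram converges to the exact law", {
  p <- feedback_params(0, 1, 1, 1)
  spec <- simulation_spec(pool_config(N_total = 20, V = 1, M = 1), p,
                          max_events = 1e6, seed = 3)
  tr <- gillespie_run(spec)
  h <- stationary_histogram(tr, burn_in = 0.2 * (tr$t_end - tr$times[1]))
  expect_lt(tv_distance(h, stationary_single(p, 20)), 0.02)
})

test_that("a stalled chain yields a point-mass histogram", {
  spec <- simulation_spec(pool_config(N_total = 0, V = 1, M = 1),
                          feedback_params(0, 0, 1, 1),
                          t_max = 10, seed = 1, burn_in = 0)
  tr <- gillespie_run(spec)
  expect_true(tr$absorbed)
  h <- stationary_histogram(tr, burn_in = 0)
  expect_equal(h$probs, 1)
  expect_equal(h$support, 0)
})

test_that("identical degenerate-line competitors anticorrelate strongly", {
  spec <- canonical_spec(t_max = 20000, seed = 7, M = 2)
  tr <- gillespie_run(spec)
  expect_lt(anticorrelation(tr), -0.9)
})

test_that("on the degenerate line the faster structure takes the pool", {
  cfg <- pool_config(N_total = 50, V = 1, M = 2)
  pars <- list(feedback_params(0, 0, 1, 1), feedback_params(0, 0, 0.5, 1))
  tr <- gillespie_run(simulation_spec(cfg, pars, t_max = 20000, seed = 2))
  s <- trajectory_summary(tr)
  expect_gt(s$means[1], 0.9 * 49)  # depletable pool N - V/kappa1
  expect_lt(s$means[2], 5)
})

test_that("production channel obeys its mean law and caps at Delta_N", {
  cfg <- pool_config(N_total = 50, V = 1, M = 1)
  p <- feedback_params(0, 1, 1, 1)
  r_p <- 0.5; Delta_N <- 30
  produced <- vapply(1:200, function(s) {
    spec <- simulation_spec(cfg, p, t_max = 1 / r_p, seed = s, burn_in = 0)
    tr <- run_with_production(spec, r_p, Delta_N)
    expect_true(all(tr$N_total - 50 <= Delta_N))
    tr$N_total[length(tr$N_total)] - 50
  }, numeric(1))
  expect_lt(abs(mean(produced) / (Delta_N * (1 - exp(-1))) - 1), 0.1)
})

test_that("a zero-size production channel leaves the trajectory unchanged", {
  spec <- canonical_spec(t_max = 500, seed = 31)
  plain <- gillespie_run(spec)
  with_null <- run_with_production(spec, r_p = 2, Delta_N = 0)
  expect_identical(plain$sizes, with_null$sizes)
  expect_identical(plain$times, with_null$times)
})

test_that("cell-growth channel produces the linear mean growth law", {
  cfg <- pool_config(N_total = 50, V = 1, M = 1)
  p <- feedback_params(0, 1, 1, 1)
  g <- 0.5; dV <- 0.02
  slopes <- vapply(1:100, function(s) {
    spec <- simulation_spec(cfg, p, t_max = 100, seed = s, record = 1,
                            burn_in = 0)
    tr <- run_with_cell_growth(spec, g, dV)
    unname(coef(lm(tr$N_total ~ tr$times))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes) / g - 1), 0.1)
  # g = 0 reduces to the fixed-pool run
  spec <- canonical_spec(t_max = 500, seed = 13)
  expect_identical(gillespie_run(spec)$sizes,
                   run_with_cell_growth(spec, 0, dV)$sizes)
})

test_that("slow cell growth is tracked by the instantaneous steady state", {
  p <- feedback_params(0, 1, 1, 1)
  spec <- simulation_spec(pool_config(N_total = 50, V = 1, M = 2), p,
                          t_max = 2000, seed = 3, record = 1, burn_in = 0)
  tr <- run_with_cell_growth(spec, g = 0.02, dV = 0.02)
  for (mid in seq(300, 1900, by = 400)) {
    sel <- tr$times >= mid - 100 & tr$times < mid + 100
    obs <- mean(tr$sizes[sel, 1])
    pred <- mean(tr$N_total[sel]) / (2 + mean(tr$V[sel]))  # kappa = 1, M = 2
    expect_lt(abs(obs / pred - 1), 0.1)
  }
})

test_that("simulation spec validates its stopping rule and blocks", {
  cfg <- pool_config(N_total = 10, V = 1, M = 1)
  p <- feedback_params(0, 0, 1, 1)
  expect_error(simulation_spec(cfg, p), "exactly one")
  expect_error(simulation_spec(cfg, p, t_max = 1, max_events = 1),
               "exactly one")
  expect_error(simulation_spec(cfg, p, t_max = 1, init = c(1, 2)))
  expect_error(simulation_spec(cfg, list(p, p), t_max = 1))
})

test_that("trajectories round-trip through the TSV writer", {
  tr <- gillespie_run(canonical_spec(t_max = 50, seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  df <- utils::read.delim(path)
  expect_equal(nrow(df), length(tr$times))
  expect_equal(df$n_1, unname(tr$sizes[, 1]))
  expect_equal(df$time, tr$times)
})
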