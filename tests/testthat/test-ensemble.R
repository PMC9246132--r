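bistable_params <- function(kappa = 0.0022) feedback_params(-1, 0, kappa, 1)

test_that("hysteresis state assignment counts no switches when monostable", {
  p <- feedback_params(0, 1, 1, 1)
  tr <- gillespie_run(simulation_spec(pool_config(N_total = 50, V = 1, M = 1),
                                      p, t_max = 5000, seed = 1, record = 1))
  rt <- residence_times(tr)
  expect_equal(rt$n_transitions, 0)
  expect_true(rt$censored)
  expect_gt(rt$tau_R, 0)  # censored lower bound, never dropped
})

test_that("bistable single-structure runs switch between branches", {
  tr <- gillespie_run(simulation_spec(pool_config(N_total = 50, V = 1, M = 1),
                                      bistable_params(), t_max = 3e5, seed = 3,
                                      record = 5))
  rt <- residence_times(tr)
  expect_gte(rt$n_transitions, 1)
  expect_true(is.finite(rt$tau_R))
})

test_that("high-branch residence grows steeply with the pool size", {
  meds <- vapply(c(40, 50, 60), function(N) {
    fp <- vapply(1:8, function(s) {
      spec <- simulation_spec(pool_config(N_total = N, V = 1, M = 1),
                              bistable_params(), t_max = 2e5, seed = s,
                              record = 2, init = round(0.8 * N), burn_in = 0)
      first_passage_time(gillespie_run(spec), threshold_frac = 0.25)$time
    }, numeric(1))
    median(fp)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
  expect_gt(meds[2] / meds[1], 10)  # exponential, not linear, trend
})

test_that("residence thresholds are validated", {
  tr <- gillespie_run(simulation_spec(pool_config(N_total = 10, V = 1, M = 1),
                                      feedback_params(0, 0, 1, 1),
                                      t_max = 100, seed = 1))
  expect_error(residence_times(tr, lo_frac = 0.8, hi_frac = 0.2))
  expect_error(residence_times(tr, lo_frac = 0, hi_frac = 0.5))
})

test_that("dynamic-state classification matches the regime phenomenology", {
  # deep sub-threshold growth: no-growth state with near-exponential law
  s_low <- classify_dynamic_state(feedback_params(0, 1, 1e-4, 1), 50)
  expect_identical(s_low$value, "no_growth")
  expect_gte(s_low$criteria_record$cv, 1)
  # the bistable reference point
  expect_identical(classify_dynamic_state(bistable_params(), 50)$value,
                   "bistable")
  # robust control far above threshold
  expect_identical(classify_dynamic_state(feedback_params(0, 1, 1, 1), 50)$value,
                   "monostable_large")
  # deterministic rule: identical labels on re-evaluation
  a <- classify_dynamic_state(bistable_params(), 50)
  b <- classify_dynamic_state(bistable_params(), 50)
  expect_identical(a$value, b$value)
  expect_identical(a$criteria_record, b$criteria_record)
})

test_that("states progress no-growth, shoulder, bistable along kappa", {
  sd_ <- state_diagram(kappa_grid = 10^seq(-4.5, -1.8, length.out = 25),
                       alpha_grid = -0.2, N = 50)
  lev <- c(no_growth = 1, shoulder = 2, bistable = 3, monostable_large = 4)
  ord <- lev[sd_$state[order(sd_$kappa)]]
  expect_true(all(diff(ord) >= 0))
  expect_true(all(c("no_growth", "shoulder", "bistable") %in% sd_$state))
  # stronger positive feedback promotes bistability at smaller kappa
  onset <- function(a) {
    g <- state_diagram(kappa_grid = 10^seq(-4.5, -1.8, length.out = 40),
                       alpha_grid = a, N = 50)
    min(g$kappa[g$state == "bistable"])
  }
  expect_lt(onset(-1), onset(-0.2))
})

test_that("coexistence requires negative feedback; rate bias sets the ranking", {
  cp <- coexistence_phase(kappa1_grid = 1, s_grid = 1, kappa2 = 0.5, N = 50)
  expect_true(cp$coexist)
  expect_gt(cp$mean1, cp$mean2)
  expect_gt(cp$mean2, 1)
  # degenerate line with a faster competitor: winner takes all
  cp0 <- coexistence_phase(kappa1_grid = 1, s_grid = 0, kappa2 = 0.5, N = 50)
  expect_false(cp0$coexist)
  expect_gt(cp0$mean1, 0.9 * 49)
})

test_that("stochastic anticorrelation matches the exact joint covariance", {
  p <- feedback_params(0, 1, 1, 1)
  exact <- joint_correlation(stationary_joint_two(p, p, 50))
  cors <- vapply(1:12, function(s) {
    tr <- gillespie_run(simulation_spec(pool_config(N_total = 50, V = 1, M = 2),
                                        p, t_max = 4000, seed = s))
    anticorrelation(tr)
  }, numeric(1))
  se <- sd(cors) / sqrt(length(cors))
  expect_lt(abs(mean(cors) - exact), 3 * se + 0.02)
  # degenerate line: strong anticorrelation in both routes
  p0 <- feedback_params(0, 0, 1, 1)
  expect_lt(joint_correlation(stationary_joint_two(p0, p0, 50)), -0.9)
})

test_that("independent constant-concentration structures are uncorrelated", {
  cfg <- pool_config(V = 1, M = 2, mode = "constant_concentration", rho = 3)
  p <- feedback_params(0, 1, 1, 1)
  tr <- gillespie_run(simulation_spec(cfg, p, t_max = 4000, seed = 5))
  expect_lt(abs(anticorrelation(tr)), 0.1)
})

test_that("autocatalytic competition selects a single persistent winner", {
  ps <- polarity_selection(M = 20, feedback_params(-1, 0, 0.0125, 1),
                           N = 2000, t_max = 4000, seeds = 1:10)
  expect_gte(ps$frac_single_winner, 0.9)
  expect_true(all(ps$dominance[!is.na(ps$winner)] > 0.5))
})

test_that("intermediate pools flicker between dominant structures", {
  # smaller pool: repeated exchanges of the dominant structure over one run
  cfg <- pool_config(N_total = 60, V = 1, M = 4)
  p <- feedback_params(-0.2, 0, 0.0125, 1)
  tr <- gillespie_run(simulation_spec(cfg, p, t_max = 4e4, seed = 2,
                                      record = 20))
  dom <- apply(tr$sizes, 1, which.max)
  big <- rowSums(tr$sizes) > 20
  expect_gt(length(unique(dom[big])), 1)
})
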