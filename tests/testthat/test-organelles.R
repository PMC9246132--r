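test_that("concentration-to-count conversion uses the fixed convention", {
  expect_equal(conc_to_count(5, 1, "uM"), round(5 * 602.214))
  expect_equal(conc_to_count(8, 100, "per_um3"), 800)
})

test_that("flagellar length decreases with flagella number at fixed pool", {
  means <- vapply(c(1, 2, 4), function(M) {
    sp <- flagella_spec(M = M)
    tr <- flagella_simulate(sp, t_max = 100, seed = M, record = 0.05)
    mean(trajectory_summary(tr, burn_in = 50)$means) * sp$subunit_size
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("two identical flagella share the balance-point steady length", {
  sp <- flagella_spec(M = 2)
  tr <- flagella_simulate(sp, t_max = 200, seed = 8, record = 0.05)
  s <- trajectory_summary(tr, burn_in = 100)
  nstar <- flagella_steady_state(sp)
  expect_lt(abs(s$means[1] / nstar - 1), 0.05)
  expect_lt(abs(s$means[2] / nstar - 1), 0.05)
  # the steady state solves the symmetric balance condition
  resid <- sp$k_plus * (sp$N - 2 * nstar) / (sp$V * (1 + nstar)) - sp$k_minus
  expect_lt(abs(resid), 1e-9)
})

test_that("amputation triggers transient shrinkage then full recovery", {
  sp <- flagella_spec()
  am <- flagella_amputate(sp, t_max = 4000, seed = 1)
  expect_equal(unname(am$post$sizes[1, 2]), 0)  # severed flagellum restarts at zero
  # the intact flagellum shrinks below its pre-cut length before recovering
  intact <- am$post$lengths[, 1]
  expect_lt(min(intact), 0.8 * am$pre_cut_lengths[1])
  # with production on, both converge back to the pre-cut length (5%)
  w <- am$post$times > 3500
  finals <- colMeans(am$post$lengths[w, ])
  expect_lt(abs(finals[1] / am$pre_cut_lengths[1] - 1), 0.05)
  expect_lt(abs(finals[2] / am$pre_cut_lengths[1] - 1), 0.05)
})

test_that("blocking production leaves two equal but shorter flagella", {
  sp <- flagella_spec()
  am <- flagella_amputate(sp, t_max = 3000, seed = 2, production = FALSE)
  w <- am$post$times > 2500
  finals <- colMeans(am$post$lengths[w, ])
  expect_lt(abs(finals[1] / finals[2] - 1), 0.1)
  expect_lt(finals[1], 0.95 * am$pre_cut_lengths[1])
})

test_that("centrosome closed forms match the stochastic model", {
  sp <- centrosome_spec(n_c = 1)
  m <- centrosome_model(sp)
  expect_equal(m$steady_size_single,
               sp$k_plus * sp$N / (sp$k_plus + sp$k_minus * sp$V_cell))
  tr <- centrosome_simulate(sp, t_max = 40, seed = 1)
  s <- trajectory_summary(tr, burn_in = 20)
  expect_lt(abs(s$means[1] / m$steady_size_single - 1), 0.05)
})

test_that("a centrosome pair stays equal-sized (no winner-takes-all)", {
  sp <- centrosome_spec(n_c = 2)
  tr <- centrosome_simulate(sp, t_max = 40, seed = 4)
  s <- trajectory_summary(tr, burn_in = 20)
  expect_lt(abs(s$means[1] / s$means[2] - 1), 0.05)
  m <- centrosome_model(sp)
  expect_lt(abs(s$means[1] / m$steady_size - 1), 0.05)
})

test_that("centrosome volume scales linearly with cell volume", {
  cs <- centrosome_scaling(centrosome_spec(n_c = 2),
                           V_grid = c(2000, 5000, 8000), t_max = 30, seed = 5)
  fit <- lm(V_c ~ V_cell, data = cs)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("droplet reduction produces the printed coefficients", {
  p <- llps_params(Q = 2, k = 1, k_BA = 3, psi_minus = 0.5, dv = 1)
  red <- llps_reduce(p)
  expect_equal(red$C0, 1)
  expect_equal(red$C1, 0.5)
  expect_equal(red$C2, 3)
  expect_equal(red$rhs(10, 100), (1 + 0.5 * 10) * 100 - 3 * 10)
  expect_error(llps_params(1, 1, 1, psi_minus = 1.5), "psi_minus")
  expect_error(llps_params(1, 1, 1, psi_minus = 0), "psi_minus")
})

test_that("regime of the reduced droplet law follows the C1/C0 balance", {
  base <- function(k) llps_reduce(llps_params(Q = 1, k = k, k_BA = 1,
                                              psi_minus = 0.5))
  expect_identical(base(0)$effective_regime, "robust_control")
  expect_identical(base(1e-4)$effective_regime, "robust_control")
  expect_identical(base(1)$effective_regime, "limiting_pool_line")
  expect_identical(base(0.1)$effective_regime, "intermediate")
})

test_that("centriole-dominated droplet growth equals the kinetic model", {
  # C1 = 0: identical propensities, hence identical trajectories per seed
  N <- 500; Vc <- 10; C0 <- 2; C2 <- 1
  lp <- llps_params(Q = C0 / 0.5, k = 0, k_BA = C2, psi_minus = 0.5,
                    N_tot = N, V_cell = Vc)
  tr_llps <- llps_simulate(lp, M = 2, t_max = 50, seed = 9)
  cfg <- pool_config(N_total = N, V = Vc, M = 2)
  kin <- feedback_params(0, 1, k_plus = C0, k_minus = C2)
  tr_kin <- gillespie_run(simulation_spec(cfg, kin, t_max = 50, seed = 9))
  expect_identical(tr_llps$sizes, tr_kin$sizes)
  expect_identical(tr_llps$times, tr_kin$times)
})

test_that("purely autocatalytic droplet assembly matches the (-1,1) law shifted by one", {
  # (c1 n) Nav / V at size n equals the power-law (-1) assembly at size n - 1
  cfg <- pool_config(N_total = 100, V = 2, M = 1)
  c1 <- 0.7
  core <- feedback_params(-1, 1, k_plus = c1, k_minus = 1)
  for (n in 1:20) {
    st <- system_state(sizes = n - 1, cfg)
    expect_equal(c1 * n * st$N_av / cfg$V,
                 assembly_propensity(st, 1, core, cfg))
  }
})

test_that("nuclear radius-count geometry gives the square and cube root laws", {
  sp <- nucleus_spec("NE_surface")
  sc <- nucleus_scaling_exponent(sp, t_max = 120, seed = 2)
  expect_lt(abs(sc$slope - 0.5), 0.02)
  spv <- nucleus_spec("NP_volume")
  scv <- nucleus_scaling_exponent(spv, t_max = 120, seed = 3)
  expect_lt(abs(scv$slope - 1 / 3), 0.02)
})

test_that("nucleus size falls with nuclei number sharing the pools", {
  cs <- nucleus_count_sweep(nucleus_spec("NE_surface"), c(1, 2, 4),
                            t_max = 120, seed = 2)
  expect_true(all(diff(cs$R_n) < 0))
})

test_that("confinement shrinks the nucleus and saturates at the aster size", {
  sp <- nucleus_spec("NE_surface")
  cs <- nucleus_confinement_sweep(sp, c(5, 10, 20, 30, Inf),
                                  t_max = 150, seed = 4)
  expect_true(all(diff(cs$R_n) > -0.05))  # monotone up to noise
  expect_lt(cs$R_n[1], 0.6 * cs$R_n[5])
  # flat beyond saturation: the wall is past the unconfined Lbar + R_n
  expect_lt(abs(cs$R_n[4] / cs$R_n[5] - 1), 0.05)
})

test_that("nucleoplasm-regulated nuclear volume scales linearly with cell volume", {
  cc <- nucleus_cell_scaling(nucleus_spec("NP_volume"),
                             V_grid = c(50, 100, 200, 400),
                             t_max = 120, seed = 6)
  expect_lt(abs(cc$exponent - 1), 0.05)
  # envelope-regulated growth is super-linear in comparison
  ne <- nucleus_cell_scaling(nucleus_spec("NE_surface"),
                             V_grid = c(50, 100, 200, 400),
                             t_max = 120, seed = 6)
  expect_gt(ne$exponent, 1.3)
  expect_true(all(diff(ne$data$V_n) > 0))
})
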