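#' Convert a concentration to a subunit count
#'
#' Single conversion point for turning printed concentrations into discrete
#' pool sizes: `N = conc * 602.214 * V` for micromolar input (1 uM =
#' 602.214 molecules per cubic micron), or `N = conc * V` when the
#' concentration is already a number density per cubic micron.
#'
#' @param conc Concentration.
#' @param V Volume in cubic microns.
#' @param unit `"uM"` or `"per_um3"`.
#' @return Integer subunit count (rounded).
#' @export
conc_to_count <- function(conc, V, unit = c("uM", "per_um3")) {
  unit <- match.arg(unit)
  factor <- if (unit == "uM") 602.214 else 1
  round(conc * factor * V)
}

# ---------------------------------------------------------------------------
# Flagella: balance-point model, (alpha, beta) = (1, 0)
# ---------------------------------------------------------------------------

#' Flagellar length-control model specification
#'
#' Balance-point model of `M` flagella growing from a shared tubulin pool.
#' Intraflagellar transport keeps the total amount of IFT particles per
#' flagellum constant, so the tip delivery rate - and hence assembly - falls
#' off inversely with length: feedback exponents `(alpha, beta) = (1, 0)`.
#' Lengths in microns are `n_i * subunit_size`.
#'
#' Defaults follow the biflagellate regrowth setting: 5 uM tubulin, a 10 nm
#' tubulin step per subunit, `k+ = 120 um^3/min`, `k- = 100 /min`,
#' amputation at `t0 = 1000 min`, and subunit production rate
#' `r_p = 0.0016 /min`.  The effective compartment volume defaults to
#' 1 um^3, which puts the two-flagella steady length near 10 um.
#'
#' @param M Number of flagella.
#' @param tubulin_conc Tubulin concentration (uM).
#' @param subunit_size Length added per tubulin subunit (um).
#' @param k_plus,k_minus Bare rates (um^3/min, 1/min).
#' @param V Compartment volume (um^3).
#' @param t0 Amputation time (min) for the regrowth protocol.
#' @param r_p Subunit production rate (1/min).
#' @return A `flagella_spec` object (includes the derived pool size `N`).
#' @export
flagella_spec <- function(M = 2, tubulin_conc = 5, subunit_size = 0.01,
                          k_plus = 120, k_minus = 100, V = 1,
                          t0 = 1000, r_p = 0.0016) {
  N <- conc_to_count(tubulin_conc, V, "uM")
  structure(list(M = as.integer(M), tubulin_conc = tubulin_conc,
                 subunit_size = subunit_size, k_plus = k_plus,
                 k_minus = k_minus, V = V, t0 = t0, r_p = r_p, N = N),
            class = "flagella_spec")
}

flagella_sim_spec <- function(spec, t_max, seed, record = "every_event",
                              init = NULL, t0 = 0, production = NULL) {
  cfg <- pool_config(N_total = spec$N, V = spec$V, M = spec$M)
  p <- feedback_params(alpha = 1, beta = 0,
                       k_plus = spec$k_plus, k_minus = spec$k_minus)
  simulation_spec(cfg, p, t_max = t_max, seed = seed, record = record,
                  init = init, t0 = t0, production = production)
}

#' Simulate flagellar length dynamics
#'
#' @param spec A [flagella_spec()].
#' @param t_max Simulated time (min).
#' @param seed RNG seed.
#' @param record Recording mode (see [simulation_spec()]).
#' @return A `trajectory` with an extra element `lengths` (um) mirroring
#'   `sizes`.
#' @export
flagella_simulate <- function(spec, t_max, seed = 1, record = "every_event") {
  tr <- gillespie_run(flagella_sim_spec(spec, t_max, seed, record))
  tr$lengths <- tr$sizes * spec$subunit_size
  tr
}

#' Amputation and regrowth protocol for two flagella
#'
#' Grows both flagella to steady state until `spec$t0`, then severs one:
#' its length is set to 0 and the lost subunits are removed from the total
#' pool (`N -> N - L2`).  A production channel with `Delta_N` equal to the
#' amputated amount then replenishes the pool at rate `r_p` (set
#' `production = FALSE` to model blocked protein synthesis, in which case
#' both flagella settle at a common shorter length).
#'
#' @param spec A [flagella_spec()] with `M = 2`.
#' @param t_max Total simulated time (min), beyond `spec$t0`.
#' @param seed RNG seed.
#' @param which Index of the flagellum to amputate.
#' @param production Logical; arm the production channel at `t0`.
#' @param record Recording mode for both phases.
#' @return A list with `pre` and `post` trajectories, `Delta_N` (subunits
#'   removed), and the pre-cut steady lengths.
#' @export
flagella_amputate <- function(spec, t_max, seed = 1, which = 2,
                              production = TRUE, record = 0.5) {
  stopifnot(spec$M == 2, t_max > spec$t0)
  pre <- gillespie_run(flagella_sim_spec(spec, spec$t0, seed, record))
  last <- nrow(pre$sizes)
  n_end <- pre$sizes[last, ]
  Delta_N <- n_end[which]
  init <- n_end
  init[which] <- 0
  spec_post <- spec
  spec_post$N <- spec$N - Delta_N
  post_sim <- flagella_sim_spec(
    spec_post, t_max, seed + 1L, record, init = init, t0 = spec$t0,
    production = if (production) list(r_p = spec$r_p, Delta_N = Delta_N) else NULL)
  post <- gillespie_run(post_sim)
  pre$lengths <- pre$sizes * spec$subunit_size
  post$lengths <- post$sizes * spec$subunit_size
  list(pre = pre, post = post, Delta_N = Delta_N,
       pre_cut_lengths = n_end * spec$subunit_size)
}

#' Symmetric steady-state flagellar length
#'
#' Root of `k+ (N - M n) / (V (1 + n)) = k-` (all flagella equal), i.e. the
#' positive solution of the quadratic balance condition.
#'
#' @param spec A [flagella_spec()].
#' @return Steady length in subunits.
#' @export
flagella_steady_state <- function(spec) {
  kappa <- spec$k_plus / spec$k_minus
  # kappa (N - M n) = V (1 + n)  =>  n = (kappa N - V) / (kappa M + V)
  max(0, (kappa * spec$N - spec$V) / (kappa * spec$M + spec$V))
}

#' Fit the subunit production rate to a length-vs-time table
#'
#' Generic one-parameter least-squares fit of the regrowth production rate
#' `r_p`: for each candidate rate the mean regrowth curve (the ODE limit of
#' the amputation protocol) is compared to user-supplied lengths.
#'
#' @param spec A [flagella_spec()] with `M = 2`.
#' @param data A data frame with columns `time` (min after amputation) and
#'   `length` (um) for the regrowing flagellum.
#' @param interval Search interval for `r_p` (1/min).
#' @return The fitted `r_p` (scalar).
#' @export
fit_production_rate <- function(spec, data, interval = c(1e-5, 1)) {
  stopifnot(all(c("time", "length") %in% names(data)))
  n_star <- flagella_steady_state(spec)
  model_curve <- function(r_p, times) {
    # deterministic amputation protocol: pre-cut steady state, cut at t=0
    cfg0 <- pool_config(N_total = spec$N, V = spec$V, M = 2)
    p <- feedback_params(1, 0, spec$k_plus, spec$k_minus)
    Delta_N <- n_star
    state <- c(n_star, 0, 0)  # n1, n2, deltaN
    f <- function(t, y, parms) {
      Neff <- spec$N - Delta_N + y[3]
      pool <- (Neff - y[1] - y[2]) / spec$V
      dn <- vapply(1:2, function(i) {
        on <- spec$k_plus * pool / (1 + y[i])
        off <- if (y[i] > 0) spec$k_minus else 0
        on - off
      }, numeric(1))
      list(c(dn, r_p * (Delta_N - y[3])))
    }
    out <- deSolve::ode(y = state, times = c(0, times), func = f, parms = NULL)
    out[-1, 3] * spec$subunit_size
  }
  obj <- function(r_p) sum((model_curve(r_p, data$time) - data$length)^2)
  stats::optimize(obj, interval)$minimum
}

# ---------------------------------------------------------------------------
# Centrosome: localized assembly, distributed disassembly, (0, 1)
# ---------------------------------------------------------------------------

#' Centrosome kinetic growth model specification
#'
#' PCM assembly is localized at the centriole (constant bare rate `k+`)
#' while disassembly occurs throughout the porous PCM volume (rate
#' `k- * n`), which maps exactly to feedback exponents
#' `(alpha, beta) = (0, 1)` and so guarantees robust size control of
#' multiple centrosomes.  Defaults follow the embryonic setting: 1.67 uM
#' PCM subunits, subunit volume `5.8e-7 um^3`, `k+ = 1e3 um^3/min`,
#' `k- = 1e-3 /min`, cell volume 5000 um^3.
#'
#' @param n_c Number of centrosomes.
#' @param subunit_conc PCM building-block concentration (uM).
#' @param subunit_volume Volume of one PCM building block (um^3).
#' @param k_plus,k_minus Bare rates.
#' @param V_cell Cell volume (um^3).
#' @return A `centrosome_spec`.
#' @export
centrosome_spec <- function(n_c = 2, subunit_conc = 1.67,
                            subunit_volume = 5.8e-7,
                            k_plus = 1e3, k_minus = 1e-3, V_cell = 5000) {
  N <- conc_to_count(subunit_conc, V_cell, "uM")
  structure(list(n_c = as.integer(n_c), subunit_conc = subunit_conc,
                 subunit_volume = subunit_volume, k_plus = k_plus,
                 k_minus = k_minus, V_cell = V_cell, N = N),
            class = "centrosome_spec")
}

#' Configure the core model for centrosome growth
#'
#' Exposes the `(0, 1)` mapping and its closed forms: single-centrosome
#' steady size `k+ N / (k+ + k- V)`, relaxation timescale
#' `(k+/V + k-)^-1`, and the `M`-centrosome steady size
#' `kappa N / (kappa M + V)`.
#'
#' @param spec A [centrosome_spec()].
#' @return A list with `params`, `cfg`, `steady_size_single`,
#'   `steady_size`, `relaxation_time`, and `volume_of(n)`.
#' @export
centrosome_model <- function(spec) {
  p <- feedback_params(alpha = 0, beta = 1,
                       k_plus = spec$k_plus, k_minus = spec$k_minus)
  cfg <- pool_config(N_total = spec$N, V = spec$V_cell, M = spec$n_c)
  kappa <- p$kappa
  list(params = p, cfg = cfg,
       steady_size_single = spec$k_plus * spec$N /
         (spec$k_plus + spec$k_minus * spec$V_cell),
       steady_size = kappa * spec$N / (kappa * spec$n_c + spec$V_cell),
       relaxation_time = 1 / (spec$k_plus / spec$V_cell + spec$k_minus),
       volume_of = function(n) n * spec$subunit_volume)
}

#' Simulate stochastic centrosome growth
#'
#' @param spec A [centrosome_spec()].
#' @param t_max Simulated time (min).
#' @param seed RNG seed.
#' @param record Recording mode.
#' @return A `trajectory` with an extra `volumes` element (um^3).
#' @export
centrosome_simulate <- function(spec, t_max, seed = 1, record = 0.1) {
  m <- centrosome_model(spec)
  tr <- gillespie_run(simulation_spec(m$cfg, m$params, t_max = t_max,
                                      seed = seed, record = record))
  tr$volumes <- tr$sizes * spec$subunit_volume
  tr
}

#' Centrosome volume versus cell volume at fixed concentration
#'
#' Sweeps the cell volume at fixed subunit concentration (so `N` scales
#' with `V_cell`) and returns the steady centrosome volume at each size,
#' measured from the stochastic model.
#'
#' @param spec A [centrosome_spec()] (its `V_cell` is replaced).
#' @param V_grid Cell volumes (um^3).
#' @param t_max Simulated time per point.
#' @param seed Base seed (one run per grid point, seeds `seed + 0:...`).
#' @return A data frame `V_cell`, `V_c` (mean steady centrosome volume).
#' @export
centrosome_scaling <- function(spec, V_grid, t_max = 30, seed = 1) {
  V_c <- vapply(seq_along(V_grid), function(k) {
    sp <- spec
    sp$V_cell <- V_grid[k]
    sp$N <- conc_to_count(sp$subunit_conc, sp$V_cell, "uM")
    tr <- centrosome_simulate(sp, t_max = t_max, seed = seed + k - 1)
    s <- trajectory_summary(tr, burn_in = 0.5 * t_max)
    s$means[1] * sp$subunit_volume
  }, numeric(1))
  data.frame(V_cell = V_grid, V_c = V_c)
}

# ---------------------------------------------------------------------------
# Liquid-liquid phase separation reduction
# ---------------------------------------------------------------------------

#' Droplet-growth parameters for the phase-separation model
#'
#' Reaction-limited growth of a centrosome treated as a liquid droplet:
#' centriole activity `Q` converts soluble material at the centriole,
#' rate `k` converts it autocatalytically inside the droplet, `k_BA` is the
#' back-conversion, `psi_minus` the (constant) droplet volume fraction of
#' the condensed form, `dv` the subunit volume.  Spontaneous condensation
#' away from the centriole is neglected (`k_AB = 0`).
#'
#' @param Q Centriole activity (condensed subunits per time per density).
#' @param k Autocatalytic conversion rate.
#' @param k_BA Back-conversion rate (1/time).
#' @param psi_minus Droplet volume fraction of the condensed form, in (0, 1].
#' @param dv Subunit volume.
#' @param N_tot Total PCM amount (subunits).
#' @param V_cell Cell volume.
#' @return An `llps_params` object.
#' @export
llps_params <- function(Q, k, k_BA, psi_minus, dv = 1,
                        N_tot = NULL, V_cell = 1) {
  if (!(psi_minus > 0 && psi_minus <= 1))
    stop("psi_minus must lie in (0, 1]")
  stopifnot(Q >= 0, k >= 0, k_BA > 0, dv > 0, V_cell > 0)
  structure(list(Q = Q, k = k, k_BA = k_BA, psi_minus = psi_minus,
                 dv = dv, N_tot = N_tot, V_cell = V_cell),
            class = "llps_params")
}

#' Reduce the droplet model to an effective size-dependent growth law
#'
#' The condensed subunit count obeys
#' `dn_B/dt = (C0 + C1 n_B) N_av / V_c - C2 n_B` with
#' `C0 = (1 - psi_minus) Q`, `C1 = (1 - psi_minus) k dv`, `C2 = k_BA`.
#' When the linear term dominates comparably to the constant one
#' (`C1 ~ C0`, closer to passive phase separation) the law matches the
#' power-law model with `(alpha, beta) = (-1, 1)` - on the degenerate
#' limiting-pool line, so multi-droplet size control fails.  When
#' `C0 >> C1` (growth dominated by centriole activity) the law reduces to
#' the centrosome kinetic model `(0, 1)` and size control is robust.
#'
#' @param p An [llps_params()].
#' @param robust_ratio `C1/C0` below which the regime is called robust
#'   (default 0.01); at or above `passive_ratio` (default 1) it is called
#'   `limiting_pool_line`; in between, `intermediate`.
#' @param passive_ratio See `robust_ratio`.
#' @return A list with `C0`, `C1`, `C2`, the ratio, `effective_regime`,
#'   and `rhs(n_B, N_av)` - the reduced growth law for use with the ODE
#'   module.
#' @export
llps_reduce <- function(p, robust_ratio = 0.01, passive_ratio = 1) {
  stopifnot(inherits(p, "llps_params"))
  C0 <- (1 - p$psi_minus) * p$Q
  C1 <- (1 - p$psi_minus) * p$k * p$dv
  C2 <- p$k_BA
  ratio <- if (C0 > 0) C1 / C0 else Inf
  regime <- if (C1 == 0) "robust_control"
  else if (ratio >= passive_ratio) "limiting_pool_line"
  else if (ratio <= robust_ratio) "robust_control"
  else "intermediate"
  list(C0 = C0, C1 = C1, C2 = C2, ratio = ratio,
       effective_regime = regime,
       rhs = function(n_B, N_av)
         (C0 + C1 * n_B) * N_av / p$V_cell - C2 * n_B)
}

#' Linear-assembly growth-law parameters
#'
#' A growth law with assembly propensity `(c0 + c1 n) N_av / V` and
#' disassembly `k_minus n` - the stochastic form of the reduced droplet
#' model.  The returned object plugs into [simulation_spec()] exactly like
#' [feedback_params()].
#'
#' @param c0,c1 Assembly coefficients (>= 0, not both 0).
#' @param k_minus Disassembly rate (> 0).
#' @return A `feedback_params` object flagged `linear = TRUE`.
#' @export
linear_assembly_params <- function(c0, c1, k_minus) {
  stopifnot(c0 >= 0, c1 >= 0, c0 + c1 > 0, k_minus > 0)
  p <- feedback_params(alpha = if (c1 > 0) -1 else 0, beta = 1,
                       k_plus = max(c0, c1), k_minus = k_minus)
  p$linear <- TRUE
  p$c0 <- c0
  p$c1 <- c1
  p
}

#' Simulate stochastic droplet growth under the reduced law
#'
#' @param p An [llps_params()] with `N_tot` set.
#' @param M Number of droplets.
#' @param t_max Simulated time.
#' @param seed RNG seed.
#' @param record Recording mode.
#' @return A `trajectory` of condensed subunit counts `n_B`.
#' @export
llps_simulate <- function(p, M = 1, t_max, seed = 1, record = "every_event") {
  stopifnot(!is.null(p$N_tot))
  red <- llps_reduce(p)
  lp <- linear_assembly_params(red$C0, red$C1, red$C2)
  cfg <- pool_config(N_total = p$N_tot, V = p$V_cell, M = M)
  gillespie_run(simulation_spec(cfg, lp, t_max = t_max, seed = seed,
                                record = record))
}
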