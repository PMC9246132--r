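#' Nucleus growth model specification
#'
#' Two-component model of nuclear size control: the nucleus (envelope or
#' nucleoplasm subunit count `n`) grows from its own limiting pool `N`,
#' with an assembly propensity proportional to the shell volume accessible
#' to a surrounding microtubule aster,
#' `K+ = k_plus * (4 pi / 3) ((Lbar + R_n)^3 - R_n^3) * (N - n) / V`,
#' and volume/surface-distributed disassembly `k_minus * n`.  The aster's
#' filaments grow from a separate tubulin pool `N_m` under the antenna law
#' (per-filament disassembly `km_minus * L_i`, assembly
#' `km_plus * (N_m - sum L) / V`), and are hindered by a confining wall:
#' filament assembly stops once `Lbar + R_n >= R_sys`.
#'
#' Geometry converts subunit count to nuclear radius: in `"NE_surface"`
#' mode `4 pi R_n^2 = n * dA` (spherical shell of constant thickness,
#' `R_n ~ n^(1/2)`); in `"NP_volume"` mode `(4 pi / 3) R_n^3 = n * dV_sub`
#' (solid sphere, `R_n ~ n^(1/3)`).
#'
#' Default rates and subunit sizes follow the egg-extract calibration:
#' NE subunit concentration 8 per um^3, `dA = 0.215 um^2`,
#' `k+ = 5e-3 um^3/min` (per unit accessible volume), `k- = 0.1 /min`;
#' NP mode uses concentration 0.75 per um^3 and `dV_sub = 0.1 um^3` with
#' `k+ = 2 um^3/min`, `k- = 1e-3 /min`; tubulin at 0.67 uM with a 5 nm
#' step, `km+ = 2 um^3/min`, `km- = 0.01 /min`.  The system volume
#' defaults to 100 um^3 with 10 aster filaments, which keeps pool sizes in
#' the 10^3-10^4 range.
#'
#' @param growth_mode `"NE_surface"` or `"NP_volume"`.
#' @param V System volume (um^3).
#' @param subunit_conc Nuclear subunit concentration (per um^3); default
#'   depends on the mode.
#' @param dsub Subunit area (um^2, NE mode) or volume (um^3, NP mode).
#' @param k_plus,k_minus Nuclear assembly/disassembly rates.
#' @param num_filaments Number of aster microtubules.
#' @param mt_conc Tubulin concentration (uM).
#' @param dL Tubulin step length (um).
#' @param km_plus,km_minus Filament rates.
#' @param R_sys Confinement radius (um); `Inf` for unconfined.
#' @param n_nuclei Number of nuclei sharing the two pools.
#' @return A `nucleus_spec`.
#' @export
nucleus_spec <- function(growth_mode = c("NE_surface", "NP_volume"),
                         V = 100,
                         subunit_conc = NULL, dsub = NULL,
                         k_plus = NULL, k_minus = NULL,
                         num_filaments = 10, mt_conc = 0.67, dL = 0.005,
                         km_plus = 2, km_minus = 0.01, R_sys = Inf,
                         n_nuclei = 1) {
  growth_mode <- match.arg(growth_mode)
  if (growth_mode == "NE_surface") {
    subunit_conc <- subunit_conc %||% 8
    dsub <- dsub %||% 0.215
    k_plus <- k_plus %||% 5e-3
    k_minus <- k_minus %||% 0.1
  } else {
    subunit_conc <- subunit_conc %||% 0.75
    dsub <- dsub %||% 0.1
    k_plus <- k_plus %||% 2
    k_minus <- k_minus %||% 1e-3
  }
  N <- conc_to_count(subunit_conc, V, "per_um3")
  Nm <- conc_to_count(mt_conc, V, "uM")
  structure(list(growth_mode = growth_mode, V = V,
                 subunit_conc = subunit_conc, dsub = dsub,
                 k_plus = k_plus, k_minus = k_minus,
                 num_filaments = as.integer(num_filaments),
                 mt_conc = mt_conc, dL = dL,
                 km_plus = km_plus, km_minus = km_minus,
                 R_sys = R_sys, n_nuclei = as.integer(n_nuclei),
                 N = N, N_m = Nm),
            class = "nucleus_spec")
}

#' Nuclear radius from subunit count
#'
#' @param n Subunit count.
#' @param spec A [nucleus_spec()].
#' @return Radius in um under the spec's geometry.
#' @export
nucleus_radius <- function(n, spec) {
  if (spec$growth_mode == "NE_surface") sqrt(n * spec$dsub / (4 * pi))
  else (3 * n * spec$dsub / (4 * pi))^(1 / 3)
}

#' Simulate stochastic nucleus growth coupled to a microtubule aster
#'
#' Exact Gillespie simulation of the coupled nucleus-plus-aster system (see
#' [nucleus_spec()] for the propensities and the confinement rule).
#'
#' @param spec A [nucleus_spec()].
#' @param t_max Simulated time (min).
#' @param seed RNG seed.
#' @param record Recording mode: `"every_event"` or a thinning interval.
#' @return A `nucleus_trajectory`: `times`, and one column per nucleus in
#'   `n`, `R_n` (um), and `Lbar` (that nucleus's mean filament length, um).
#' @export
nucleus_simulate <- function(spec, t_max, seed = 1, record = 0.5) {
  if (is.finite(spec$R_sys) && spec$R_sys <= 0)
    stop("R_sys must be positive")
  record_dt <- if (identical(record, "every_event")) -1 else as.numeric(record)
  geometry <- if (spec$growth_mode == "NE_surface") 0L else 1L
  if (is.finite(spec$R_sys) && nucleus_radius(0, spec) >= spec$R_sys)
    stop("confinement radius smaller than the initial nucleus")
  set.seed(seed)
  raw <- ssa_nucleus_cpp(spec$n_nuclei, spec$num_filaments,
                         spec$N, spec$N_m, spec$V,
                         spec$k_plus, spec$k_minus,
                         spec$km_plus, spec$km_minus,
                         geometry, spec$dsub, spec$dL,
                         spec$R_sys, t_max, record_dt)
  structure(c(raw, list(spec = spec)), class = "nucleus_trajectory")
}

#' @export
print.nucleus_trajectory <- function(x, ...) {
  k <- length(x$times)
  cat(sprintf("<nucleus_trajectory> %d nuclei, %d records, final R_n = %.3g um, Lbar = %.3g um\n",
              ncol(x$n), k, x$R_n[k, 1], x$Lbar[k, 1]))
  invisible(x)
}

nucleus_steady <- function(spec, t_max, seed, frac = 0.5) {
  tr <- nucleus_simulate(spec, t_max, seed)
  keep <- tr$times >= (1 - frac) * t_max
  list(n = mean(tr$n[keep, ]), R_n = mean(tr$R_n[keep, ]),
       Lbar = mean(tr$Lbar[keep, ]))
}

#' Steady nucleus size versus nuclei number at fixed pools
#'
#' Multiple nuclei assembled from one limiting pool partition it, so the
#' steady radius decreases as the nuclei count rises.
#'
#' @param spec A [nucleus_spec()] (its `n_nuclei` is replaced).
#' @param n_nuclei_grid Nuclei counts.
#' @param t_max Simulated time per point.
#' @param seed Base RNG seed.
#' @return A data frame `n_nuclei`, `R_n` (mean steady radius over nuclei).
#' @export
nucleus_count_sweep <- function(spec, n_nuclei_grid, t_max = 150, seed = 1) {
  rows <- lapply(seq_along(n_nuclei_grid), function(k) {
    sp <- spec
    sp$n_nuclei <- as.integer(n_nuclei_grid[k])
    st <- nucleus_steady(sp, t_max, seed + k - 1)
    data.frame(n_nuclei = n_nuclei_grid[k], R_n = st$R_n)
  })
  do.call(rbind, rows)
}

#' Radius-count scaling exponent across a pool-size sweep
#'
#' Runs the stochastic model over a sweep of nuclear subunit pool sizes
#' (concentration scaled by `factor_grid`) and fits
#' `log R_n* ~ log n*`: surface (NE) growth gives slope 1/2, volume (NP)
#' growth 1/3.
#'
#' @param spec A [nucleus_spec()].
#' @param factor_grid Multiplicative factors applied to the subunit
#'   concentration.
#' @param t_max Simulated time per point.
#' @param seed Base RNG seed.
#' @return A list with the fitted `slope` and the sweep data frame.
#' @export
nucleus_scaling_exponent <- function(spec, factor_grid = c(0.5, 1, 2, 4),
                                     t_max = 150, seed = 1) {
  rows <- lapply(seq_along(factor_grid), function(k) {
    sp <- spec
    sp$subunit_conc <- spec$subunit_conc * factor_grid[k]
    sp$N <- conc_to_count(sp$subunit_conc, sp$V, "per_um3")
    st <- nucleus_steady(sp, t_max, seed + k - 1)
    data.frame(factor = factor_grid[k], n_star = st$n, R_star = st$R_n)
  })
  df <- do.call(rbind, rows)
  slope <- coef(lm(log(R_star) ~ log(n_star), data = df))[2]
  list(slope = unname(slope), data = df)
}

#' Nucleus size versus confinement radius
#'
#' Sweeps the confinement radius at otherwise fixed conditions.  The
#' steady nuclear radius increases with `R_sys` and saturates once the
#' confinement exceeds the unconfined steady `Lbar + R_n` (aster size sets
#' the maximum nucleus size).
#'
#' @param spec A [nucleus_spec()].
#' @param R_sys_grid Confinement radii (um; may include `Inf`).
#' @param t_max Simulated time per point.
#' @param seed Base RNG seed.
#' @return A data frame `R_sys`, `R_n`, `Lbar`.
#' @export
nucleus_confinement_sweep <- function(spec, R_sys_grid, t_max = 150, seed = 1) {
  rows <- lapply(seq_along(R_sys_grid), function(k) {
    sp <- spec
    sp$R_sys <- R_sys_grid[k]
    st <- nucleus_steady(sp, t_max, seed + k - 1)
    data.frame(R_sys = R_sys_grid[k], R_n = st$R_n, Lbar = st$Lbar)
  })
  do.call(rbind, rows)
}

#' Nucleus-to-cell volume scaling exponent
#'
#' Sweeps the cell volume at fixed subunit concentrations (all pools scale
#' with `V`) and fits `log V_n ~ log V_cell`.  Nucleoplasm-regulated growth
#' gives exponent ~1 (`V_n` proportional to cell volume); envelope-regulated
#' growth gives a super-linear exponent, since `V_n ~ n^(3/2)` under surface
#' geometry.  The measured exponent is reported rather than asserted.
#'
#' @param spec A [nucleus_spec()].
#' @param V_grid Cell volumes (um^3).
#' @param t_max Simulated time per point.
#' @param seed Base RNG seed.
#' @return A list with `exponent` and the sweep data frame.
#' @export
nucleus_cell_scaling <- function(spec, V_grid, t_max = 150, seed = 1) {
  rows <- lapply(seq_along(V_grid), function(k) {
    sp <- spec
    sp$V <- V_grid[k]
    sp$N <- conc_to_count(sp$subunit_conc, sp$V, "per_um3")
    sp$N_m <- conc_to_count(sp$mt_conc, sp$V, "uM")
    st <- nucleus_steady(sp, t_max, seed + k - 1)
    V_n <- (4 * pi / 3) * st$R_n^3
    data.frame(V_cell = V_grid[k], n_star = st$n, V_n = V_n)
  })
  df <- do.call(rbind, rows)
  expo <- coef(lm(log(V_n) ~ log(V_cell), data = df))[2]
  list(exponent = unname(expo), data = df)
}
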