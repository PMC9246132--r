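#' Residence times in the branches of a bistable trajectory
#'
#' Assigns each sample of a trajectory to a "low" or "high" size state with
#' two-threshold hysteresis on the occupied pool fraction: the high state
#' is entered when `n_i / N_current >= hi_frac` and the low state when
#' `<= lo_frac`; in between, the previous state persists, which suppresses
#' spurious switch counts from small fluctuations.  Dwell times are
#' measured between confirmed switches.
#'
#' @param tr A `trajectory`.
#' @param i Structure index.
#' @param lo_frac,hi_frac Hysteresis thresholds, `0 < lo < hi < 1`.
#' @param burn_in Time discarded from the start (default: the spec's).
#' @return A `residence_stats` object: `tau_R` (mean dwell over completed
#'   dwells, or the censored lower bound), `dwells`, `n_transitions`,
#'   `censored` flag, and the thresholds used.
#' @export
residence_times <- function(tr, i = 1, lo_frac = 0.25, hi_frac = 0.75,
                            burn_in = NULL) {
  stopifnot(inherits(tr, "trajectory"), lo_frac > 0, hi_frac < 1,
            lo_frac < hi_frac)
  if (is.null(burn_in)) burn_in <- tr$spec$burn_in
  keep <- tr$times >= tr$times[1] + burn_in
  times <- tr$times[keep]
  frac <- tr$sizes[keep, i] / pmax(tr$N_total[keep], 1)
  state <- integer(length(frac))  # 0 unknown, 1 low, 2 high
  cur <- 0L
  for (k in seq_along(frac)) {
    if (frac[k] >= hi_frac) cur <- 2L
    else if (frac[k] <= lo_frac) cur <- 1L
    state[k] <- cur
  }
  switch_idx <- which(diff(state) != 0 & state[-length(state)] != 0L)
  dwells <- if (length(switch_idx) >= 2) diff(times[switch_idx + 1]) else numeric(0)
  n_transitions <- length(switch_idx)
  censored <- length(dwells) == 0
  tau <- if (censored) {
    # no completed dwell: elapsed observation time is a lower bound
    times[length(times)] - times[1]
  } else mean(dwells)
  structure(list(tau_R = tau, dwells = dwells,
                 n_transitions = n_transitions, censored = censored,
                 lo_frac = lo_frac, hi_frac = hi_frac),
            class = "residence_stats")
}

#' @export
print.residence_stats <- function(x, ...) {
  cat(sprintf("<residence_stats> tau_R %s %.4g (%d transitions)\n",
              if (x$censored) ">=" else "=", x$tau_R, x$n_transitions))
  invisible(x)
}

#' First-passage time across a pool-fraction threshold
#'
#' Time from the start of a trajectory until structure `i` first crosses
#' `threshold_frac` of the current total pool in the given direction.  Used
#' to measure the residence of the large-size branch directly: initialize
#' the run in the high state and take the first downward passage.
#'
#' @param tr A `trajectory`.
#' @param i Structure index.
#' @param threshold_frac Pool fraction defining the crossing.
#' @param direction `"down"` (first time at or below) or `"up"`.
#' @return A list with `time` (censored at the trajectory end when no
#'   crossing occurs) and `censored`.
#' @export
first_passage_time <- function(tr, i = 1, threshold_frac = 0.25,
                               direction = c("down", "up")) {
  direction <- match.arg(direction)
  stopifnot(inherits(tr, "trajectory"))
  frac <- tr$sizes[, i] / pmax(tr$N_total, 1)
  hit <- if (direction == "down") frac <= threshold_frac else frac >= threshold_frac
  k <- which(hit)[1]
  if (is.na(k))
    list(time = tr$times[length(tr$times)] - tr$times[1], censored = TRUE)
  else
    list(time = tr$times[k] - tr$times[1], censored = FALSE)
}

#' Classify the dynamic growth state of a single structure
#'
#' Deterministic decision rule evaluated on the exact stationary size
#' distribution: two or more modes means `bistable`; a single mode at small
#' size (`n <= 2`) means `no_growth` when the distribution is close to the
#' mean-matched geometric (discrete exponential) law - total variation
#' below `exp_tol` - and `shoulder` when it deviates from it (excess mass
#' pushed into a long upper tail that has not yet split into a second
#' mode); a single mode at larger size is `monostable_large`.  All
#' measured quantities and thresholds are surfaced in the returned record.
#'
#' @param p A [feedback_params()].
#' @param N Pool size.
#' @param V Volume.
#' @param exp_tol Total-variation threshold against the mean-matched
#'   geometric law separating `no_growth` from `shoulder`.
#' @return A `dynamic_state` object with `value` and `criteria_record`.
#' @export
classify_dynamic_state <- function(p, N, V = 1, exp_tol = 0.02) {
  d <- stationary_single(p, N, V)
  n_modes <- count_modes(d)
  mode_at <- d$support[which.max(d$probs)]
  # mean-matched geometric reference, the discrete exponential P(n) ~ q^n
  q <- d$mean / (1 + d$mean)
  geo <- (1 - q) * q^d$support
  tv_exp <- sum(abs(d$probs - geo / sum(geo))) / 2
  value <- if (n_modes >= 2) "bistable"
  else if (mode_at <= 2 && tv_exp < exp_tol) "no_growth"
  else if (mode_at <= 2) "shoulder"
  else "monostable_large"
  structure(list(value = value,
                 criteria_record = list(modes = n_modes, mode_at = mode_at,
                                        cv = d$cv, tv_exponential = tv_exp,
                                        exp_tol = exp_tol)),
            class = "dynamic_state")
}

#' @export
print.dynamic_state <- function(x, ...) {
  cat(sprintf("<dynamic_state> %s (modes=%d, cv=%.3g, tv_exp=%.3g)\n",
              x$value, x$criteria_record$modes, x$criteria_record$cv,
              x$criteria_record$tv_exponential))
  invisible(x)
}

#' State diagram over a grid of growth rates and feedback strengths
#'
#' @param kappa_grid Growth rates.
#' @param alpha_grid Assembly feedback exponents (typically negative).
#' @param beta Disassembly exponent (fixed, default 0).
#' @param N Pool size.
#' @param V Volume.
#' @return A data frame `kappa`, `alpha`, `state`.
#' @export
state_diagram <- function(kappa_grid, alpha_grid, beta = 0, N = 50, V = 1) {
  grid <- expand.grid(kappa = kappa_grid, alpha = alpha_grid)
  grid$state <- mapply(function(k, a) {
    classify_dynamic_state(feedback_params(a, beta, k_plus = k, k_minus = 1),
                           N, V)$value
  }, grid$kappa, grid$alpha)
  grid
}

#' Coexistence phase map for two competing structures
#'
#' Two structures coexist when both stationary marginal means exceed one
#' subunit.  The map is computed from the exact two-structure joint
#' distribution over a grid of the first structure's growth rate and the
#' shared feedback sum `alpha + beta`.
#'
#' @param kappa1_grid Growth rates of structure 1.
#' @param s_grid Values of `alpha + beta` (shared by both structures).
#' @param kappa2 Growth rate of structure 2.
#' @param N Pool size.
#' @param V Volume.
#' @return A data frame `kappa1`, `s`, `mean1`, `mean2`, `coexist`.
#' @export
coexistence_phase <- function(kappa1_grid, s_grid, kappa2 = 2, N = 50, V = 1) {
  grid <- expand.grid(kappa1 = kappa1_grid, s = s_grid)
  res <- mapply(function(k1, s) {
    p1 <- feedback_params(alpha = 0, beta = s, k_plus = k1, k_minus = 1)
    p2 <- feedback_params(alpha = 0, beta = s, k_plus = kappa2, k_minus = 1)
    j <- stationary_joint_two(p1, p2, N, V)
    c(marginalize(j, 1)$mean, marginalize(j, 2)$mean)
  }, grid$kappa1, grid$s)
  grid$mean1 <- res[1, ]
  grid$mean2 <- res[2, ]
  grid$coexist <- grid$mean1 > 1 & grid$mean2 > 1
  grid
}

#' Stationary size correlation of two competing structures
#'
#' Holding-time weighted Pearson correlation of `(n_1, n_2)` after
#' burn-in.  Strongly negative values are the signature of the degenerate
#' limiting-pool line, where the structures trade subunits.
#'
#' @param tr A `trajectory` with `M = 2`.
#' @param burn_in Time discarded from the start (default: the spec's).
#' @return Correlation in `[-1, 1]`, or `NA` when either size has zero
#'   variance.
#' @export
anticorrelation <- function(tr, burn_in = NULL) {
  stopifnot(inherits(tr, "trajectory"), ncol(tr$sizes) == 2)
  s <- trajectory_summary(tr, burn_in)
  s$correlation[1, 2]
}

#' Exact size correlation from the two-structure joint distribution
#'
#' @param j A `joint_dist`.
#' @return Pearson correlation of `(n1, n2)` under the exact law.
#' @export
joint_correlation <- function(j) {
  stopifnot(inherits(j, "joint_dist"))
  n <- 0:j$N
  p1 <- rowSums(j$probs); p2 <- colSums(j$probs)
  m1 <- sum(n * p1); m2 <- sum(n * p2)
  v1 <- sum((n - m1)^2 * p1); v2 <- sum((n - m2)^2 * p2)
  e12 <- sum(outer(n, n) * j$probs)
  (e12 - m1 * m2) / sqrt(v1 * v2)
}

#' Stochastic selection of a single dominant structure
#'
#' Under net positive feedback at high subunit abundance, one structure is
#' stochastically selected and takes essentially the whole consumed pool,
#' while its competitors die out - a minimal model of polarity
#' establishment.  Runs the simulator over many seeds and scores, per run,
#' the identity of the dominant structure (more than half of all
#' incorporated subunits at the final time) and whether a single dominant
#' structure exists.
#'
#' @param M Number of structures.
#' @param p A [feedback_params()] shared by all structures.
#' @param N Pool size.
#' @param V Volume.
#' @param t_max Simulated time per run.
#' @param seeds Integer vector of seeds (one run each).
#' @param record Thinning interval for the runs.
#' @return A `polarity_stats` object: per-seed `winner` (`NA` when no
#'   structure dominates), `dominance` (winner's share of incorporated
#'   subunits), and the fraction of runs with a single dominant structure.
#' @export
polarity_selection <- function(M, p, N, V = 1, t_max = 100,
                               seeds = 1:50, record = NULL) {
  cfg <- pool_config(N_total = N, V = V, M = M)
  if (is.null(record)) record <- t_max / 400
  winner <- integer(length(seeds))
  dominance <- numeric(length(seeds))
  for (k in seq_along(seeds)) {
    tr <- gillespie_run(simulation_spec(cfg, p, t_max = t_max,
                                        seed = seeds[k], record = record))
    final <- tr$sizes[nrow(tr$sizes), ]
    consumed <- sum(final)
    if (consumed == 0) { winner[k] <- NA_integer_; next }
    shares <- final / consumed
    w <- which.max(shares)
    dominance[k] <- shares[w]
    winner[k] <- if (shares[w] > 0.5) w else NA_integer_
  }
  structure(list(winner = winner, dominance = dominance,
                 frac_single_winner = mean(!is.na(winner)),
                 seeds = seeds),
            class = "polarity_stats")
}

#' @export
print.polarity_stats <- function(x, ...) {
  cat(sprintf("<polarity_stats> single winner in %.0f%% of %d runs\n",
              100 * x$frac_single_winner, length(x$seeds)))
  invisible(x)
}
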