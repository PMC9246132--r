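#' Specification of one stochastic simulation run
#'
#' Collects everything a Gillespie run needs: the pool configuration, one
#' [feedback_params()] per structure, a stopping rule (`t_max` or
#' `max_events`, exactly one), the RNG seed, the recording mode, and the
#' optional subunit-production and cell-growth channels.
#'
#' The production channel fires with propensity `r_p * (Delta_N - delta_N)`,
#' where `delta_N` counts subunits produced since activation; each firing
#' adds one subunit to the available pool, so the expected cumulative
#' production follows `Delta_N * (1 - exp(-r_p * t))`.  The cell-growth
#' channel fires at constant rate `g`; each firing adds one subunit to the
#' pool and `dV` to the volume, so `E[N(t)] = N0 + g t` and
#' `E[V(t)] = V0 + g dV t` (a linearly growing cell, made stochastic as a
#' unit-Poisson channel to keep the simulation exact).
#'
#' @param cfg A [pool_config()].
#' @param params A single [feedback_params()] (recycled over `cfg$M`) or a
#'   list of `M` of them.
#' @param t_max Stop time (exclusive with `max_events`).
#' @param max_events Event-count stop (exclusive with `t_max`).
#' @param seed Integer RNG seed; fixed before any draw.
#' @param record `"every_event"` or a positive number interpreted as the
#'   thinning interval `dt` of a regular sampling grid.
#' @param burn_in Burn-in time discarded by downstream stationary
#'   statistics; defaults to 20% of `t_max`.
#' @param production Optional `list(r_p=, Delta_N=)`.
#' @param growth Optional `list(g=, dV=)`.
#' @param init Initial sizes (default all zero).
#' @param t0 Start time (used when continuing a run).
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(cfg, params, t_max = NULL, max_events = NULL,
                            seed = 1, record = "every_event",
                            burn_in = NULL, production = NULL,
                            growth = NULL, init = NULL, t0 = 0) {
  if (inherits(params, "feedback_params")) params <- rep(list(params), cfg$M)
  stopifnot(length(params) == cfg$M,
            all(vapply(params, inherits, logical(1), "feedback_params")))
  if (is.null(t_max) == is.null(max_events))
    stop("set exactly one of `t_max` or `max_events`")
  if (is.null(t_max)) t_max <- Inf
  if (is.null(max_events)) max_events <- Inf
  if (!is.null(production))
    stopifnot(production$r_p >= 0, production$Delta_N >= 0)
  if (!is.null(growth)) stopifnot(growth$g >= 0, growth$dV >= 0)
  if (is.null(init)) init <- rep(0, cfg$M)
  stopifnot(length(init) == cfg$M, all(init >= 0))
  if (is.null(burn_in))
    burn_in <- if (is.finite(t_max)) 0.2 * (t_max - t0) else 0
  structure(list(cfg = cfg, params = params, t_max = t_max,
                 max_events = max_events, seed = as.integer(seed),
                 record = record, burn_in = burn_in,
                 production = production, growth = growth,
                 init = init, t0 = t0),
            class = "simulation_spec")
}

#' Run an exact Gillespie simulation
#'
#' Exact stochastic simulation of `M` structures competing for the
#' configured pool: waiting times `tau = log(1/r1) / sum(R)` and channel
#' selection by cumulative-propensity inversion with `r2`, with the two
#' uniforms drawn in that fixed order each step.  Channels are ordered
#' (assembly_1, disassembly_1, ..., assembly_M, disassembly_M), then the
#' optional production channel, then the optional growth channel.
#' Trajectories are bit-for-bit reproducible given the seed.
#'
#' @param spec A [simulation_spec()].
#' @return A `trajectory` object: `times`, `sizes` (matrix with one column
#'   per structure), `N_av`, `N_total`, `V`, `events` (event-recording mode
#'   only; 0 marks snapshots, `2i-1`/`2i` assembly/disassembly of structure
#'   `i`), `absorbed` flag, and the generating `spec`.
#' @examples
#' cfg <- pool_config(N_total = 50, V = 1, M = 1)
#' tr <- gillespie_run(simulation_spec(cfg, feedback_params(0, 0),
#'                                     t_max = 200, seed = 42))
#' @export
gillespie_run <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  cfg <- spec$cfg
  M <- cfg$M
  alpha <- vapply(spec$params, `[[`, numeric(1), "alpha")
  beta <- vapply(spec$params, `[[`, numeric(1), "beta")
  kplus <- vapply(spec$params, `[[`, numeric(1), "k_plus")
  kminus <- vapply(spec$params, `[[`, numeric(1), "k_minus")
  form <- vapply(spec$params, function(p) as.integer(isTRUE(p$linear)), integer(1))
  c0 <- vapply(spec$params, function(p) p$c0 %||% 0, numeric(1))
  c1 <- vapply(spec$params, function(p) p$c1 %||% 0, numeric(1))
  record_dt <- if (identical(spec$record, "every_event")) -1 else as.numeric(spec$record)
  mode <- if (cfg$mode == "limiting_pool") 0L else 1L
  N0 <- if (mode == 0L) cfg$N_total else sum(spec$init)
  set.seed(spec$seed)
  raw <- ssa_core_cpp(as.numeric(spec$init), N0, cfg$V,
                      alpha, beta, kplus, kminus,
                      mode, if (is.na(cfg$rho)) 0 else cfg$rho,
                      form, c0, c1,
                      spec$t0, spec$t_max, spec$max_events, record_dt,
                      if (is.null(spec$production)) 0 else spec$production$r_p,
                      if (is.null(spec$production)) 0 else spec$production$Delta_N,
                      if (is.null(spec$growth)) 0 else spec$growth$g,
                      if (is.null(spec$growth)) 0 else spec$growth$dV)
  colnames(raw$sizes) <- paste0("n_", seq_len(M))
  structure(list(times = raw$times, sizes = raw$sizes,
                 N_av = raw$N_av, N_total = raw$N_total, V = raw$V,
                 events = raw$events, absorbed = raw$absorbed,
                 n_events = raw$n_events, t_end = raw$t_end,
                 spec = spec),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d structures, %d records, t in [%.4g, %.4g]%s\n",
              ncol(x$sizes), length(x$times), x$times[1],
              x$times[length(x$times)],
              if (x$absorbed) " [absorbed]" else ""))
  invisible(x)
}

#' Run with the subunit-production channel active
#'
#' Convenience wrapper: attaches `production = list(r_p, Delta_N)` to the
#' spec and runs.  See [simulation_spec()] for the channel's law.
#'
#' @param spec A [simulation_spec()].
#' @param r_p Production rate (1/time).
#' @param Delta_N Total amount to be produced (subunits).
#' @return A `trajectory`.
#' @export
run_with_production <- function(spec, r_p, Delta_N) {
  spec$production <- list(r_p = r_p, Delta_N = Delta_N)
  gillespie_run(spec)
}

#' Run with the linear cell-growth channel active
#'
#' @param spec A [simulation_spec()].
#' @param g Growth rate: subunits (and volume increments) per unit time.
#' @param dV Volume added per growth event.
#' @return A `trajectory`.
#' @export
run_with_cell_growth <- function(spec, g, dV) {
  spec$growth <- list(g = g, dV = dV)
  gillespie_run(spec)
}

#' Occupancy-weighted stationary histogram from a trajectory
#'
#' Estimates the stationary size distribution of one structure from a
#' trajectory by weighting each visited state with its holding time (for
#' event-mode recordings) or with equal weights (for regular-grid thinned
#' recordings, where uniform time sampling is already occupancy-weighted).
#' Event-count histograms are biased and are deliberately not offered.
#'
#' @param tr A `trajectory`.
#' @param burn_in Time to discard from the start; defaults to the spec's.
#' @param i Structure index.
#' @return An empirical `stationary_dist` (support `0:max observed`).
#' @export
stationary_histogram <- function(tr, burn_in = NULL, i = 1) {
  stopifnot(inherits(tr, "trajectory"))
  if (is.null(burn_in)) burn_in <- tr$spec$burn_in
  t0 <- tr$times[1] + burn_in
  keep <- tr$times >= t0
  if (sum(keep) < 2) stop("no samples after burn-in")
  times <- tr$times[keep]
  n <- tr$sizes[keep, i]
  if (identical(tr$spec$record, "every_event")) {
    w <- diff(times)
    n <- n[-length(n)]
  } else {
    w <- rep(1, length(n))
  }
  if (sum(w) <= 0) stop("empty post-burn-in window")
  support <- 0:max(n)
  p <- vapply(support, function(k) sum(w[n == k]), numeric(1)) / sum(w)
  m <- moments_from_probs(support, p)
  structure(list(support = support, probs = p,
                 log_weights = log(p), log_normalizer = 0,
                 mean = m$mean, sd = m$sd, cv = m$cv,
                 params = list(empirical = TRUE, burn_in = burn_in)),
            class = "stationary_dist")
}

#' Total-variation distance between two discrete distributions
#'
#' @param d1,d2 `stationary_dist` objects (supports may differ; both are
#'   aligned on the union).
#' @return TV distance in `[0, 1]`.
#' @export
tv_distance <- function(d1, d2) {
  hi <- max(max(d1$support), max(d2$support))
  p <- q <- numeric(hi + 1)
  p[d1$support + 1] <- d1$probs
  q[d2$support + 1] <- d2$probs
  sum(abs(p - q)) / 2
}

#' Holding-time weighted summary statistics of a trajectory
#'
#' @param tr A `trajectory`.
#' @param burn_in Time discarded from the start (default: the spec's).
#' @return A list with per-structure `means`, `sds`, `cvs`, and the
#'   size correlation matrix.
#' @export
trajectory_summary <- function(tr, burn_in = NULL) {
  stopifnot(inherits(tr, "trajectory"))
  if (is.null(burn_in)) burn_in <- tr$spec$burn_in
  keep <- tr$times >= tr$times[1] + burn_in
  x <- tr$sizes[keep, , drop = FALSE]
  if (identical(tr$spec$record, "every_event")) {
    w <- diff(tr$times[keep])
    x <- x[-nrow(x), , drop = FALSE]
  } else {
    w <- rep(1, nrow(x))
  }
  w <- w / sum(w)
  mu <- colSums(x * w)
  xc <- sweep(x, 2, mu)
  cv <- t(xc) %*% (xc * w)
  sds <- sqrt(pmax(diag(cv), 0))
  corr <- cv / outer(sds, sds)
  corr[!is.finite(corr)] <- NA_real_
  list(means = mu, sds = sds,
       cvs = ifelse(mu > 0, sds / mu, Inf),
       correlation = corr)
}

#' Write a trajectory as tab-separated values
#'
#' Columns: `time`, `n_1 ... n_M`, `N_av`, `N_total`, `V`.
#'
#' @param tr A `trajectory`.
#' @param path Output file; `.gz` suffix gzips.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(tr, path) {
  df <- data.frame(time = tr$times, tr$sizes,
                   N_av = tr$N_av, N_total = tr$N_total, V = tr$V,
                   check.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
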