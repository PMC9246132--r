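#' Size-dependent growth law parameters
#'
#' Bundles the four parameters that define one structure's growth law: the
#' feedback exponents `alpha` (assembly) and `beta` (disassembly) and the bare
#' rates `k_plus` (volume/time) and `k_minus` (1/time).  The assembly
#' propensity of a structure of size `n` is
#' `k_plus * N_av * (1 + n)^-alpha / V` (limiting pool) and the disassembly
#' propensity is `k_minus * n^beta`, with disassembly set to zero at `n = 0`
#' so that sizes stay non-negative (this also regularizes the divergence for
#' `beta < 0`).  The derived ratio `kappa = k_plus / k_minus` is the net
#' growth rate that controls all stationary properties.
#'
#' @param alpha Feedback exponent on assembly (dimensionless).  `alpha > 0`
#'   means assembly slows as the structure grows (negative feedback).
#' @param beta Feedback exponent on disassembly.  `beta > 0` means
#'   disassembly accelerates with size (negative feedback).
#' @param k_plus Bare assembly rate (> 0), units volume/time.
#' @param k_minus Bare disassembly rate (> 0), units 1/time.
#' @return An object of class `feedback_params` with fields `alpha`, `beta`,
#'   `k_plus`, `k_minus`, and `kappa`.
#' @examples
#' p <- feedback_params(alpha = 0, beta = 1, k_plus = 1, k_minus = 1)
#' p$kappa
#' @export
feedback_params <- function(alpha = 0, beta = 0, k_plus = 1, k_minus = 1) {
  stopifnot(is.finite(alpha), is.finite(beta),
            is.finite(k_plus), k_plus > 0,
            is.finite(k_minus), k_minus > 0)
  structure(list(alpha = alpha, beta = beta,
                 k_plus = k_plus, k_minus = k_minus,
                 kappa = k_plus / k_minus),
            class = "feedback_params")
}

#' @export
print.feedback_params <- function(x, ...) {
  cat(sprintf("<feedback_params> alpha=%g beta=%g k+=%g k-=%g (kappa=%g, %s)\n",
              x$alpha, x$beta, x$k_plus, x$k_minus, x$kappa,
              classify_regime(x$alpha, x$beta)))
  invisible(x)
}

#' Global subunit-pool configuration
#'
#' Describes the shared resource pool from which `M` structures grow: either
#' a limiting pool of `N_total` subunits in volume `V` (conserved total:
#' `N = N_av + sum(n_i)`), or a pool held at a constant homeostatic
#' concentration `rho` (subunit exchange with an implicit reservoir).
#'
#' @param N_total Total subunit count (limiting-pool mode).
#' @param V System (cell) volume, > 0.
#' @param M Number of competing structures.
#' @param mode `"limiting_pool"` or `"constant_concentration"`.
#' @param rho Fixed subunit concentration; required in
#'   `"constant_concentration"` mode, unused otherwise.
#' @return An object of class `pool_config` with the derived overall density
#'   `rho0 = N_total / V` in limiting-pool mode.
#' @export
pool_config <- function(N_total = NULL, V = 1, M = 1,
                        mode = c("limiting_pool", "constant_concentration"),
                        rho = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.finite(V), V > 0, M >= 1, M == round(M))
  if (mode == "limiting_pool") {
    if (is.null(N_total))
      stop("limiting_pool mode requires `N_total`")
    stopifnot(is.finite(N_total), N_total >= 0, N_total == round(N_total))
    rho0 <- N_total / V
  } else {
    if (is.null(rho))
      stop("constant_concentration mode requires `rho`")
    stopifnot(is.finite(rho), rho >= 0)
    N_total <- NA_real_
    rho0 <- NA_real_
  }
  structure(list(N_total = N_total, V = V, M = as.integer(M),
                 mode = mode, rho = if (is.null(rho)) NA_real_ else rho,
                 rho0 = rho0),
            class = "pool_config")
}

#' @export
print.pool_config <- function(x, ...) {
  if (x$mode == "limiting_pool")
    cat(sprintf("<pool_config> limiting pool: N=%g V=%g M=%d (rho0=%g)\n",
                x$N_total, x$V, x$M, x$rho0))
  else
    cat(sprintf("<pool_config> constant concentration: rho=%g V=%g M=%d\n",
                x$rho, x$V, x$M))
  invisible(x)
}

#' Instantaneous system state
#'
#' @param sizes Integer vector of structure sizes `n_i >= 0`.
#' @param cfg A [pool_config()].
#' @param t Time (>= 0).
#' @param V_current,N_current Current volume and total pool; default to the
#'   configured values (they drift only under the cell-growth / production
#'   channels).
#' @return An object of class `system_state`; in limiting-pool mode `N_av` is
#'   derived from conservation `N_av = N_current - sum(sizes)`.
#' @export
system_state <- function(sizes, cfg, t = 0,
                         V_current = cfg$V, N_current = cfg$N_total) {
  stopifnot(all(sizes >= 0), t >= 0, V_current > 0)
  N_av <- NA_real_
  if (cfg$mode == "limiting_pool") {
    N_av <- N_current - sum(sizes)
    if (N_av < 0) stop("conservation violated: sum(sizes) exceeds N_current")
  }
  structure(list(t = t, sizes = sizes, N_av = N_av,
                 V_current = V_current, N_current = N_current),
            class = "system_state")
}

#' Assembly propensity of one structure
#'
#' `k_plus * N_av * (1 + n_i)^-alpha / V` in limiting-pool mode, or
#' `k_plus * rho * (1 + n_i)^-alpha` at constant concentration.  Returns 0
#' when the limiting pool is empty.
#'
#' @param state A [system_state()].
#' @param i Structure index (1-based).
#' @param p A [feedback_params()].
#' @param cfg A [pool_config()].
#' @return Non-negative propensity (1/time).
#' @export
assembly_propensity <- function(state, i, p, cfg) {
  n <- state$sizes[i]
  if (is.na(n) || n < 0) stop("invalid structure size")
  fb <- exp(-p$alpha * log1p(n))
  if (cfg$mode == "limiting_pool") {
    if (state$N_av < 0) stop("negative available pool")
    if (state$N_av == 0) return(0)
    p$k_plus * state$N_av * fb / state$V_current
  } else {
    p$k_plus * cfg$rho * fb
  }
}

#' Disassembly propensity of one structure
#'
#' `k_minus * n_i^beta` for `n_i >= 1` and exactly 0 at `n_i = 0` for any
#' `beta` (boundary rule; regularizes `beta < 0`).
#'
#' @inheritParams assembly_propensity
#' @return Non-negative propensity (1/time).
#' @export
disassembly_propensity <- function(state, i, p) {
  n <- state$sizes[i]
  if (is.na(n) || n < 0) stop("invalid structure size")
  if (n == 0) return(0)
  p$k_minus * n^p$beta
}

#' Classify the feedback regime from the exponents
#'
#' The sign of `alpha + beta` is the sole determinant of the qualitative
#' growth regime: positive sum means net negative feedback (robust size
#' control), zero puts the model on the degenerate limiting-pool line (no
#' individual size control), and a negative sum means net positive feedback
#' (autocatalytic growth and bistability).  The comparison is exact, with no
#' tolerance: the exponents are user inputs, not estimates.
#'
#' @param alpha,beta Finite feedback exponents.
#' @return One of `"negative_feedback"`, `"limiting_pool_line"`,
#'   `"positive_feedback"`.
#' @examples
#' classify_regime(0, 1)   # microtubule / centrosome point
#' classify_regime(0, 0)   # canonical limiting pool
#' classify_regime(-1, 0)  # autocatalytic
#' @export
classify_regime <- function(alpha, beta) {
  stopifnot(is.finite(alpha), is.finite(beta))
  s <- alpha + beta
  if (s > 0) "negative_feedback"
  else if (s == 0) "limiting_pool_line"
  else "positive_feedback"
}

#' Serialize model parameters to a flat key-value list
#'
#' @param p A [feedback_params()].
#' @param cfg A [pool_config()].
#' @return A named list with keys `alpha`, `beta`, `k_plus`, `k_minus`,
#'   `N_total`, `V`, `M`, `mode`, `rho`, suitable for YAML/JSON round trips
#'   via [params_from_list()].
#' @export
params_to_list <- function(p, cfg) {
  list(alpha = p$alpha, beta = p$beta,
       k_plus = p$k_plus, k_minus = p$k_minus,
       N_total = cfg$N_total, V = cfg$V, M = cfg$M,
       mode = cfg$mode, rho = cfg$rho)
}

#' Deserialize model parameters from a flat key-value list
#'
#' @param x A named list as produced by [params_to_list()] (or read from a
#'   YAML/JSON config block).
#' @return A list with elements `params` ([feedback_params()]) and `cfg`
#'   ([pool_config()]).
#' @export
params_from_list <- function(x) {
  p <- feedback_params(alpha = x$alpha %||% 0, beta = x$beta %||% 0,
                       k_plus = x$k_plus %||% 1, k_minus = x$k_minus %||% 1)
  mode <- x$mode %||% "limiting_pool"
  cfg <- pool_config(N_total = x$N_total, V = x$V %||% 1, M = x$M %||% 1,
                     mode = mode,
                     rho = if (identical(mode, "constant_concentration")) x$rho else NULL)
  list(params = p, cfg = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
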