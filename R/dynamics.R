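#' Mean-field growth rate of each structure
#'
#' Right-hand side of the deterministic rate equations,
#' `dn_i/dt = k_i+ (N - sum n_j) (1 + n_i)^-alpha_i / V - k_i- n_i^beta_i`
#' in limiting-pool mode, or the constant-concentration form with
#' `(N - sum n_j)/V` replaced by `rho`.  Sizes are treated as continuous
#' (continuum relaxation of the counts); these equations are the model's
#' approximate deterministic description, not the exact first moment of the
#' master equation.
#'
#' @param sizes Numeric vector of sizes (>= 0 componentwise).
#' @param params A [feedback_params()] or a list of `M` of them.
#' @param cfg A [pool_config()].
#' @return Numeric vector `dn/dt`.
#' @export
ode_rhs <- function(sizes, params, cfg) {
  if (inherits(params, "feedback_params")) params <- rep(list(params), length(sizes))
  stopifnot(length(params) == length(sizes))
  pool <- if (cfg$mode == "limiting_pool")
    (cfg$N_total - sum(sizes)) / cfg$V else cfg$rho
  vapply(seq_along(sizes), function(i) {
    p <- params[[i]]
    n <- max(sizes[i], 0)
    on <- p$k_plus * pool * exp(-p$alpha * log1p(n))
    off <- if (n > 0) p$k_minus * n^p$beta else 0
    on - off
  }, numeric(1))
}

# Analytic Jacobian of ode_rhs (limiting pool or constant concentration).
ode_jacobian <- function(sizes, params, cfg) {
  if (inherits(params, "feedback_params")) params <- rep(list(params), length(sizes))
  M <- length(sizes)
  limiting <- cfg$mode == "limiting_pool"
  pool <- if (limiting) (cfg$N_total - sum(sizes)) / cfg$V else cfg$rho
  J <- matrix(0, M, M)
  eps <- 1e-9  # domain floor for beta < 1 derivative terms
  for (i in seq_len(M)) {
    p <- params[[i]]
    n <- max(sizes[i], 0)
    fb <- exp(-p$alpha * log1p(n))
    if (limiting)
      J[i, ] <- J[i, ] - p$k_plus * fb / cfg$V  # pool depletion by any n_j
    dfb <- -p$alpha * exp(-(p$alpha + 1) * log1p(n))
    doff <- if (p$beta == 0) 0 else p$k_minus * p$beta * max(n, eps)^(p$beta - 1)
    J[i, i] <- J[i, i] + p$k_plus * pool * dfb - doff
  }
  J
}

#' Integrate the deterministic rate equations
#'
#' Adaptive stiff-capable integration (`deSolve::ode`, lsoda) of [ode_rhs()]
#' with sizes clipped at zero from below.
#'
#' @param init Non-negative initial sizes.
#' @param params A [feedback_params()] or list of them.
#' @param cfg A [pool_config()].
#' @param times Output time grid.
#' @param ... Passed to [deSolve::ode()] (e.g. `rtol`, `atol`).
#' @return A matrix with columns `time`, `n_1 ... n_M`, of class
#'   `deterministic_trajectory`.
#' @export
integrate_sizes <- function(init, params, cfg, times,
                            ...) {
  stopifnot(all(init >= 0))
  f <- function(t, y, parms) list(ode_rhs(pmax(y, 0), params, cfg))
  out <- deSolve::ode(y = as.numeric(init), times = times, func = f,
                      parms = NULL, rtol = 1e-10, atol = 1e-12, ...)
  out[, -1] <- pmax(out[, -1], 0)
  colnames(out) <- c("time", paste0("n_", seq_along(init)))
  class(out) <- c("deterministic_trajectory", class(out))
  out
}

#' Locate and classify fixed points of the rate equations
#'
#' Seeds a dense grid over the search box with candidate points where the
#' flow magnitude is locally minimal, polishes each by damped Newton
#' iteration using the analytic Jacobian, deduplicates the roots, and
#' classifies each by the Jacobian spectrum: `stable_node` (all real parts
#' < 0), `unstable_node` (all > 0), `saddle` (mixed), or `marginal` (an
#' eigenvalue with vanishing real part).  States with a coordinate pinned
#' at 0 are examined separately under the boundary rule (disassembly 0 at
#' size 0): where `beta < 0` these are reported as `boundary_regularized`.
#'
#' @param params A [feedback_params()] or list of `M` of them (`M <= 2` for
#'   the exhaustive grid; larger `M` should use a symmetric ansatz).
#' @param cfg A [pool_config()].
#' @param search_box `c(lo, hi)` per axis; default `[0, N]` (or `[0, 10 *
#'   kappa * rho]` at constant concentration).
#' @param n_grid Grid points per axis.
#' @return A list of `fixed_point` objects, each with `location`,
#'   `eigenvalues`, and `classification`.
#' @export
fixed_points <- function(params, cfg, search_box = NULL, n_grid = 200) {
  M <- cfg$M
  if (inherits(params, "feedback_params")) params <- rep(list(params), M)
  stopifnot(length(params) == M)
  if (M > 2) stop("exhaustive search supports M <= 2; use a symmetric ansatz")
  if (is.null(search_box)) {
    hi <- if (cfg$mode == "limiting_pool") cfg$N_total
    else 10 * max(vapply(params, `[[`, numeric(1), "kappa")) * cfg$rho + 10
    search_box <- c(0, hi)
  }
  axis <- seq(search_box[1], search_box[2], length.out = n_grid)
  f <- function(x) ode_rhs(x, params, cfg)
  J <- function(x) ode_jacobian(x, params, cfg)

  newton <- function(x0) {
    x <- x0
    for (it in 1:200) {
      fx <- f(x)
      if (sqrt(sum(fx^2)) < 1e-12) break
      step <- tryCatch(solve(J(x), fx), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lam <- 1
      repeat {
        xn <- x - lam * step
        if (all(xn >= -1e-9) && sqrt(sum(f(pmax(xn, 0))^2)) <= sqrt(sum(fx^2)))
          break
        lam <- lam / 2
        if (lam < 1e-8) return(NULL)
      }
      x <- pmax(xn, 0)
    }
    if (sqrt(sum(f(x)^2)) < 1e-9) x else NULL
  }

  seeds <- list()
  if (M == 1) {
    g <- vapply(axis, function(v) abs(f(v)), numeric(1))
    loc_min <- which(diff(sign(diff(c(Inf, g, Inf)))) == 2)
    seeds <- lapply(axis[loc_min], identity)
  } else {
    # vectorized flow magnitude on the grid
    n1 <- matrix(axis, n_grid, n_grid)
    n2 <- matrix(axis, n_grid, n_grid, byrow = TRUE)
    pool <- if (cfg$mode == "limiting_pool")
      (cfg$N_total - n1 - n2) / cfg$V else cfg$rho
    comp <- function(p, n) {
      on <- p$k_plus * pool * exp(-p$alpha * log1p(n))
      off <- ifelse(n > 0, p$k_minus * n^p$beta, 0)
      on - off
    }
    G <- comp(params[[1]], n1)^2 + comp(params[[2]], n2)^2
    pad <- matrix(Inf, n_grid + 2, n_grid + 2)
    pad[2:(n_grid + 1), 2:(n_grid + 1)] <- G
    is_min <- G <= Inf
    for (da in -1:1) for (db in -1:1) {
      if (da == 0 && db == 0) next
      is_min <- is_min &
        (G <= pad[(2 + da):(n_grid + 1 + da), (2 + db):(n_grid + 1 + db)])
    }
    idx <- which(is_min, arr.ind = TRUE)
    if (nrow(idx) > 400) idx <- idx[order(G[idx])[1:400], , drop = FALSE]
    seeds <- lapply(seq_len(nrow(idx)),
                    function(r) c(axis[idx[r, 1]], axis[idx[r, 2]]))
  }

  roots <- list()
  add_root <- function(x, boundary = FALSE) {
    for (r in roots) if (sqrt(sum((r$location - x)^2)) < 1e-6) return(invisible())
    ev <- eigen(J(x), only.values = TRUE)$values
    re <- Re(ev)
    cls <- if (boundary) "boundary_regularized"
    else if (any(abs(re) < 1e-8)) "marginal"
    else if (all(re < 0)) "stable_node"
    else if (all(re > 0)) "unstable_node"
    else "saddle"
    roots[[length(roots) + 1]] <<- structure(
      list(location = x, eigenvalues = ev, classification = cls),
      class = "fixed_point")
  }

  for (s in seeds) {
    r <- newton(s)
    if (!is.null(r) && all(r >= -1e-9) && all(r <= search_box[2] + 1e-6))
      add_root(pmax(r, 0))
  }

  # boundary states with one or more coordinates held at zero
  any_neg_beta <- any(vapply(params, `[[`, numeric(1), "beta") < 0)
  zero_sets <- if (M == 1) list(1L) else list(1L, 2L, c(1L, 2L))
  for (zs in zero_sets) {
    free <- setdiff(seq_len(M), zs)
    cand <- NULL
    if (length(free) == 0) {
      cand <- rep(0, M)
    } else {
      g1 <- function(v) {
        x <- rep(0, M); x[free] <- v
        ode_rhs(x, params, cfg)[free]
      }
      vals <- vapply(axis, function(v) g1(v), numeric(1))
      sc <- which(vals[-1] * vals[-length(vals)] <= 0)
      if (length(sc) > 0) {
        rt <- uniroot(g1, c(axis[sc[1]], axis[sc[1] + 1]), tol = 1e-12)$root
        cand <- rep(0, M); cand[free] <- rt
      }
    }
    if (is.null(cand)) next
    rhs0 <- ode_rhs(cand, params, cfg)
    # at a boundary point the zeroed coordinates obey the K_off(0) = 0 rule;
    # with beta < 0 the point is a regularized boundary state even though the
    # bare rate law diverges as n -> 0+
    if (any_neg_beta) add_root(cand, boundary = TRUE)
    else if (all(abs(rhs0) < 1e-9)) add_root(cand)
  }
  roots
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("<fixed_point> (%s): %s; Re(eig) = %s\n",
              paste(signif(x$location, 6), collapse = ", "),
              x$classification,
              paste(signif(Re(x$eigenvalues), 4), collapse = ", ")))
  invisible(x)
}

#' Closed-form steady-state size for the two tractable exponent pairs
#'
#' For `M` identical structures at fixed overall density `rho0 = N/V`:
#' the `(alpha, beta) = (0, 1)` model (constant assembly, volume-distributed
#' disassembly) has `n* = kappa rho0 V / (kappa M + V)`; the `(1, 0)` model
#' (antenna-limited assembly, constant disassembly) has
#' `n* = (kappa rho0 - 1) V / (kappa M + V)`, which is 0 (no growth) when
#' `kappa rho0 <= 1`.
#'
#' @param model `"01"` for `(alpha, beta) = (0, 1)` or `"10"` for `(1, 0)`.
#' @param kappa Net growth rate `k+/k-`.
#' @param rho0 Overall subunit density `N/V`.
#' @param V Volume.
#' @param M Number of structures.
#' @return Steady size `n*`; for `"10"` with `kappa * rho0 <= 1` returns 0
#'   with attribute `no_growth = TRUE`.
#' @export
steady_state_formula <- function(model = c("01", "10"), kappa, rho0, V, M) {
  model <- match.arg(model)
  stopifnot(kappa > 0, rho0 >= 0, V > 0, M >= 1)
  if (model == "01") {
    kappa * rho0 * V / (kappa * M + V)
  } else {
    if (kappa * rho0 <= 1)
      structure(0, no_growth = TRUE)
    else
      (kappa * rho0 - 1) * V / (kappa * M + V)
  }
}

#' Steady-size scaling sweep over system size
#'
#' Evaluates [steady_state_formula()] along a grid of volumes (or structure
#' counts) at fixed overall density `rho0`, tagging each point
#' `linear_scaling` when `kappa M > V` (size grows with the cell, `n* ~
#' rho0 V / M`) or `saturated` when `kappa M < V` (size independent of `V`
#' and `M`).
#'
#' @param model `"01"` or `"10"` (see [steady_state_formula()]).
#' @param kappa Net growth rate.
#' @param rho0 Fixed overall density across the sweep.
#' @param V_grid Volumes to sweep (used with fixed `M`).
#' @param M Structure count (fixed), or a grid if `V_grid` has length 1.
#' @return A data frame of class `scaling_curve`: `V`, `M`, `n_star`,
#'   `regime`.
#' @export
scaling_sweep <- function(model, kappa, rho0, V_grid, M = 1) {
  grid <- expand.grid(V = V_grid, M = M)
  grid$n_star <- mapply(function(v, m)
    as.numeric(steady_state_formula(model, kappa, rho0, v, m)),
    grid$V, grid$M)
  grid$regime <- ifelse(kappa * grid$M > grid$V, "linear_scaling", "saturated")
  class(grid) <- c("scaling_curve", class(grid))
  grid
}
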