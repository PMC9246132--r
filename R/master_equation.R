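#' Exact stationary size distribution of a single structure
#'
#' Solves the chemical master equation for one structure growing from a
#' limiting pool of `N` subunits by detailed balance.  The stationary
#' probability of size `n` is proportional to
#' `(kappa/V)^n * N! / ((N - n)! * (n!)^(alpha+beta))`.
#' Weights are accumulated as log-gamma sums and normalized by
#' log-sum-exp, so arbitrarily large `N` cannot overflow.  Volumes other
#' than 1 enter through the substitution `kappa -> kappa / V`.
#'
#' @param p A [feedback_params()].
#' @param N Total pool size (non-negative integer).
#' @param V System volume (> 0).
#' @return A `stationary_dist` object: integer `support` `0:N`, `probs`
#'   summing to 1, pre-normalization `log_weights`, `log_normalizer`, and
#'   moments `mean`, `sd`, `cv`.
#' @examples
#' d <- stationary_single(feedback_params(0, 1), N = 50)
#' d$mean; d$cv
#' @export
stationary_single <- function(p, N, V = 1) {
  stopifnot(N >= 0, N == round(N), V > 0)
  s <- p$alpha + p$beta
  n <- 0:N
  lw <- n * log(p$kappa / V) + lgamma(N + 1) - lgamma(N - n + 1) -
    s * lgamma(n + 1)
  new_stationary_dist(n, lw,
                      params = list(alpha = p$alpha, beta = p$beta,
                                    kappa = p$kappa, N = N, V = V))
}

new_stationary_dist <- function(support, log_weights, params = NULL) {
  lse <- logsumexp(log_weights)
  probs <- exp(log_weights - lse)
  m <- moments_from_probs(support, probs)
  structure(list(support = support, probs = probs,
                 log_weights = log_weights, log_normalizer = lse,
                 mean = m$mean, sd = m$sd, cv = m$cv,
                 params = params),
            class = "stationary_dist")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

moments_from_probs <- function(support, probs) {
  mu <- sum(support * probs)
  v <- sum((support - mu)^2 * probs)
  s <- sqrt(max(v, 0))
  list(mean = mu, sd = s, cv = if (mu > 0) s / mu else Inf)
}

#' Moments of a stationary distribution
#'
#' @param d A `stationary_dist` (exact or empirical).
#' @return A list with `mean`, `sd`, and `cv` (`Inf` when the mean is 0).
#' @export
moments <- function(d) {
  stopifnot(inherits(d, "stationary_dist"))
  moments_from_probs(d$support, d$probs)
}

#' @export
print.stationary_dist <- function(x, ...) {
  cat(sprintf("<stationary_dist> support [%d, %d], mean=%.4g sd=%.4g cv=%.4g\n",
              min(x$support), max(x$support), x$mean, x$sd, x$cv))
  invisible(x)
}

#' Exact stationary joint distribution of two competing structures
#'
#' Joint stationary law of two structures drawing on one limiting pool, at
#' unit volume: `P(n1, n2)` proportional to
#' `kappa1^n1 * kappa2^n2 * N! / ((n1!)^(alpha+beta) (n2!)^(alpha+beta) N_av!)`
#' over the simplex `n1 + n2 <= N`.  Other volumes are handled by rescaling
#' each `kappa_i -> kappa_i / V` (recorded in the metadata).  Per-structure
#' exponents are permitted (each `n_i!` then carries its own
#' `alpha_i + beta_i`); the result is flagged as an extension because the
#' closed form is stated for a shared exponent pair.
#'
#' @param p1,p2 [feedback_params()] for the two structures.
#' @param N Total pool size.
#' @param V System volume (default 1).
#' @return A `joint_dist` object with fields `N`, `probs` (an
#'   `(N+1) x (N+1)` matrix, zero off the simplex), `P00` (the probability of
#'   the empty state, i.e. the reciprocal normalization), and metadata.
#' @export
stationary_joint_two <- function(p1, p2, N, V = 1) {
  stopifnot(N >= 0, N == round(N), V > 0)
  s1 <- p1$alpha + p1$beta
  s2 <- p2$alpha + p2$beta
  n1 <- 0:N
  n2 <- 0:N
  lw <- outer(n1 * log(p1$kappa / V) - s1 * lgamma(n1 + 1),
              n2 * log(p2$kappa / V) - s2 * lgamma(n2 + 1), `+`)
  nav <- outer(n1, n2, function(a, b) N - a - b)
  lw <- lw + lgamma(N + 1) - lgamma(nav + 1)
  lw[nav < 0] <- -Inf
  lse <- logsumexp(lw[is.finite(lw)])
  probs <- exp(lw - lse)
  probs[nav < 0] <- 0
  structure(list(N = N, probs = probs, P00 = probs[1, 1],
                 params = list(kappa1 = p1$kappa, kappa2 = p2$kappa,
                               s1 = s1, s2 = s2, V = V,
                               shared_exponents = isTRUE(all.equal(s1, s2)))),
            class = "joint_dist")
}

#' @export
print.joint_dist <- function(x, ...) {
  cat(sprintf("<joint_dist> N=%d, P(0,0)=%.4g%s\n", x$N, x$P00,
              if (!x$params$shared_exponents) " [per-structure exponent extension]" else ""))
  invisible(x)
}

#' Marginal size distribution from a two-structure joint distribution
#'
#' Sums the joint law over all sizes of the other structure.
#'
#' @param j A `joint_dist` from [stationary_joint_two()].
#' @param which 1 or 2: which structure's marginal to return.
#' @return A `stationary_dist` over `0:N`.
#' @export
marginalize <- function(j, which = 1) {
  stopifnot(inherits(j, "joint_dist"), which %in% c(1, 2))
  p <- if (which == 1) rowSums(j$probs) else colSums(j$probs)
  support <- 0:j$N
  m <- moments_from_probs(support, p)
  structure(list(support = support, probs = p,
                 log_weights = log(p), log_normalizer = 0,
                 mean = m$mean, sd = m$sd, cv = m$cv,
                 params = j$params),
            class = "stationary_dist")
}

#' Stationary distributions at constant subunit concentration
#'
#' When the pool is held at concentration `rho` instead of being limited,
#' the two structures decouple and each marginal has weights
#' `(kappa_i * rho)^n / (n!)^(alpha_i+beta_i)` on `n = 0, 1, ...`.  For
#' `alpha + beta = 1` this is exactly Poisson with mean `kappa * rho`.  The
#' series diverges - growth is unbounded and no stationary law exists - when
#' `alpha + beta < 0`, or when `alpha + beta = 0` with `kappa * rho >= 1`;
#' this is detected from a persistently non-decreasing weight ratio and
#' reported via the `normalizable` flags rather than by truncating blindly.
#'
#' @param p1,p2 [feedback_params()] for the two structures.
#' @param rho Fixed subunit concentration (>= 0).
#' @param n_max Optional truncation; by default it is doubled adaptively
#'   until the appended geometric tail bound is below `tail_tol`.
#' @param tail_tol Tail-mass tolerance for the adaptive truncation.
#' @return A list with `marginal1`, `marginal2` (each a `stationary_dist`
#'   or `NULL` when not normalizable), `normalizable` (logical of length 2),
#'   and the truncation used.
#' @export
stationary_const_conc <- function(p1, p2, rho, n_max = NULL,
                                  tail_tol = 1e-10) {
  stopifnot(rho >= 0)
  one <- function(p) {
    s <- p$alpha + p$beta
    x <- p$kappa * rho
    # weight ratio w(n)/w(n-1) = x / n^s
    if (s < 0 || (s == 0 && x >= 1))
      return(list(dist = NULL, ok = FALSE, n_max = NA_integer_))
    nm <- if (is.null(n_max)) 256L else as.integer(n_max)
    repeat {
      n <- 0:nm
      lw <- n * log(x) - s * lgamma(n + 1)
      ratio <- x / (nm + 1)^s  # next-term ratio, decreasing in n for s > 0
      tail_bound <- if (ratio < 1)
        exp(lw[nm + 1] - logsumexp(lw)) * ratio / (1 - ratio)
      else Inf
      if (tail_bound < tail_tol) break
      if (!is.null(n_max))
        stop("truncation n_max too small: tail mass above tolerance; ",
             "increase n_max or leave it NULL for adaptive doubling")
      nm <- nm * 2L
      if (nm > 2^26) stop("adaptive truncation exceeded 2^26 states")
    }
    list(dist = new_stationary_dist(0:nm, lw,
                                    params = list(kappa = p$kappa, rho = rho,
                                                  s = s)),
         ok = TRUE, n_max = nm)
  }
  m1 <- one(p1)
  m2 <- one(p2)
  list(marginal1 = m1$dist, marginal2 = m2$dist,
       normalizable = c(m1$ok, m2$ok),
       n_max = c(m1$n_max, m2$n_max))
}

#' Count modes of a discrete distribution
#'
#' Number of strict local maxima of the exact probability vector over the
#' integer support.  Runs of exactly equal probabilities are merged first
#' (a plateau counts once); the endpoints of the support are eligible.  No
#' smoothing is applied: the input is an exact distribution, not a histogram.
#'
#' @param d A `stationary_dist`.
#' @return Integer number of modes (>= 1 for any proper distribution).
#' @export
count_modes <- function(d) {
  stopifnot(inherits(d, "stationary_dist"))
  v <- rle(d$probs)$values
  k <- length(v)
  if (k == 1) return(1L)
  n_modes <- 0L
  for (i in seq_len(k)) {
    left_ok <- (i == 1) || (v[i] > v[i - 1])
    right_ok <- (i == k) || (v[i] > v[i + 1])
    if (left_ok && right_ok) n_modes <- n_modes + 1L
  }
  n_modes
}

#' Growth-rate threshold where the size CV crosses 1
#'
#' Below a threshold growth rate the structure barely grows and size
#' fluctuations exceed the mean (CV > 1, near-exponential distribution);
#' above it the CV falls below 1.  `find_kappa0` locates the smallest
#' crossing of CV = 1 in the bracket by a grid scan followed by bisection on
#' the exact single-structure stationary distribution.
#'
#' @param p A [feedback_params()]; its `kappa` is ignored (kappa is the free
#'   variable).
#' @param N Pool size.
#' @param V Volume.
#' @param bracket Search interval for kappa.
#' @param tol Tolerance on |CV - 1| at the returned point.
#' @return The threshold `kappa0`.
#' @export
find_kappa0 <- function(p, N, V = 1, bracket = c(1e-8, 100), tol = 1e-6) {
  cv_at <- function(kappa) {
    pp <- feedback_params(p$alpha, p$beta, k_plus = kappa, k_minus = 1)
    stationary_single(pp, N, V)$cv
  }
  f <- function(kappa) cv_at(kappa) - 1
  grid <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = 64))
  fg <- vapply(grid, f, numeric(1))
  idx <- which(fg[-length(fg)] * fg[-1] <= 0)
  if (length(idx) == 0)
    stop(sprintf("CV - 1 does not change sign in bracket: CV(%g)=%g, CV(%g)=%g",
                 bracket[1], fg[1] + 1, bracket[2], fg[length(fg)] + 1))
  i <- idx[1]  # smallest crossing
  r <- uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-14)
  if (abs(f(r$root)) > tol)
    stop("bisection did not reach the CV tolerance")
  r$root
}

#' Bistable window of growth rates for a single structure
#'
#' For net positive feedback (`alpha + beta < 0`) the exact stationary
#' distribution is bimodal in an intermediate window of growth rates
#' `kappa_star < kappa < kappa_c`; below the window the structure does not
#' grow, above it a single large structure takes essentially the whole pool.
#' The window edges are located by a log-grid scan for a bimodal point
#' followed by bisection on the exact mode count.
#'
#' @param alpha,beta Feedback exponents with `alpha + beta < 0` (otherwise
#'   the window is empty for every kappa).
#' @param N Pool size.
#' @param V Volume.
#' @param kappa_range Search range.
#' @param rel_tol Relative tolerance on the window edges.
#' @return A list of class `kappa_thresholds` with `kappa_star`, `kappa_c`,
#'   `kappa0` (CV = 1 crossing, `NA` if absent in range) and `empty`.
#' @export
bistable_window <- function(alpha, beta, N, V = 1,
                            kappa_range = c(1e-6, 10), rel_tol = 1e-6) {
  modes_at <- function(kappa) {
    p <- feedback_params(alpha, beta, k_plus = kappa, k_minus = 1)
    count_modes(stationary_single(p, N, V))
  }
  k0 <- tryCatch(
    find_kappa0(feedback_params(alpha, beta), N, V, bracket = kappa_range),
    error = function(e) NA_real_)
  if (alpha + beta >= 0) {
    return(structure(list(kappa_star = NA_real_, kappa_c = NA_real_,
                          kappa0 = k0, empty = TRUE),
                     class = "kappa_thresholds"))
  }
  grid <- exp(seq(log(kappa_range[1]), log(kappa_range[2]), length.out = 400))
  m <- vapply(grid, modes_at, integer(1))
  bi <- which(m == 2L)
  if (length(bi) == 0) {
    return(structure(list(kappa_star = NA_real_, kappa_c = NA_real_,
                          kappa0 = k0, empty = TRUE),
                     class = "kappa_thresholds"))
  }
  bisect_edge <- function(lo, hi, want_hi_bimodal) {
    # invariant: exactly one endpoint is bimodal
    while ((hi - lo) / hi > rel_tol) {
      mid <- sqrt(lo * hi)
      if ((modes_at(mid) == 2L) == want_hi_bimodal) hi <- mid else lo <- mid
    }
    if (want_hi_bimodal) hi else lo
  }
  lo_i <- bi[1]
  kappa_star <- if (lo_i == 1) grid[1] else
    bisect_edge(grid[lo_i - 1], grid[lo_i], want_hi_bimodal = TRUE)
  hi_i <- bi[length(bi)]
  kappa_c <- if (hi_i == length(grid)) grid[length(grid)] else
    bisect_edge(grid[hi_i], grid[hi_i + 1], want_hi_bimodal = FALSE)
  structure(list(kappa_star = kappa_star, kappa_c = kappa_c,
                 kappa0 = k0, empty = FALSE),
            class = "kappa_thresholds")
}

#' @export
print.kappa_thresholds <- function(x, ...) {
  if (x$empty)
    cat("<kappa_thresholds> no bistable window; kappa0 =", x$kappa0, "\n")
  else
    cat(sprintf("<kappa_thresholds> bistable for kappa in (%.4g, %.4g); kappa0 = %.4g\n",
                x$kappa_star, x$kappa_c, x$kappa0))
  invisible(x)
}

#' Export a stationary distribution as a two-column data frame
#'
#' @param d A `stationary_dist`.
#' @return `data.frame(n, probability)`, ready for `write.csv`.
#' @export
as.data.frame.stationary_dist <- function(x, ...) {
  data.frame(n = x$support, probability = x$probs)
}

#' Export a joint distribution as a three-column data frame
#'
#' @param x A `joint_dist`.
#' @return `data.frame(n1, n2, probability)` over the simplex.
#' @export
as.data.frame.joint_dist <- function(x, ...) {
  idx <- which(x$probs > 0 | row(x$probs) + col(x$probs) - 2 <= x$N,
               arr.ind = TRUE)
  data.frame(n1 = idx[, 1] - 1L, n2 = idx[, 2] - 1L,
             probability = x$probs[idx])
}
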