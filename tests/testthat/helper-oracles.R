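# Independent linear-algebra oracle for the single-structure stationary law:
# builds the (N+1)-state birth-death generator from the bare propensities and
# solves Q^T pi = 0, sum(pi) = 1 directly.  No detailed-balance shortcut.
bd_stationary_oracle <- function(alpha, beta, kappa, N, V = 1) {
  n <- 0:N
  up <- kappa * (N - n) * (1 + n)^(-alpha) / V   # rate n -> n+1
  down <- ifelse(n > 0, n^beta, 0)               # rate n -> n-1 (k- = 1)
  Q <- matrix(0, N + 1, N + 1)
  for (k in seq_len(N + 1)) {
    out_rate <- 0
    if (k <= N) { Q[k, k + 1] <- up[k]; out_rate <- out_rate + up[k] }
    if (k >= 2) { Q[k, k - 1] <- down[k]; out_rate <- out_rate + down[k] }
    Q[k, k] <- -out_rate
  }
  A <- t(Q)
  A[N + 1, ] <- 1  # replace one balance equation by normalization
  b <- c(rep(0, N), 1)
  as.numeric(solve(A, b))
}

# convenience constructor for a bare empirical stationary_dist from a
# probability vector (used to probe count_modes on crafted shapes)
manual_dist <- function(probs) {
  probs <- probs / sum(probs)
  support <- seq_along(probs) - 1L
  mu <- sum(support * probs)
  s <- sqrt(sum((support - mu)^2 * probs))
  structure(list(support = support, probs = probs,
                 log_weights = log(probs), log_normalizer = 0,
                 mean = mu, sd = s, cv = if (mu > 0) s / mu else Inf,
                 params = list(manual = TRUE)),
            class = "stationary_dist")
}
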