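# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: exhaustive enumeration, direct sampling and
# plainly-coded closed forms.

# Exhaustive activation-schedule statistics: enumerate all 2^P schedules of a
# post-synaptic neuron (active or not in each of patterns 1..P), weight by
# the schedule probability and accumulate the first two moments of the
# potentiated-input fraction. Feasible for P <= 15.
brute_schedule_stats <- function(f) {
  P <- length(f) - 1
  fk <- f[-1]          # pattern k = 1..P participation probabilities
  fprev <- f[-length(f)]
  s1 <- 0; s2 <- 0
  for (bits in 0:(2^P - 1)) {
    A <- as.logical(bitwAnd(bits, 2^(0:(P - 1))))
    pA <- prod(ifelse(A, fk, 1 - fk))
    sA <- if (any(A)) 1 - prod(1 - fprev[A]) else 0
    s1 <- s1 + pA * sA
    s2 <- s2 + pA * sA^2
  }
  list(varsigma = s1, E2 = s2)
}

# Brute-force ensemble mean and variance of varsigma over the phi ensemble,
# by exhaustive expansion of <prod (1 - f_k f_(k-1))> and its square in the
# raw moments of the coding-ratio distribution. Exponential in P (3^P).
brute_ensemble_moments <- function(mom, P) {
  momx <- c(1, mom)
  expect_val <- function(coeffs) {
    # coeffs[e + 1] is the factor coefficient for exponent e per position
    nlev <- length(coeffs)
    grid <- as.matrix(expand.grid(rep(list(0:(nlev - 1)), P)))
    tot <- 0
    for (r in seq_len(nrow(grid))) {
      e <- grid[r, ]
      ev <- c(e, 0) + c(0, e)     # per-variable exponents (shared neighbours)
      tot <- tot + prod(coeffs[e + 1]) * prod(momx[ev + 1])
    }
    tot
  }
  G1 <- expect_val(c(1, -1))          # (1 - x)
  G2 <- expect_val(c(1, -2, 1))       # (1 - x)^2
  mean_v <- 1 - G1
  second <- 1 - 2 * G1 + G2
  list(mean_varsigma = mean_v, var_varsigma = second - mean_v^2)
}

# Direct Monte Carlo of the varsigma ensemble for a Gamma coding-ratio
# distribution, sampled with stats::rgamma and the bare product formula.
mc_gamma_varsigma <- function(phi0, sigma_phi, P, n, seed) {
  withr::with_seed(seed, {
    f <- matrix(stats::rgamma(n * (P + 1), shape = phi0^2 / sigma_phi^2,
                              scale = sigma_phi^2 / phi0), nrow = n)
    1 - exp(rowSums(log(1 - f[, -1, drop = FALSE] * f[, -(P + 1), drop = FALSE])))
  })
}

# Independently coded homogeneous mean-field map (constant pattern size M,
# scalar potentiation probability vs, linear inhibition b = cm * vs).
hom_meanfield <- function(M, N, cm, vs, V2, theta, Q) {
  b <- cm * vs
  m <- M; n <- 0
  out <- matrix(NA_real_, Q, 2)
  for (t in seq_len(Q)) {
    th <- theta + b * (m + n)
    mu_on <- cm * m + cm * vs * n
    s_on <- sqrt(cm * m * (1 - cm) +
                   cm * vs * n * (1 - cm * vs + V2 * cm * vs * (n - 1)))
    mu_off <- cm * vs * (m + n)
    s_off <- sqrt(cm * vs * (m + n) *
                    (1 - cm * vs + V2 * cm * vs * (m + n - 1)))
    pon <- if (s_on > 0) pnorm((mu_on - th) / s_on) else as.numeric(mu_on > th)
    poff <- if (s_off > 0) pnorm((mu_off - th) / s_off) else as.numeric(mu_off > th)
    m <- M * pon
    n <- (N - M) * poff
    out[t, ] <- c(m, n)
  }
  out
}

# Find the largest connectivity c at which the homogeneous mean-field map
# (coded above) still replays T_min steps with quality > 0.5 for some theta.
hom_max_stable_c <- function(phi0, N, cm, theta_grid, T_min,
                             tol = 1e-4) {
  V2_of <- function(vs, P, f) {
    E2 <- 2 * vs - 1 + (1 - f * (2 * f - f^2))^P
    max(0, E2 - vs^2) / vs^2
  }
  stable_at <- function(cc) {
    vs <- cc / cm
    P <- log(1 - vs) / log(1 - phi0^2)
    V2 <- V2_of(vs, P, phi0)
    M <- phi0 * N
    any(vapply(theta_grid, function(th) {
      tr <- hom_meanfield(M, N, cm, vs, V2, th, T_min)
      all(tr[, 1] / M - tr[, 2] / (N - M) > 0.5)
    }, logical(1)))
  }
  lo <- 0.01; hi <- cm * 0.999
  if (!stable_at(lo)) stop("homogeneous map unstable even at c = 0.01")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stable_at(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
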