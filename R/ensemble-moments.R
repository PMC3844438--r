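# Ensemble statistics of the potentiation probability over the coding-ratio
# distribution: mean <varsigma> and variance sigma_varsigma^2 over all
# realizations of phi, as functions of the first four raw moments of p_phi.

# ---- analytic moment expansion ---------------------------------------------

# <varsigma> as the alternating double sum over run-counted combinations.
# Terms are evaluated in log magnitude; cancellation is tracked and an error
# is raised when the result would carry fewer than ~6 significant digits.
eq71_mean <- function(mom, P) {
  lm1 <- log(mom[1]); lm2 <- log(mom[2])
  acc <- 0; tot_abs <- 0; peak <- 0
  for (k in seq_len(P)) {
    j <- seq_len(min(k, P - k + 1))
    lterm <- lchoose(P - k + 1, j) + lchoose(k - 1, k - j) +
      2 * j * lm1 + (k - j) * lm2
    lmax <- max(lterm)
    if (lmax > 700)
      stop("moment expansion overflows at P = ", P, " (k = ", k, "); ",
           "use method = 'chain' or 'mc'", call. = FALSE)
    inner <- exp(lmax) * sum(exp(lterm - lmax))
    acc <- acc + if (k %% 2L == 1L) inner else -inner
    tot_abs <- tot_abs + inner
    peak <- max(peak, inner)
    if (inner < 1e-18 * tot_abs && k > 3) break
  }
  if (tot_abs * .Machine$double.eps > 1e-6 * max(abs(acc), 1e-300))
    stop("catastrophic cancellation in moment expansion at P = ", P,
         "; use method = 'chain' or 'mc'", call. = FALSE)
  acc
}

# psi_m: sum over placements of m "squared" factors among k chain positions,
# split by how many maximal runs touch the chain boundary.
psi_m <- function(mom, k, m) {
  m1 <- mom[1]; m2 <- mom[2]; m3 <- mom[3]; m4 <- mom[4]
  if (m == 0) return(m1^2 * m2^(k - 1))
  if (m == k) return(m2^2 * m4^(k - 1))
  # index ranges restricted to where the run counts and prefactors are
  # nonzero; outside them the moment powers can over-/underflow to Inf/0
  # and poison the sum with 0 * Inf.
  i1 <- seq_len(max(0L, min(m, k - m - 1)))
  s1 <- sum((k - m - i1) / (k - m) * n_combinations(k - 1, m, i1) *
              m2^(k - m - i1 - 1) * m3^(2 * i1) * m4^(m - i1))
  i2 <- seq_len(min(m, k - m))
  s2 <- sum(i2 / (k - m) * n_combinations(k - 1, m, i2) *
              m2^(k - m - i2) * m3^(2 * i2 - 1) * m4^(m - i2))
  i3 <- seq_len(max(0L, min(k - m, m - 1)))
  s3 <- sum((m - i3) / m * n_combinations(k - 1, k - m, i3) *
              m2^(k - m - i3) * m3^(2 * i3) * m4^(m - i3 - 1))
  m1^2 * s1 + 2 * m1 * m2 * s2 + m2^2 * s3
}

# pi_k = < prod_{t=1..k} (2 f_t f_{t+1} - f_t^2 f_{t+1}^2) > for a run of k
# adjacent squared factors, via the signed sum over psi_m.
pi_runs <- function(mom, kmax) {
  vapply(seq_len(kmax), function(k) {
    m <- 0:k
    sum((-1)^m * 2^(k - m) *
          vapply(m, function(mm) psi_m(mom, k, mm), numeric(1)))
  }, numeric(1))
}

# <prod (1 - f_k f_(k-1))^2> via the run-sum recursion S_kj.
eq79_G2 <- function(mom, P) {
  piv <- pi_runs(mom, P)
  S <- matrix(0, P, P)
  S[, 1] <- piv
  for (k in seq_len(P)) {
    if (k >= 2) for (j in 2:k) {
      i <- seq_len(k - j + 1)
      S[k, j] <- sum(piv[i] * S[cbind(k - i, j - 1)])
    }
  }
  acc <- 1; tot_abs <- 1
  for (k in seq_len(P)) {
    j <- seq_len(min(k, P - k + 1))
    inner <- sum(choose(P - k + 1, j) * S[k, j])
    if (!is.finite(inner))
      stop("moment expansion overflows at P = ", P,
           "; use method = 'chain' or 'mc'", call. = FALSE)
    acc <- acc + if (k %% 2L == 0L) inner else -inner
    tot_abs <- tot_abs + abs(inner)
  }
  if (tot_abs * .Machine$double.eps > 1e-6 * max(abs(acc), 1e-300))
    stop("catastrophic cancellation in moment expansion at P = ", P,
         "; use method = 'chain' or 'mc'", call. = FALSE)
  acc
}

# ---- transfer-matrix ("chain") evaluation ----------------------------------
# The product prod_k (1 - f_k f_(k-1)) couples only consecutive i.i.d. coding
# ratios, so its expectation (and that of its square) is a matrix power over
# the per-factor exponent carried to the shared variable. Exact at any P.

chain_G1 <- function(mom, P) {
  m1 <- mom[1]; m2 <- mom[2]
  u <- c(1, -m1)
  Tm <- matrix(c(1, m1, -m1, -m2), 2, 2)
  w <- c(1, m1)
  v <- u
  if (P > 1) for (t in 2:P) v <- v %*% Tm
  drop(sum(v * w))
}

chain_G2 <- function(mom, P) {
  m1 <- mom[1]; m2 <- mom[2]; m3 <- mom[3]; m4 <- mom[4]
  u <- c(1, -2 * m1, m2)
  Tm <- cbind(c(1, m1, m2), -2 * c(m1, m2, m3), c(m2, m3, m4))
  w <- c(1, m1, m2)
  v <- u
  if (P > 1) for (t in 2:P) v <- v %*% Tm
  drop(sum(v * w))
}

# ---- public API -------------------------------------------------------------

#' Mean and variance of the potentiation probability over the phi-ensemble
#'
#' The potentiation probability varsigma depends on the realized coding-ratio
#' vector phi; over the ensemble of phi it has mean `<varsigma>` and variance
#' `sigma_varsigma^2`, both functions of the first four raw moments of the
#' coding-ratio distribution. Three evaluation methods are available:
#'
#' * `"moments"`: the combinatorial moment expansion (run-counted alternating
#'   sums with the S_kj recursion). Numerically guarded: raises an error,
#'   reporting P, if the alternating sums lose more than ~6 significant
#'   digits or overflow. Cost grows as P^2; intended for P up to a few
#'   hundred.
#' * `"chain"`: exact transfer-matrix evaluation exploiting the Markov
#'   structure of the product over consecutive coding ratios; O(P), stable at
#'   any P.
#' * `"mc"`: Monte Carlo over `n_mc` sampled phi vectors pushed through
#'   [varsigma_exact()] (chunked so that memory stays bounded).
#'
#' `method = "auto"` uses `"moments"` for P <= 300 and `"chain"` otherwise.
#' For the degenerate distribution (sigma_phi = 0) the mean equals
#' 1 - (1 - phi0^2)^P and the variance is 0, whichever method is used.
#'
#' @param spec a [coding_spec()].
#' @param P number of stored associations.
#' @param method see Details.
#' @param n_mc Monte-Carlo sample size for `method = "mc"`.
#' @param seed optional seed (Monte Carlo only).
#' @return list with `mean_varsigma`, `var_varsigma`, `P`, `method`, and for
#'   Monte Carlo additionally `se_mean` (standard error of the mean).
#' @examples
#' spec <- coding_spec("gamma", phi0 = 0.01, sigma_phi = 0.001)
#' ensemble_moments(spec, P = 50)
#' @export
ensemble_moments <- function(spec, P,
                             method = c("auto", "moments", "chain", "mc"),
                             n_mc = 1e5, seed = NULL) {
  stopifnot(inherits(spec, "coding_spec"), P >= 1)
  method <- match.arg(method)
  if (method == "auto") method <- if (P <= 300) "moments" else "chain"
  mom <- phi_moments(spec)

  if (spec$sigma_phi == 0 && method != "mc") {
    mean_v <- -expm1(P * log1p(-spec$phi0^2))
    return(list(mean_varsigma = mean_v, var_varsigma = 0,
                P = P, method = method))
  }

  if (method == "moments") {
    mean_v <- eq71_mean(mom, P)
    second <- 2 * mean_v - 1 + eq79_G2(mom, P)
    list(mean_varsigma = mean_v,
         var_varsigma = max(0, second - mean_v^2),
         P = P, method = "moments")
  } else if (method == "chain") {
    G1 <- chain_G1(mom, P)
    G2 <- chain_G2(mom, P)
    mean_v <- 1 - G1
    second <- 1 - 2 * G1 + G2
    list(mean_varsigma = mean_v,
         var_varsigma = max(0, second - mean_v^2),
         P = P, method = "chain")
  } else {
    vs <- with_seed_if(seed, {
      chunk <- max(1L, as.integer(2e7 %/% (P + 1)))
      out <- numeric(n_mc)
      done <- 0L
      while (done < n_mc) {
        nb <- min(chunk, n_mc - done)
        f <- matrix(r_coding(spec, nb * (P + 1)), nrow = nb)
        lg <- log1p(-f[, -1, drop = FALSE] * f[, -(P + 1), drop = FALSE])
        out[done + seq_len(nb)] <- -expm1(rowSums(lg))
        done <- done + nb
      }
      out
    })
    list(mean_varsigma = mean(vs), var_varsigma = stats::var(vs),
         P = P, method = "mc", se_mean = stats::sd(vs) / sqrt(n_mc))
  }
}

# draw coding ratios subject to the same rejection rule as sample_phi
r_coding_valid <- function(spec, n, N) {
  x <- r_coding(spec, n)
  bad <- x >= 1 | round(x * N) < 1
  rounds <- 0L
  while (any(bad)) {
    rounds <- rounds + 1L
    if (rounds > 1000L) stop("rejection sampling failed after 1000 rounds")
    x[bad] <- r_coding(spec, sum(bad))
    bad <- x >= 1 | round(x * N) < 1
  }
  x
}

#' Calibrate the number of stored associations to a target connectivity
#'
#' The experiments fix the mean effective connectivity c by adjusting the
#' number P of stored associations. Two calibration modes:
#'
#' * `"per_realization"`: sample a coding-ratio vector and extend it one
#'   pattern at a time until its realized potentiation probability
#'   varsigma(phi) reaches `c_target / cm`; returns that P together with the
#'   phi actually used. The realized varsigma overshoots the target by at
#'   most f_max^2 (one pattern's worth).
#' * `"ensemble"`: the smallest P whose ensemble mean `<varsigma>` reaches
#'   `c_target / cm`, found by bisection on the monotone mean (evaluated with
#'   the moment expansion at small P and the exact chain method at large P).
#'
#' @param spec a [coding_spec()].
#' @param c_target target effective connectivity, 0 < c_target < cm.
#' @param cm morphological connectivity.
#' @param mode `"per_realization"` or `"ensemble"`.
#' @param N network size (required for `"per_realization"`: the sampled
#'   ratios obey the same validity rules as [sample_phi()]).
#' @param seed optional seed (per-realization mode).
#' @param max_P iteration cap; error if the target is unreachable below it.
#' @return for `"per_realization"`, list with `P`, `phi` (a
#'   [pattern_sizes()]), and the realized `varsigma`; for `"ensemble"`, list
#'   with `P` and `mean_varsigma` at that P.
#' @examples
#' spec0 <- coding_spec("gamma", phi0 = 0.01, sigma_phi = 0)
#' calibrate_P(spec0, c_target = 0.05, cm = 0.1, N = 1e5)$P  # 6932
#' @export
calibrate_P <- function(spec, c_target, cm,
                        mode = c("per_realization", "ensemble"),
                        N = NULL, seed = NULL, max_P = 2^22) {
  stopifnot(inherits(spec, "coding_spec"), cm > 0, cm <= 1)
  if (c_target <= 0 || c_target >= cm)
    stop("need 0 < c_target < cm")
  mode <- match.arg(mode)
  target <- c_target / cm

  if (mode == "per_realization") {
    if (is.null(N)) stop("`N` is required for per-realization calibration")
    res <- with_seed_if(seed, {
      f_acc <- r_coding_valid(spec, 1L, N)  # cue pattern f_0
      last <- f_acc
      cum <- 0; P <- 0L
      lthr <- log1p(-target)
      repeat {
        chunk <- r_coding_valid(spec, 4096L, N)
        lg <- log1p(-chunk * c(last, chunk[-length(chunk)]))
        cs <- cum + cumsum(lg)
        hit <- which(cs <= lthr)
        if (length(hit)) {
          h <- hit[1]
          f_acc <- c(f_acc, chunk[seq_len(h)])
          P <- P + h
          break
        }
        f_acc <- c(f_acc, chunk)
        P <- P + length(chunk)
        cum <- cs[length(cs)]
        last <- chunk[length(chunk)]
        if (P > max_P)
          stop("target connectivity unreachable within max_P = ", max_P)
      }
      list(P = P, f = f_acc)
    })
    phi <- pattern_sizes(res$f, N)
    list(P = res$P, phi = phi, varsigma = varsigma_exact(phi))
  } else {
    mean_at <- function(P) {
      ensemble_moments(spec, P,
                       method = if (P <= 300) "moments" else "chain"
                       )$mean_varsigma
    }
    hi <- 1024L
    while (mean_at(hi) < target) {
      hi <- hi * 2L
      if (hi > max_P)
        stop("target connectivity unreachable within max_P = ", max_P)
    }
    lo <- 1L
    if (mean_at(lo) >= target) return(list(P = 1L, mean_varsigma = mean_at(1L)))
    while (hi - lo > 1L) {
      mid <- as.integer((lo + hi) %/% 2L)
      if (mean_at(mid) >= target) hi <- mid else lo <- mid
    }
    list(P = hi, mean_varsigma = mean_at(hi))
  }
}
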