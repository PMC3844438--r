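# Derived replay metrics and experiments: retrieval quality, success rates,
# T90 / maximum retrievable sequence length, phase diagrams, capacity curves
# and termination statistics.

#' Retrieval quality
#'
#' Gamma = m/M - n/(N - M), the hit fraction minus the false-alarm fraction;
#' a pattern counts as successfully retrieved when Gamma > 0.5 (strict).
#'
#' @param m hits.
#' @param n false alarms.
#' @param M pattern size, 0 < M < N.
#' @param N network size.
#' @return Gamma in \[-1, 1\] (vectorized).
#' @export
retrieval_quality <- function(m, n, M, N) {
  stopifnot(all(M > 0), all(M < N))
  m / M - n / (N - M)
}

# One mean-field realization: sample phi (fixed P or calibrated to c_target)
# and compute its realized connectivity statistics.
draw_realization <- function(spec, N, cm, Q, seed,
                             c_target = NULL, P = NULL) {
  if (is.null(c_target) == is.null(P))
    stop("give exactly one of `c_target` or `P`")
  if (!is.null(c_target)) {
    cal <- calibrate_P(spec, c_target, cm, mode = "per_realization",
                       N = N, seed = seed)
    f <- cal$phi$f; Pr <- cal$P
  } else {
    f <- sample_phi(spec, P, N, seed = seed)$f; Pr <- P
  }
  if (Pr < Q)
    stop("realization stores P = ", Pr, " < Q = ", Q, " associations")
  ss <- schedule_stats(f)
  list(f_head = f[seq_len(Q + 1)], varsigma = ss$varsigma, V2 = ss$V2, P = Pr)
}

prepare_realizations <- function(spec, N, cm, Q, n_real, seed,
                                 c_target = NULL, P = NULL) {
  lapply(seq_len(n_real), function(i) {
    draw_realization(spec, N, cm, Q,
                     seed = if (is.null(seed)) NULL else substream_seed(seed, i),
                     c_target = c_target, P = P)
  })
}

# Gamma trajectory (t = 1..Q) of one prepared realization at threshold theta.
realization_gamma <- function(rs, theta, N, cm, inhibition, spec_phi0,
                              b = NULL) {
  p <- mf_params(N = N, cm = cm, theta = theta, varsigma = rs$varsigma,
                 V2 = rs$V2, b = b, inhibition = inhibition,
                 phi0 = spec_phi0)
  tr <- run_replay(rs$f_head, p, Q = length(rs$f_head) - 1L)
  tr$gamma[-1]
}

#' Empirical replay success rate over an ensemble of coding-ratio vectors
#'
#' Runs the mean-field replay for `n_real` independent realizations of phi
#' (each calibrated to `c_target`, or each sampled with fixed `P`) and
#' returns, per time step, the fraction of runs with retrieval quality
#' Gamma_t > 0.5.
#'
#' @param spec a [coding_spec()].
#' @param theta firing threshold.
#' @param N,cm network size and morphological connectivity.
#' @param Q replay length.
#' @param n_real ensemble size (>= 1).
#' @param seed master seed; realization i uses an independent sub-stream.
#' @param c_target calibrate P per realization to this effective
#'   connectivity (exclusive with `P`).
#' @param P fixed number of stored associations (exclusive with `c_target`).
#' @param inhibition `"linear"` or `"nonlinear"`.
#' @param b optional inhibitory-weight override.
#' @return data.frame of class `success_curve` with columns `t` (1..Q),
#'   `rho`, `n_real`.
#' @export
success_rate <- function(spec, theta, N, cm, Q, n_real, seed = NULL,
                         c_target = NULL, P = NULL,
                         inhibition = c("linear", "nonlinear"), b = NULL) {
  inhibition <- match.arg(inhibition)
  rs_list <- prepare_realizations(spec, N, cm, Q, n_real, seed,
                                  c_target = c_target, P = P)
  succ <- vapply(rs_list, function(rs) {
    realization_gamma(rs, theta, N, cm, inhibition, spec$phi0, b) > 0.5
  }, logical(Q))
  rho <- if (Q == 1) mean(succ) else rowMeans(succ)
  structure(data.frame(t = seq_len(Q), rho = rho, n_real = n_real),
            class = c("success_curve", "data.frame"))
}

#' Longest prefix with success rate above 90 percent
#'
#' T90 is the largest t such that the replay success rate exceeds 0.9
#' (strictly) at every step s <= t; a single dip ends the credited length.
#'
#' @param x a `success_curve` (from [success_rate()]) or a bare numeric
#'   vector of per-step success rates starting at t = 1.
#' @return integer T90, between 0 and the curve length.
#' @export
t90 <- function(x) {
  rho <- if (is.data.frame(x)) x$rho else as.numeric(x)
  if (!length(rho)) stop("empty success curve")
  bad <- which(!(rho > 0.9))
  if (!length(bad)) length(rho) else bad[1] - 1L
}

#' Maximum retrievable sequence length
#'
#' T = max over the firing-threshold grid of [t90()]: the longest sequence
#' prefix replayed with more than 90 percent success at the best threshold.
#'
#' @inheritParams success_rate
#' @param theta_grid thresholds to maximize over (the default integer grid
#'   1..60 covers the wedge at phi0 = 0.01).
#' @return list with `T`, `theta_opt`, and `per_theta` (data.frame of
#'   theta and t90).
#' @export
max_retrievable_length <- function(spec, N, cm, theta_grid = 1:60, Q = 100,
                                   n_real = 100, seed = NULL,
                                   c_target = NULL, P = NULL,
                                   inhibition = c("linear", "nonlinear")) {
  inhibition <- match.arg(inhibition)
  rs_list <- prepare_realizations(spec, N, cm, Q, n_real, seed,
                                  c_target = c_target, P = P)
  t90s <- vapply(theta_grid, function(theta) {
    succ <- vapply(rs_list, function(rs) {
      realization_gamma(rs, theta, N, cm, inhibition, spec$phi0) > 0.5
    }, logical(Q))
    rho <- if (Q == 1) mean(succ) else rowMeans(succ)
    t90(rho)
  }, integer(1))
  best <- which.max(t90s)
  list(T = t90s[best], theta_opt = theta_grid[best],
       per_theta = data.frame(theta = theta_grid, t90 = t90s))
}

#' Largest number of stored associations sustaining a given replay length
#'
#' Bisects on P (the maximum retrievable sequence length is non-increasing
#' in the storage load) for the largest P whose T, maximized over the
#' threshold grid, still reaches `T_min`. This is the quantity whose ratio
#' between the homogeneous and inhomogeneous ensembles measures the capacity
#' cost of inhomogeneity for short sequences.
#'
#' @inheritParams max_retrievable_length
#' @param T_min required replay length (the replay is run for Q = T_min
#'   steps).
#' @param P_hi upper bound for the search (doubled until replay fails).
#' @return list with `P_max` and the bracketing evaluations `evals`
#'   (data.frame of P and T).
#' @export
largest_stable_P <- function(spec, N, cm, theta_grid = 1:60, T_min = 10,
                             n_real = 100, seed = NULL, P_hi = 1024,
                             inhibition = c("linear", "nonlinear")) {
  inhibition <- match.arg(inhibition)
  evals <- list()
  T_at <- function(P) {
    r <- max_retrievable_length(
      spec, N, cm, theta_grid = theta_grid, Q = T_min, n_real = n_real,
      seed = if (is.null(seed)) NULL else substream_seed(seed, P),
      P = P, inhibition = inhibition)$T
    evals[[length(evals) + 1L]] <<- data.frame(P = P, T = r)
    r
  }
  if (T_at(T_min) < T_min)   # smallest admissible storage already fails
    return(list(P_max = 0L, evals = do.call(rbind, evals)))
  lo <- T_min
  hi <- max(P_hi, lo + 1L)
  while (T_at(hi) >= T_min) {
    lo <- hi
    hi <- hi * 2L
    if (hi > 2^22) stop("no failing P found below 2^22")
  }
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2L)
    if (T_at(mid) >= T_min) lo <- mid else hi <- mid
  }
  list(P_max = lo, evals = do.call(rbind, evals))
}

#' Replay phase diagram over (coding ratio, threshold)
#'
#' Evaluates replay over a grid of mean coding ratios (or triangular modes)
#' and firing thresholds, each cell averaged over `n_real` realizations of
#' phi calibrated to `c_target`. The stable region forms the typical wedge:
#' low thresholds or large coding ratios tip the network into the all-active
#' state, high thresholds or small coding ratios into the all-silent state.
#'
#' @param spec_fun function mapping a grid value to a [coding_spec()], e.g.
#'   `function(phi) coding_spec("gamma", phi0 = phi, sigma_phi = 0.1 * phi)`.
#' @param phi_grid grid of mean coding ratios (or modes).
#' @param theta_grid grid of firing thresholds.
#' @param N,cm,Q,n_real,seed,inhibition as in [success_rate()].
#' @param c_target effective connectivity each realization is calibrated to.
#' @param t_eval time step at which the cell statistic is taken.
#' @param metric `"success"` for the replay success rate at `t_eval`,
#'   `"gamma"` for the mean retrieval quality at `t_eval`.
#' @return data.frame with columns `phi`, `theta`, `value`, plus the
#'   settings as attributes.
#' @export
phase_diagram <- function(spec_fun, phi_grid, theta_grid, N, cm, c_target,
                          Q = 100, n_real = 100, t_eval = Q, seed = NULL,
                          metric = c("success", "gamma"),
                          inhibition = c("linear", "nonlinear")) {
  metric <- match.arg(metric)
  inhibition <- match.arg(inhibition)
  stopifnot(t_eval >= 1, t_eval <= Q)
  rows <- vector("list", length(phi_grid) * length(theta_grid))
  r <- 0L
  for (iphi in seq_along(phi_grid)) {
    spec <- spec_fun(phi_grid[iphi])
    rs_list <- prepare_realizations(
      spec, N, cm, Q, n_real,
      seed = if (is.null(seed)) NULL else substream_seed(seed, iphi),
      c_target = c_target)
    for (theta in theta_grid) {
      g_eval <- vapply(rs_list, function(rs) {
        realization_gamma(rs, theta, N, cm, inhibition, spec$phi0)[t_eval]
      }, numeric(1))
      val <- if (metric == "success") mean(g_eval > 0.5) else mean(g_eval)
      r <- r + 1L
      rows[[r]] <- data.frame(phi = phi_grid[iphi], theta = theta,
                              value = val)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "metric") <- metric
  attr(out, "n_real") <- n_real
  attr(out, "t_eval") <- t_eval
  out
}

#' Capacity-stability trade-off curve
#'
#' Maximum retrievable sequence length T as a function of the number P of
#' stored associations (with the corresponding ensemble-mean connectivity),
#' plus a power-law fit T ~ P^(-alpha) to the decreasing branch. The fitted
#' line's intersection with the plateau T = Q operationalizes the cutoff
#' capacity Pc at which the curve starts to fall.
#'
#' @inheritParams max_retrievable_length
#' @param P_grid increasing vector of association counts.
#' @return list with `curve` (data.frame P, c, T) and `fit` (see
#'   [fit_capacity()]).
#' @export
capacity_sweep <- function(spec, N, cm, P_grid, theta_grid = 1:60, Q = 100,
                           n_real = 100, seed = NULL,
                           inhibition = c("linear", "nonlinear")) {
  inhibition <- match.arg(inhibition)
  stopifnot(!is.unsorted(P_grid))
  T_vals <- vapply(seq_along(P_grid), function(i) {
    max_retrievable_length(
      spec, N, cm, theta_grid = theta_grid, Q = Q, n_real = n_real,
      seed = if (is.null(seed)) NULL else substream_seed(seed, i),
      P = P_grid[i], inhibition = inhibition)$T
  }, integer(1))
  c_vals <- vapply(P_grid, function(P)
    cm * ensemble_moments(spec, P)$mean_varsigma, numeric(1))
  curve <- data.frame(P = P_grid, c = c_vals, T = T_vals)
  list(curve = curve, fit = fit_capacity(P_grid, T_vals, Q))
}

#' Power-law fit to the decreasing branch of a capacity curve
#'
#' Least-squares fit of log T = const - alpha * log P over the strictly
#' decreasing branch (points after the last maximum with T > 0). The cutoff
#' capacity Pc is where the fitted line meets the plateau T = Q. The fit is
#' skipped (with a warning, `fitted = FALSE`) when fewer than 3 points lie
#' on the branch.
#'
#' @param P association counts.
#' @param T maximum retrievable lengths.
#' @param Q plateau value (full sequence length).
#' @return list with `alpha`, `Pc`, `n_points`, `fitted`.
#' @export
fit_capacity <- function(P, T, Q) {
  stopifnot(length(P) == length(T))
  ipk <- max(which(T == max(T)))
  idx <- which(seq_along(T) > ipk & T > 0)
  if (length(idx) < 3) {
    warning("fewer than 3 points on the decreasing branch; fit skipped")
    return(list(alpha = NA_real_, Pc = NA_real_,
                n_points = length(idx), fitted = FALSE))
  }
  fit <- stats::lm(log(T[idx]) ~ log(P[idx]))
  alpha <- -unname(stats::coef(fit)[2])
  Pc <- exp((unname(stats::coef(fit)[1]) - log(Q)) / alpha)
  list(alpha = alpha, Pc = Pc, n_points = length(idx), fitted = TRUE)
}

#' Pattern-size pairs at sequence termination
#'
#' For each realization, tau is the last time step with retrieval quality
#' Gamma > 0.5; runs that never fail within Q are excluded (and counted).
#' The returned pairs (M_tau, M_tau+1) — size of the last correctly
#' replayed pattern vs. the following one — reveal the termination
#' mechanism: points above the diagonal are failures at small-to-big
#' transitions (insufficient synaptic drive), points below at big-to-small
#' transitions (activity explosion under feedback inhibition).
#'
#' @inheritParams success_rate
#' @return list with `pairs` (data.frame tau, M_tau, M_tau1),
#'   `frac_above` (fraction of failure pairs with M_tau+1 > M_tau),
#'   `n_failed`, `n_completed`.
#' @export
termination_scatter <- function(spec, theta, N, cm, c_target, Q = 100,
                                n_real = 1e4, seed = NULL,
                                inhibition = c("linear", "nonlinear")) {
  inhibition <- match.arg(inhibition)
  tau <- integer(n_real); M1 <- numeric(n_real); M2 <- numeric(n_real)
  failed <- logical(n_real)
  for (i in seq_len(n_real)) {
    rs <- draw_realization(
      spec, N, cm, Q,
      seed = if (is.null(seed)) NULL else substream_seed(seed, i),
      c_target = c_target)
    g <- realization_gamma(rs, theta, N, cm, inhibition, spec$phi0)
    good <- which(c(TRUE, g > 0.5)) - 1L   # the cue (t = 0) always counts
    ta <- max(good)
    if (ta < Q) {
      failed[i] <- TRUE
      tau[i] <- ta
      M1[i] <- rs$f_head[ta + 1] * N
      M2[i] <- rs$f_head[ta + 2] * N
    }
  }
  pairs <- data.frame(tau = tau[failed], M_tau = M1[failed],
                      M_tau1 = M2[failed])
  list(pairs = pairs,
       frac_above = if (nrow(pairs)) mean(pairs$M_tau1 > pairs$M_tau)
                    else NA_real_,
       n_failed = sum(failed), n_completed = sum(!failed))
}
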