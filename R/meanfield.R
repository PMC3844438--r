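#' Mean-field model parameters
#'
#' Parameters of the two-variable mean-field replay map (hits m_t, false
#' alarms n_t) with instantaneous feedback inhibition. The inhibitory weight
#' defaults to b = cm * varsigma, the mean potentiated synaptic weight.
#' For `inhibition = "nonlinear"` the feedback is a sigmoid below the
#' operating point x0 = phi0 * N and linear (b * x) above it, with sigmoid
#' parameters chosen so that h is continuous at x0 with slope b on both
#' branches:
#'
#'   lambda = 1e-4 / phi0,
#'   nu     = x0 - log(lambda * x0 - 1) / lambda,
#'   kappa  = b * lambda * x0^2 / (lambda * x0 - 1).
#'
#' This requires lambda * x0 > 1 (equivalently N > 1e4); otherwise an error
#' is raised.
#'
#' @param N network size (neurons).
#' @param cm morphological connectivity in (0, 1].
#' @param theta firing threshold (synaptic-input units), >= 0.
#' @param varsigma potentiation probability used for the noise input and the
#'   default inhibitory weight (typically the realized varsigma(phi)).
#' @param V2 squared variation coefficient of varsigma_A over activation
#'   schedules (from [schedule_stats()]); 0 drops the learning-induced
#'   synaptic correlations.
#' @param b inhibitory weight; default cm * varsigma.
#' @param inhibition `"linear"` or `"nonlinear"`.
#' @param phi0 mean coding ratio; sets the nonlinear operating point
#'   phi0 * N (required for nonlinear inhibition).
#' @return an object of class `mf_params`.
#' @seealso [replay_params()] to derive all of this from a sampled phi.
#' @export
mf_params <- function(N, cm, theta, varsigma, V2 = 0, b = NULL,
                      inhibition = c("linear", "nonlinear"), phi0 = NULL) {
  inhibition <- match.arg(inhibition)
  stopifnot(N >= 1, cm > 0, cm <= 1, theta >= 0,
            varsigma >= 0, varsigma <= 1, V2 >= 0)
  if (is.null(b)) b <- cm * varsigma
  p <- list(N = N, cm = cm, theta = theta, varsigma = varsigma, V2 = V2,
            b = b, inhibition = inhibition, phi0 = phi0)
  if (inhibition == "nonlinear") {
    if (is.null(phi0)) stop("nonlinear inhibition requires `phi0`")
    x0 <- phi0 * N
    lambda <- 1e-4 / phi0
    if (lambda * x0 <= 1)
      stop("nonlinear inhibition undefined: lambda * phi0 * N = ",
           signif(lambda * x0, 4), " must exceed 1")
    p$x0 <- x0
    p$lambda <- lambda
    p$nu <- x0 - log(lambda * x0 - 1) / lambda
    p$kappa <- b * lambda * x0^2 / (lambda * x0 - 1)
  }
  structure(p, class = "mf_params")
}

#' @export
print.mf_params <- function(x, ...) {
  cat(sprintf(
    "mf_params: N = %g, cm = %g, theta = %g, varsigma = %.4g, V2 = %.4g, b = %.4g, %s inhibition\n",
    x$N, x$cm, x$theta, x$varsigma, x$V2, x$b, x$inhibition))
  invisible(x)
}

#' Mean-field parameters realized from a sampled coding-ratio vector
#'
#' Computes the realized potentiation probability varsigma(phi) and its
#' schedule variation coefficient V2 from the specific sampled vector (not
#' ensemble means) and builds the corresponding [mf_params()], with
#' b = cm * varsigma(phi).
#'
#' @param phi a [pattern_sizes()] or numeric coding-ratio vector.
#' @param N,cm,theta,inhibition,b as in [mf_params()].
#' @param phi0 operating point for nonlinear inhibition; defaults to the
#'   mean of the sampled coding ratios.
#' @return an `mf_params` object.
#' @export
replay_params <- function(phi, N, cm, theta,
                          inhibition = c("linear", "nonlinear"),
                          b = NULL, phi0 = NULL) {
  inhibition <- match.arg(inhibition)
  f <- as_coding_ratios(phi)
  ss <- schedule_stats(f)
  if (is.null(phi0)) phi0 <- mean(f)
  mf_params(N = N, cm = cm, theta = theta, varsigma = ss$varsigma,
            V2 = ss$V2, b = b, inhibition = inhibition, phi0 = phi0)
}

#' Gaussian input moments of the On and Off populations
#'
#' Mean and variance of the total synaptic input to neurons that should fire
#' (On: members of the next pattern) and should stay silent (Off), given the
#' current hits m and false alarms n. The V2 terms carry the synaptic
#' correlations induced by clipped Hebbian learning; they enter only the
#' potentiated-noise contributions. Variances are floored at 0.
#'
#' @param m hits at time t (real-valued neurons).
#' @param n false alarms at time t.
#' @param p an [mf_params()].
#' @return list `mu_on`, `s2_on`, `mu_off`, `s2_off`.
#' @export
input_moments <- function(m, n, p) {
  cm <- p$cm; vs <- p$varsigma; V2 <- p$V2
  mu_on <- cm * m + cm * vs * n
  s2_on <- cm * m * (1 - cm) +
    cm * vs * n * (1 - cm * vs + V2 * cm * vs * (n - 1))
  x <- m + n
  mu_off <- cm * vs * x
  s2_off <- cm * vs * x * (1 - cm * vs + V2 * cm * vs * (x - 1))
  list(mu_on = mu_on, s2_on = max(0, s2_on),
       mu_off = mu_off, s2_off = max(0, s2_off))
}

#' Instantaneous feedback inhibition
#'
#' Inhibitory drive as a function of the total activity x = m_t + n_t at the
#' current step. Linear mode returns b * x; nonlinear mode returns the
#' sigmoid branch for x <= phi0 * N and b * x above, continuous with slope b
#' at the operating point. The sigmoid is close to zero at low activity, so
#' supralinear feedback effectively boosts (dis-inhibits) a network whose
#' activity has dropped below the operating point.
#'
#' @param x total activity (vectorized).
#' @param p an [mf_params()].
#' @return inhibitory drive h(x) in synaptic-input units.
#' @export
inhibition <- function(x, p) {
  if (p$inhibition == "linear") return(p$b * x)
  ifelse(x <= p$x0,
         p$kappa / (1 + exp(-p$lambda * (x - p$nu))),
         p$b * x)
}

#' One step of the mean-field replay map
#'
#' Advances (m, n) by one association: the effective threshold is
#' theta + h(m + n), and the next hits and false alarms are the Gaussian
#' firing probabilities of the On/Off populations scaled by the next pattern
#' size. A vanishing input variance is treated as a hard threshold.
#'
#' @param m,n current hits and false alarms.
#' @param M_next size of the next pattern (real-valued allowed).
#' @param p an [mf_params()].
#' @return numeric c(m_next, n_next).
#' @export
mf_step <- function(m, n, M_next, p) {
  theta_eff <- p$theta + inhibition(m + n, p)
  im <- input_moments(m, n, p)
  m2 <- M_next * gauss_fire(im$mu_on, sqrt(im$s2_on), theta_eff)
  n2 <- (p$N - M_next) * gauss_fire(im$mu_off, sqrt(im$s2_off), theta_eff)
  c(m2, n2)
}

#' Run a mean-field replay of a stored sequence
#'
#' Iterates the mean-field map along the first Q associations of the stored
#' sequence, starting from an intact cue (m_0 = cue * M_0, n_0 = 0; the
#' default cue = 1 is the perfect first pattern). Hits and false alarms are
#' propagated as real-valued expectation values; pattern sizes are the
#' real-valued f_t * N unless `integer_sizes = TRUE`.
#'
#' @param phi a [pattern_sizes()] or numeric coding-ratio vector
#'   (length >= Q + 1).
#' @param p an [mf_params()] (typically from [replay_params()]).
#' @param Q replay length (number of associations), Q <= P.
#' @param cue fraction of the first pattern activated at t = 0.
#' @param integer_sizes use the integerized pattern sizes M_k instead of
#'   f_k * N.
#' @return a data.frame of class `mf_trace` with columns `t` (0..Q), `M`,
#'   `m`, `n`, `gamma` (retrieval quality).
#' @examples
#' phi <- sample_phi(coding_spec("gamma", 0.01, 0), P = 100, N = 1e5, seed = 1)
#' p <- replay_params(phi, N = 1e5, cm = 0.1, theta = 26)
#' tail(run_replay(phi, p, Q = 100), 3)
#' @export
run_replay <- function(phi, p, Q = NULL, cue = 1, integer_sizes = FALSE) {
  f <- as_coding_ratios(phi)
  P <- length(f) - 1L
  if (is.null(Q)) Q <- P
  if (Q > P) stop("Q must not exceed the number of stored associations P")
  M <- if (integer_sizes && inherits(phi, "pattern_sizes"))
    as.numeric(phi$M[seq_len(Q + 1)]) else f[seq_len(Q + 1)] * p$N
  N <- p$N
  m <- numeric(Q + 1); n <- numeric(Q + 1)
  m[1] <- cue * M[1]; n[1] <- 0
  for (t in seq_len(Q)) {
    st <- mf_step(m[t], n[t], M[t + 1], p)
    m[t + 1] <- st[1]; n[t + 1] <- st[2]
  }
  gamma <- m / M - n / (N - M)
  structure(data.frame(t = 0:Q, M = M, m = m, n = n, gamma = gamma),
            class = c("mf_trace", "data.frame"))
}
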