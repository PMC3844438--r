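#' Exact synaptic potentiation probability for a coding-ratio vector
#'
#' Under the clipped-Hebbian (Willshaw) rule, a synapse is potentiated iff
#' its pre-neuron fires in some pattern k-1 and its post-neuron in pattern k,
#' for at least one of the P stored associations. For a given coding-ratio
#' vector phi = (f_0, ..., f_P) the potentiated fraction of morphological
#' synapses is
#'
#'   varsigma = 1 - prod_k (1 - f_k * f_(k-1)).
#'
#' The product is accumulated in log space so that P in the thousands with
#' f ~ 0.01 loses no precision. The effective connectivity is c = cm *
#' varsigma.
#'
#' @param phi a [pattern_sizes()] object or a bare numeric vector of
#'   coding ratios (length P + 1).
#' @return the potentiation probability, a number in \[0, 1\].
#' @examples
#' varsigma_exact(c(0.01, 0.01))           # one association: f1 * f0 = 1e-4
#' varsigma_exact(rep(0.01, 6932))         # ~ 0.5
#' @export
varsigma_exact <- function(phi) {
  f <- as_coding_ratios(phi)
  n <- length(f)
  -expm1(sum(log1p(-f[-1] * f[-n])))
}

#' Classical Willshaw capacity relation (homogeneous sparseness)
#'
#' Number of stored associations P at which a homogeneous network with coding
#' ratio f reaches effective connectivity c, given morphological connectivity
#' cm: P = log(1 - c/cm) / log(1 - f^2). Returns the real-valued solution;
#' callers round as needed.
#'
#' @param c effective (noise) connectivity, 0 < c < cm.
#' @param cm morphological connectivity, 0 < cm <= 1.
#' @param f homogeneous coding ratio, 0 < f < 1.
#' @return real-valued P.
#' @examples
#' willshaw_capacity(c = 0.05, cm = 0.1, f = 0.01)  # ~ 6931.1
#' @export
willshaw_capacity <- function(c, cm, f) {
  stopifnot(cm > 0, cm <= 1, f > 0, f < 1)
  if (any(c <= 0)) stop("`c` must be positive")
  if (any(c >= cm)) stop("`c` must be smaller than `cm`")
  log1p(-c / cm) / log1p(-f^2)
}

#' Activation-schedule statistics of the potentiation probability
#'
#' A neuron's activation schedule records the patterns in which it fires;
#' the fraction varsigma_A of its potentiated inputs depends on the schedule,
#' and the Willshaw rule therefore induces correlations between synapses
#' converging on the same neuron. This returns the schedule average
#' varsigma (identical to [varsigma_exact()]), the second moment
#' E\[varsigma_A^2\] from its closed product form, and the squared variation
#' coefficient V2 = (E\[varsigma_A^2\] - varsigma^2) / varsigma^2 that enters
#' the mean-field input variances. V2 is floored at 0 against roundoff.
#'
#' @inheritParams varsigma_exact
#' @return list with `varsigma`, `E2` (second moment of varsigma_A) and `V2`.
#' @export
schedule_stats <- function(phi) {
  f <- as_coding_ratios(phi)
  n <- length(f)
  fk <- f[-1]; fp <- f[-n]             # f_k and f_(k-1), k = 1..P
  varsigma <- -expm1(sum(log1p(-fk * fp)))
  E2 <- 2 * varsigma - 1 + exp(sum(log1p(-fk * (2 * fp - fp^2))))
  V2 <- if (varsigma > 0) max(0, E2 - varsigma^2) / varsigma^2 else 0
  list(varsigma = varsigma, E2 = E2, V2 = V2)
}

#' Count k-combinations of P ordered elements with j maximal runs
#'
#' `n_combinations(P, k, j)` is the number of k-element subsets of P ordered
#' elements that consist of exactly j maximal runs of adjacent elements:
#' choose(P - k + 1, j) * choose(k - 1, k - j) for
#' j <= min(k, P - k + 1) and 0 otherwise. These counts organize the moment
#' expansion of the ensemble-averaged potentiation probability.
#'
#' @param P number of elements (>= 1).
#' @param k subset size, 1 <= k <= P.
#' @param j number of maximal runs (vectorized).
#' @return integer-valued count(s).
#' @examples
#' n_combinations(5, 3, 1:3)  # 3 6 1
#' @export
n_combinations <- function(P, k, j) {
  stopifnot(P >= 1, k >= 1, k <= P)
  out <- ifelse(j >= 1 & j <= pmin(k, P - k + 1),
                choose(P - k + 1, j) * choose(k - 1, k - j), 0)
  out
}
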