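#' Generate random binary activity patterns
#'
#' Each pattern xi_k has exactly M_k active neurons at uniformly random
#' positions, independent across patterns.
#'
#' @param M integer vector of pattern sizes (length P + 1).
#' @param N network size.
#' @param seed optional integer seed.
#' @return list of sorted integer index vectors (the active neurons).
#' @export
generate_patterns <- function(M, N, seed = NULL) {
  if (inherits(M, "pattern_sizes")) M <- M$M
  stopifnot(all(M >= 1), all(M <= N))
  with_seed_if(seed, lapply(M, function(Mk) sort(sample.int(N, Mk))))
}

#' Store a pattern sequence with the Willshaw rule in a diluted network
#'
#' Builds the binary recurrent network that stores the given sequence:
#' a synapse j -> i is potentiated (s_ij = 1) iff neuron j fires in some
#' pattern xi_k and neuron i in xi_(k+1); a synapse exists morphologically
#' (w_ij = 1) with independent probability cm; the effective weight is
#' J_ij = w_ij * s_ij. Self-connections are excluded. Learning is an
#' idempotent OR over the consecutive pattern pairs, hence order-insensitive.
#'
#' Only the effective weights J (potentiated AND morphological) are
#' materialized as a sparse matrix; for the remaining morphological synapses,
#' which never transmit, only their count is sampled. The joint distribution
#' of J and of the morphological-synapse count is exactly that of the full
#' construction, at a fraction of the memory.
#'
#' @param patterns list of active-neuron index vectors (from
#'   [generate_patterns()]).
#' @param N network size.
#' @param cm morphological connectivity.
#' @param seed optional integer seed.
#' @return object of class `binary_network`: sparse `J` (N x N,
#'   dgCMatrix, post x pre), `nnz_w` (number of morphological synapses),
#'   `nnz_s` (number of potentiated pairs), `patterns`, `f` (realized coding
#'   ratios), `N`, `cm`, `P`.
#' @export
learn_willshaw <- function(patterns, N, cm, seed = NULL) {
  stopifnot(length(patterns) >= 2, cm > 0, cm <= 1)
  P <- length(patterns) - 1L
  with_seed_if(seed, {
    keys <- vector("list", P)
    for (k in seq_len(P)) {
      pre <- patterns[[k]]; post <- patterns[[k + 1]]
      # key encodes (pre, post) as a double; N^2 < 2^53 keeps it exact
      keys[[k]] <- rep((pre - 1) * N, each = length(post)) +
        rep(post - 1, length(pre))
    }
    keys <- unique(unlist(keys))
    pre_id <- keys %/% N + 1
    post_id <- keys %% N + 1
    off_diag <- post_id != pre_id
    pre_id <- pre_id[off_diag]; post_id <- post_id[off_diag]
    nnz_s <- length(pre_id)
    keep <- stats::runif(nnz_s) < cm
    J <- Matrix::sparseMatrix(i = post_id[keep], j = pre_id[keep],
                              x = 1, dims = c(N, N))
    n_rest <- N * (N - 1) - nnz_s      # morphological synapses never potentiated
    nnz_w <- sum(keep) + if (n_rest < 2^31) {
      stats::rbinom(1L, as.integer(n_rest), cm)
    } else {
      round(stats::rnorm(1, n_rest * cm, sqrt(n_rest * cm * (1 - cm))))
    }
    structure(list(J = J, nnz_w = nnz_w, nnz_s = nnz_s,
                   patterns = patterns,
                   f = vapply(patterns, length, integer(1)) / N,
                   N = N, cm = cm, P = P),
              class = "binary_network")
  })
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf(
    "binary_network: N = %d, P = %d associations, cm = %g, potentiation %.4g\n",
    x$N, x$P, x$cm, potentiation_fraction(x)))
  invisible(x)
}

#' Measured potentiation fraction of a learned network
#'
#' Fraction of morphological synapses in the potentiated state; its
#' expectation is varsigma(phi) from [varsigma_exact()].
#'
#' @param net a [learn_willshaw()] network.
#' @return a number in \[0, 1\].
#' @export
potentiation_fraction <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  Matrix::nnzero(net$J) / net$nnz_w
}

#' Simulate replay in the binary network
#'
#' Synchronous threshold dynamics: neuron i fires at t + 1 iff
#' sum_j J_ij x_j(t) - theta - h(|x(t)|) >= 0, where h is the same
#' instantaneous feedback inhibition as in the mean-field model (linear
#' b * x or the supralinear sigmoid). A neuron exactly at threshold fires
#' (`tie = "fire"`, the default; switchable). The network is initialized
#' with the first stored pattern as cue and hits/false alarms are scored
#' against the stored sequence.
#'
#' @param net a [learn_willshaw()] network.
#' @param theta firing threshold.
#' @param Q number of replay steps (<= P).
#' @param b inhibitory weight; default cm * varsigma(phi) of the realized
#'   pattern sequence.
#' @param inhibition `"linear"` or `"nonlinear"`.
#' @param phi0 operating point for nonlinear inhibition (defaults to the
#'   mean realized coding ratio).
#' @param tie `"fire"` or `"silent"`: behaviour of a neuron whose input
#'   exactly equals the effective threshold.
#' @return a data.frame of class `activity_trace` with columns `t` (0..Q),
#'   `M`, `m` (hits), `n` (false alarms), `gamma`.
#' @export
simulate_network <- function(net, theta, Q = net$P, b = NULL,
                             inhibition = c("linear", "nonlinear"),
                             phi0 = NULL, tie = c("fire", "silent")) {
  stopifnot(inherits(net, "binary_network"), Q <= net$P)
  inhibition <- match.arg(inhibition)
  tie <- match.arg(tie)
  vs <- varsigma_exact(net$f)
  if (is.null(b)) b <- net$cm * vs
  p <- mf_params(N = net$N, cm = net$cm, theta = theta, varsigma = vs,
                 b = b, inhibition = inhibition,
                 phi0 = if (is.null(phi0)) mean(net$f) else phi0)
  N <- net$N
  M <- vapply(net$patterns, length, integer(1))[seq_len(Q + 1)]
  x <- numeric(N)
  x[net$patterns[[1]]] <- 1
  m <- integer(Q + 1); n <- integer(Q + 1)
  m[1] <- M[1]; n[1] <- 0L
  for (t in seq_len(Q)) {
    drive <- as.numeric(net$J %*% x) - theta - inhibition(sum(x), p)
    fired <- if (tie == "fire") drive >= 0 else drive > 0
    x <- as.numeric(fired)
    tgt <- net$patterns[[t + 1]]
    m[t + 1] <- as.integer(sum(x[tgt]))
    n[t + 1] <- as.integer(sum(x) - m[t + 1])
  }
  gamma <- m / M - n / (N - M)
  structure(data.frame(t = 0:Q, M = M, m = m, n = n, gamma = gamma),
            class = c("activity_trace", "data.frame"))
}
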