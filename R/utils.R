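# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed
#'
#' One master seed spawns independent per-realization seeds by counter, so
#' ensembles are reproducible and order-independent (changing `n_real` does
#' not reshuffle earlier realizations).
#'
#' @param seed master seed (integer).
#' @param i counter (realization index, >= 0).
#' @return an integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, i) {
  s <- as.double(seed) %% 2147483647
  # affine hash in exact double arithmetic (products stay < 2^53)
  as.integer((s * 48271 + as.double(i) * 16807 + 101) %% 2147483647)
}

# Evaluate expr under a local RNG state when seed is non-NULL.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Gaussian firing probability Phi((mu - thr)/sigma) with the sigma = 0 limit
# defined as a hard threshold (1 if mu > thr, 1/2 at equality).
gauss_fire <- function(mu, sigma, thr) {
  if (sigma > 0) stats::pnorm((mu - thr) / sigma)
  else (mu > thr) + 0.5 * (mu == thr)
}

# Accept either a pattern_sizes object or a bare numeric coding-ratio vector.
as_coding_ratios <- function(phi) {
  if (inherits(phi, "pattern_sizes")) return(phi$f)
  if (is.numeric(phi)) {
    if (length(phi) < 2) stop("need at least two coding ratios (P >= 1)")
    if (any(phi <= 0 | phi >= 1)) stop("coding ratios must lie in (0, 1)")
    return(as.numeric(phi))
  }
  stop("`phi` must be a pattern_sizes object or a numeric vector")
}
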