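#' Coding-ratio distribution specification
#'
#' A coding ratio f is the fraction of the N neurons active in a stored
#' pattern; its distribution p_phi controls how strongly pattern sizes vary
#' along a stored sequence ("inhomogeneous sparseness"). Two families are
#' supported:
#'
#' * `"gamma"`: Gamma distribution with mean `phi0` and standard deviation
#'   `sigma_phi`, parameterized as shape = phi0^2/sigma_phi^2,
#'   scale = sigma_phi^2/phi0. `sigma_phi = 0` is legal and denotes the
#'   degenerate (homogeneous) distribution, a point mass at `phi0`.
#' * `"triangular"`: triangular density with mode `phi_max` and standard
#'   deviation `sigma_phi`. `skew = "symmetric"` is the symmetric triangle
#'   centred on the mode; `"negative"` is the one-sided triangle with all
#'   mass below the mode (an excess of small patterns), `"positive"` its
#'   mirror image above the mode. The one-sided triangles match `sigma_phi`
#'   exactly, which places their mean at `phi_max` -/+ sqrt(2)*sigma_phi.
#'
#' @param family `"gamma"` or `"triangular"`.
#' @param phi0 mean coding ratio (gamma family), 0 < phi0 < 1.
#' @param sigma_phi standard deviation of the coding ratio, >= 0
#'   (strictly > 0 for the triangular family).
#' @param phi_max mode of the triangular density (ignored for gamma).
#' @param skew `"symmetric"`, `"negative"` or `"positive"` (triangular only).
#' @return an object of class `coding_spec` with fields `family`, `phi0`,
#'   `sigma_phi`, `phi_max`, `skew` and, for triangular, the `support`.
#' @seealso [triangular_spec()], [sample_phi()], [phi_moments()]
#' @examples
#' coding_spec("gamma", phi0 = 0.01, sigma_phi = 0.001)
#' coding_spec("triangular", phi_max = 0.01, sigma_phi = 0.001,
#'             skew = "negative")
#' @export
coding_spec <- function(family = c("gamma", "triangular"),
                        phi0 = NULL, sigma_phi = NULL, phi_max = NULL,
                        skew = c("symmetric", "negative", "positive")) {
  family <- match.arg(family)
  skew <- match.arg(skew)
  if (is.null(sigma_phi) || !is.numeric(sigma_phi) || length(sigma_phi) != 1 ||
      is.na(sigma_phi) || sigma_phi < 0)
    stop("`sigma_phi` must be a single number >= 0")

  if (family == "gamma") {
    if (is.null(phi0) || !is.numeric(phi0) || length(phi0) != 1 ||
        is.na(phi0) || phi0 <= 0 || phi0 >= 1)
      stop("`phi0` must be a single number in (0, 1)")
    spec <- list(family = "gamma", phi0 = phi0, sigma_phi = sigma_phi,
                 phi_max = NA_real_, skew = NA_character_,
                 support = c(0, Inf))
  } else {
    if (is.null(phi_max) || !is.numeric(phi_max) || length(phi_max) != 1 ||
        is.na(phi_max) || phi_max <= 0 || phi_max >= 1)
      stop("`phi_max` must be a single number in (0, 1)")
    if (sigma_phi <= 0)
      stop("the triangular family needs `sigma_phi` > 0")
    support <- switch(skew,
      symmetric = phi_max + c(-1, 1) * sqrt(6) * sigma_phi,
      negative  = c(phi_max - 3 * sqrt(2) * sigma_phi, phi_max),
      positive  = c(phi_max, phi_max + 3 * sqrt(2) * sigma_phi))
    if (support[1] <= 0 || support[2] >= 1)
      stop("triangular support [", signif(support[1], 4), ", ",
           signif(support[2], 4), "] leaves (0, 1)")
    phi0 <- switch(skew,
      symmetric = phi_max,
      negative  = phi_max - sqrt(2) * sigma_phi,
      positive  = phi_max + sqrt(2) * sigma_phi)
    spec <- list(family = "triangular", phi0 = phi0, sigma_phi = sigma_phi,
                 phi_max = phi_max, skew = skew, support = support)
  }
  structure(spec, class = "coding_spec")
}

#' Triangular coding-ratio specification from mode, spread and skew
#'
#' Convenience constructor for the skewness experiments: fixes the mode at
#' `phi_max`, matches the standard deviation `sigma_phi` exactly, and places
#' the mass symmetrically, entirely below, or entirely above the mode.
#'
#' @inheritParams coding_spec
#' @return a `coding_spec` of the triangular family. Its `phi0` field reports
#'   the achieved mean: `phi_max` for the symmetric case and
#'   `phi_max -/+ sqrt(2)*sigma_phi` for the one-sided cases.
#' @export
triangular_spec <- function(phi_max, sigma_phi,
                            skew = c("symmetric", "negative", "positive")) {
  coding_spec("triangular", phi_max = phi_max, sigma_phi = sigma_phi,
              skew = match.arg(skew))
}

#' @export
print.coding_spec <- function(x, ...) {
  if (x$family == "gamma") {
    cat(sprintf("coding_spec: gamma, phi0 = %g, sigma_phi = %g%s\n",
                x$phi0, x$sigma_phi,
                if (x$sigma_phi == 0) " (homogeneous)" else ""))
  } else {
    cat(sprintf(
      "coding_spec: triangular (%s), mode = %g, sigma_phi = %g, mean = %g\n",
      x$skew, x$phi_max, x$sigma_phi, x$phi0))
  }
  invisible(x)
}

# Density of the coding-ratio distribution (vectorized in x).
phi_density <- function(spec) {
  stopifnot(inherits(spec, "coding_spec"))
  if (spec$family == "gamma") {
    if (spec$sigma_phi == 0)
      stop("the degenerate distribution has no density")
    shape <- spec$phi0^2 / spec$sigma_phi^2
    scale <- spec$sigma_phi^2 / spec$phi0
    return(function(x) stats::dgamma(x, shape = shape, scale = scale))
  }
  lo <- spec$support[1]; hi <- spec$support[2]; mode <- spec$phi_max
  function(x) {
    d <- numeric(length(x))
    if (spec$skew == "symmetric") {
      up <- x >= lo & x <= mode
      dn <- x > mode & x <= hi
      d[up] <- 2 * (x[up] - lo) / ((hi - lo) * (mode - lo))
      d[dn] <- 2 * (hi - x[dn]) / ((hi - lo) * (hi - mode))
    } else if (spec$skew == "negative") {
      inb <- x >= lo & x <= hi
      d[inb] <- 2 * (x[inb] - lo) / (hi - lo)^2
    } else {
      inb <- x >= lo & x <= hi
      d[inb] <- 2 * (hi - x[inb]) / (hi - lo)^2
    }
    d
  }
}

# Draw n coding ratios (no rejection handling; see sample_phi).
r_coding <- function(spec, n) {
  if (spec$family == "gamma") {
    if (spec$sigma_phi == 0) return(rep(spec$phi0, n))
    shape <- spec$phi0^2 / spec$sigma_phi^2
    scale <- spec$sigma_phi^2 / spec$phi0
    return(stats::rgamma(n, shape = shape, scale = scale))
  }
  lo <- spec$support[1]; hi <- spec$support[2]; mode <- spec$phi_max
  u <- stats::runif(n)
  if (spec$skew == "symmetric") {
    w <- hi - lo
    fc <- (mode - lo) / w
    ifelse(u < fc,
           lo + sqrt(u * w * (mode - lo)),
           hi - sqrt((1 - u) * w * (hi - mode)))
  } else if (spec$skew == "negative") {
    lo + (hi - lo) * sqrt(u)            # rising right triangle, mode at hi
  } else {
    lo + (hi - lo) * (1 - sqrt(1 - u))  # falling right triangle, mode at lo
  }
}

#' First four raw moments of the coding-ratio distribution
#'
#' For the Gamma family the moments are closed-form in (phi0, sigma_phi);
#' for the triangular family they are obtained by numeric quadrature over the
#' density. The degenerate case sigma_phi = 0 returns phi0^k.
#'
#' @param spec a [coding_spec()].
#' @return named numeric vector `c(m1, m2, m3, m4)` with `mk` = E\[f^k\].
#' @examples
#' phi_moments(coding_spec("gamma", phi0 = 0.01, sigma_phi = 0.002))
#' @export
phi_moments <- function(spec) {
  stopifnot(inherits(spec, "coding_spec"))
  if (spec$family == "gamma") {
    p0 <- spec$phi0; s <- spec$sigma_phi
    if (s == 0) {
      m <- p0^(1:4)
    } else {
      shape <- p0^2 / s^2
      scale <- s^2 / p0
      m <- vapply(1:4, function(k) scale^k * prod(shape + 0:(k - 1)),
                  numeric(1))
    }
  } else {
    dens <- phi_density(spec)
    m <- vapply(1:4, function(k) {
      stats::integrate(function(x) x^k * dens(x),
                       spec$support[1], spec$support[2],
                       rel.tol = 1e-12, abs.tol = 0)$value
    }, numeric(1))
  }
  names(m) <- c("m1", "m2", "m3", "m4")
  m
}

#' Sample a coding-ratio vector and its integer pattern sizes
#'
#' Draws P + 1 i.i.d. coding ratios f_0, ..., f_P from `spec` and converts
#' them to pattern sizes M_k. Draws with f >= 1 or round(f * N) < 1 are
#' rejected and resampled (at most 1000 rounds). Integer sizes are
#' M_k = round(f_k * N) clamped to >= 1; the mean-field equations consume the
#' real-valued sizes f_k * N instead (see [run_replay()]).
#'
#' @param spec a [coding_spec()].
#' @param P number of stored associations (>= 1); the vector has P + 1
#'   entries, f_0 being the cue pattern's coding ratio.
#' @param N network size (neurons).
#' @param seed optional integer seed; the draw is deterministic given it.
#' @return an object of class `pattern_sizes`: list with elements `f`
#'   (numeric, length P + 1), `M` (integer sizes), `N`, `P`.
#' @examples
#' sample_phi(coding_spec("gamma", phi0 = 0.01, sigma_phi = 0.001),
#'            P = 5, N = 1e5, seed = 1)
#' @export
sample_phi <- function(spec, P, N, seed = NULL) {
  stopifnot(inherits(spec, "coding_spec"), P >= 1, N >= 1)
  f <- with_seed_if(seed, {
    x <- r_coding(spec, P + 1)
    bad <- x >= 1 | round(x * N) < 1
    rounds <- 0L
    while (any(bad)) {
      rounds <- rounds + 1L
      if (rounds > 1000L)
        stop("rejection sampling failed after 1000 rounds; ",
             "spec support is incompatible with N = ", N)
      x[bad] <- r_coding(spec, sum(bad))
      bad <- x >= 1 | round(x * N) < 1
    }
    x
  })
  pattern_sizes(f, N)
}

#' Construct a pattern-size vector from coding ratios
#'
#' @param f numeric vector of P + 1 coding ratios in (0, 1).
#' @param N network size.
#' @return object of class `pattern_sizes`.
#' @export
pattern_sizes <- function(f, N) {
  f <- as.numeric(f)
  if (length(f) < 2) stop("need at least two coding ratios (P >= 1)")
  if (any(f <= 0 | f >= 1)) stop("coding ratios must lie in (0, 1)")
  M <- pmax(1L, as.integer(round(f * N)))
  structure(list(f = f, M = M, N = N, P = length(f) - 1L),
            class = "pattern_sizes")
}

#' @export
print.pattern_sizes <- function(x, ...) {
  cat(sprintf(
    "pattern_sizes: P = %d associations, N = %g, mean f = %.4g, sd f = %.3g\n",
    x$P, x$N, mean(x$f), stats::sd(x$f)))
  invisible(x)
}
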