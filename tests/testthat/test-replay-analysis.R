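spec_hom <- coding_spec("gamma", phi0 = 0.01, sigma_phi = 0)

test_that("retrieval quality is the hit/false-alarm contrast", {
  expect_equal(retrieval_quality(1000, 0, 1000, 1e5), 1)
  expect_equal(retrieval_quality(500, 0.5 * (1e5 - 1000), 1000, 1e5), 0)
  expect_equal(retrieval_quality(900, 0.1 * (1e5 - 1000), 1000, 1e5), 0.8)
  expect_error(retrieval_quality(1, 1, 0, 10))
})

test_that("success rate is 1 in the homogeneous stable wedge and binary for one run", {
  sc <- success_rate(spec_hom, theta = 26, N = 1e5, cm = 0.1, Q = 100,
                     n_real = 3, seed = 1, c_target = 0.05)
  expect_equal(sc$rho, rep(1, 100))
  sc1 <- success_rate(spec_hom, theta = 200, N = 1e5, cm = 0.1, Q = 10,
                      n_real = 1, seed = 1, c_target = 0.05)
  expect_true(all(sc1$rho %in% c(0, 1)))
  expect_equal(sc1$rho, rep(0, 10))
  # determinism under a fixed master seed
  spec <- coding_spec("gamma", phi0 = 0.01, sigma_phi = 0.002)
  a <- success_rate(spec, 27, 1e5, 0.1, Q = 20, n_real = 5, seed = 9,
                    c_target = 0.05)
  b <- success_rate(spec, 27, 1e5, 0.1, Q = 20, n_real = 5, seed = 9,
                    c_target = 0.05)
  expect_identical(a, b)
})

test_that("t90 uses the strict prefix convention", {
  expect_equal(t90(rep(1, 50)), 50)
  expect_equal(t90(c(1, 1, 0.85, 1, 1)), 2)
  expect_equal(t90(c(0.9, 1, 1)), 0)   # strict: 0.9 does not count
  expect_equal(t90(data.frame(t = 1:3, rho = c(1, 0.95, 0.91))), 3)
})

test_that("maximum retrievable length maximizes t90 over the threshold grid", {
  r <- max_retrievable_length(spec_hom, N = 1e5, cm = 0.1,
                              theta_grid = c(10, 26, 28, 50), Q = 20,
                              n_real = 1, seed = 2, c_target = 0.05)
  expect_equal(r$T, 20L)
  expect_true(r$theta_opt %in% c(26, 28))
  expect_equal(r$T, max(r$per_theta$t90))
  # a subset grid can never do better
  r_sub <- max_retrievable_length(spec_hom, N = 1e5, cm = 0.1,
                                  theta_grid = c(10, 50), Q = 20,
                                  n_real = 1, seed = 2, c_target = 0.05)
  expect_lte(r_sub$T, r$T)
})

test_that("homogeneous storage limit agrees with a direct connectivity scan", {
  # package route: bisection on P with the full pipeline
  got <- largest_stable_P(spec_hom, N = 1e5, cm = 0.1, theta_grid = 20:40,
                          T_min = 10, n_real = 1, seed = 3, P_hi = 4096)
  # oracle route: scan the independently coded homogeneous map over the
  # effective connectivity, then invert the capacity relation
  c_max <- hom_max_stable_c(0.01, 1e5, 0.1, theta_grid = 20:40, T_min = 10)
  P_pred <- willshaw_capacity(c_max, 0.1, 0.01)
  expect_lt(abs(got$P_max - P_pred) / P_pred, 0.01)
})

test_that("power-law fit recovers a planted exponent and flags short branches", {
  P <- c(100, 200, 400, 800, 1600, 3200)
  T_pl <- round(1e7 * P^(-2))
  fit <- fit_capacity(P, T_pl, Q = 1e3)
  expect_true(fit$fitted)
  expect_equal(fit$alpha, 2, tolerance = 0.01)
  # Pc solves A * P^-2 = Q
  expect_equal(fit$Pc, sqrt(1e7 / 1e3), tolerance = 0.05)
  expect_warning(f2 <- fit_capacity(c(10, 20, 40), c(5, 3, 2), Q = 10),
                 "skipped")
  expect_false(f2$fitted)
})

test_that("homogeneous capacity curve falls near-vertically past the plateau", {
  sw <- capacity_sweep(spec_hom, N = 1e5, cm = 0.1,
                       P_grid = seq(7000, 11000, by = 500),
                       theta_grid = 20:45, Q = 15, n_real = 1, seed = 4)
  T_ <- sw$curve$T
  expect_equal(T_[1], 15L)                 # below capacity: full plateau
  expect_true(all(diff(T_) <= 0))
  # effectively infinite log-log slope: the curve loses two thirds of the
  # plateau within ~15% of P past the last full-retrieval point
  P_edge <- max(sw$curve$P[T_ == 15])
  P_low <- min(sw$curve$P[T_ <= 5])
  expect_lte(P_low / P_edge, 1.2)
})

test_that("stronger inhomogeneity flattens the capacity trade-off", {
  spec5 <- coding_spec("gamma", phi0 = 0.01, sigma_phi = 0.0005)
  spec25 <- coding_spec("gamma", phi0 = 0.01, sigma_phi = 0.0025)
  sw5 <- capacity_sweep(spec5, N = 1e5, cm = 0.1,
                        P_grid = c(8000, 9000, 10000, 11000, 12500, 14000),
                        theta_grid = 22:40, Q = 30, n_real = 30, seed = 5)
  sw25 <- capacity_sweep(spec25, N = 1e5, cm = 0.1,
                         P_grid = c(2500, 3500, 5000, 7000, 10000),
                         theta_grid = 22:40, Q = 30, n_real = 30, seed = 5)
  expect_true(sw5$fit$fitted && sw25$fit$fitted)
  expect_lt(sw25$fit$alpha, sw5$fit$alpha)
  # the cutoff capacity also shrinks with inhomogeneity
  expect_lt(sw25$fit$Pc, sw5$fit$Pc)
})

test_that("termination pairs sit on the diagonal for homogeneous sizes", {
  # choose a threshold at which even the homogeneous network dies
  sc <- termination_scatter(spec_hom, theta = 40, N = 1e5, cm = 0.1,
                            c_target = 0.05, Q = 20, n_real = 5, seed = 6)
  expect_equal(sc$n_failed, 5)
  expect_true(all(sc$pairs$M_tau == sc$pairs$M_tau1))
  expect_equal(sc$frac_above, 0)
})

test_that("failures concentrate on small-to-big transitions at the high-threshold edge", {
  spec15 <- coding_spec("gamma", phi0 = 0.01, sigma_phi = 0.0015)
  hi <- termination_scatter(spec15, theta = 30, N = 1e5, cm = 0.1,
                            c_target = 0.05, Q = 100, n_real = 300, seed = 7)
  lo <- termination_scatter(spec15, theta = 25, N = 1e5, cm = 0.1,
                            c_target = 0.05, Q = 100, n_real = 300, seed = 7)
  expect_gt(hi$frac_above, 0.7)
  expect_lt(abs(lo$frac_above - 0.5), 0.15)
  expect_gt(hi$frac_above, lo$frac_above)
})

test_that("phase diagram fails everywhere at huge thresholds and is reproducible", {
  sf <- function(phi) coding_spec("gamma", phi0 = phi, sigma_phi = 0.1 * phi)
  pd <- phase_diagram(sf, phi_grid = c(0.008, 0.012), theta_grid = c(27, 500),
                      N = 1e5, cm = 0.1, c_target = 0.05, Q = 30,
                      n_real = 10, seed = 8)
  expect_true(all(pd$value[pd$theta == 500] == 0))
  pd2 <- phase_diagram(sf, phi_grid = c(0.008, 0.012), theta_grid = c(27, 500),
                       N = 1e5, cm = 0.1, c_target = 0.05, Q = 30,
                       n_real = 10, seed = 8)
  expect_identical(pd, pd2)
  expect_true(all(pd$value >= 0 & pd$value <= 1))
})

test_that("widening inhomogeneity erodes the wedge mainly from the high-theta side", {
  sf0 <- function(phi) coding_spec("gamma", phi0 = phi, sigma_phi = 0)
  sf10 <- function(phi) coding_spec("gamma", phi0 = phi, sigma_phi = 0.1 * phi)
  pd0 <- phase_diagram(sf0, 0.01, 20:36, N = 1e5,
                       cm = 0.1, c_target = 0.05, Q = 100, n_real = 1,
                       seed = 9)
  pd10 <- phase_diagram(sf10, 0.01, 20:36, N = 1e5,
                        cm = 0.1, c_target = 0.05, Q = 100, n_real = 40,
                        seed = 9)
  band0 <- range(pd0$theta[pd0$value > 0.5])
  band10 <- range(pd10$theta[pd10$value > 0.5])
  # the wedge shrinks, and the high-theta boundary retreats further than the
  # low-theta boundary advances
  expect_lt(diff(band10), diff(band0))
  expect_gt(band0[2] - band10[2], band10[1] - band0[1])
})
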