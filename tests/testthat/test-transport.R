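test_that("transported fraction follows the occupancy balance", {
  expect_equal(transported_fraction(0, 0.5), 0)
  expect_equal(transported_fraction(0.5, 0.5), 2 / 3)
  expect_equal(transported_fraction(0.25, 0.5), 1 / 2)
  expect_error(transported_fraction(0.1, 0), class = "dendrocost_config_error")
})

test_that("three-state model reduces to diffusion-decay without runs", {
  tp <- transport_params(v = 0, beta = 0.5, alpha = 0.1)
  prof <- solve_three_state(tp, lambda_m = 1e-4, D_m0 = 0.04, L = 50,
                            dx = 0.05)
  l <- sqrt(0.04 / 1e-4)
  ref <- cosh((50 - prof$x) / l) / cosh(50 / l)
  ref <- ref / dendrocost:::trapz(prof$x, ref)
  expect_lt(max(abs(prof$total - ref)) / max(ref), 1e-6)
})

test_that("fast decay confines the profile near the soma, monotonically", {
  tp <- transport_params(v = 1, beta = 0.5, theta = 0.1)
  prof <- solve_three_state(tp, lambda_m = 0.05, D_m0 = 0.01, L = 100)
  expect_true(all(diff(prof$total) <= 1e-12 * max(prof$total)))
  # mass concentrated in the proximal tenth of the dendrite
  i <- prof$x <= 10
  expect_gt(dendrocost:::trapz(prof$x[i], prof$total[i]), 0.9)
})

test_that("three-state steady state matches a stochastic particle oracle", {
  tp <- transport_params(v = 0.5, beta = 0.5, alpha = 0.05)
  lambda <- 0.01; D0 <- 0.01; L <- 20
  prof <- solve_three_state(tp, lambda, D0, L, dx = 0.05)
  sim <- simulate_transport_particles(tp, lambda, D0, L,
                                      n_particles = 5000, burn_in = 400,
                                      n_snapshots = 12, snapshot_every = 150,
                                      dt = 0.04, seed = 42)
  breaks <- seq(0, 12, by = 2)
  props <- t(vapply(sim$positions, function(xs) {
    h <- hist(pmin(xs, L), breaks = c(breaks, L), plot = FALSE)$counts
    (h / length(xs))[seq_len(length(breaks) - 1)]
  }, numeric(length(breaks) - 1)))
  mean_p <- colMeans(props)
  se_p <- apply(props, 2, sd) / sqrt(nrow(props))
  # analytic bin masses
  dens <- function(x) approx(prof$x, prof$total, x)$y
  expected <- vapply(seq_len(length(breaks) - 1), function(j)
    integrate(dens, breaks[j], breaks[j + 1])$value, numeric(1))
  expect_true(all(abs(mean_p - expected) <= 3 * pmax(se_p, 1e-4)),
              info = paste(round((mean_p - expected) / pmax(se_p, 1e-4), 2),
                           collapse = " "))
})

test_that("effective diffusion recovers the resting constant without runs", {
  tp <- transport_params(v = 0, beta = 0.5, alpha = 0.1)
  D <- effective_diffusion(tp, lambda_m = 1e-4, D_m0 = 0.04, L = 100,
                           dx = 0.1)
  expect_lt(abs(D - 0.04) / 0.04, 0.01)
})

test_that("effective diffusion grows with the re-entry rate", {
  Ds <- vapply(c(0.01, 0.03, 0.1, 0.3, 1), function(a)
    as.numeric(effective_diffusion(transport_params(v = 1, beta = 0.5,
                                                    alpha = a),
                                   lambda_m = 1e-4, D_m0 = 0.005, L = 300)),
    numeric(1))
  expect_true(all(diff(Ds) > 0))
  expect_true(all(Ds > 0.005))          # motor transport never slows mixing
  # near-permanent runs: ballistic-dominated spread far above resting D
  expect_gt(Ds[length(Ds)], 50 * 0.005)
})

test_that("flat profiles are reported as unidentifiable", {
  tp <- transport_params(v = 1, beta = 0.5, theta = 0.2)
  expect_error(effective_diffusion(tp, lambda_m = 1e-12, D_m0 = 1, L = 5),
               class = "dendrocost_numeric_error")
})

test_that("decay-length matching agrees with the profile fit to leading order", {
  tp <- transport_params(v = 1, beta = 0.5, theta = 0.1)
  D1 <- effective_diffusion(tp, 1e-4, 0.005, 200, strategy = "profile")
  D2 <- effective_diffusion(tp, 1e-4, 0.005, 200, strategy = "length")
  expect_lt(abs(D1 - D2) / D1, 0.15)
})
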