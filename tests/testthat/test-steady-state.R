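test_that("quasi-steady spine occupancy saturates at capacity", {
  sp <- fast_species()
  geom <- small_geom()
  cap <- geom$rho * sp$eta_p
  expect_equal(spine_occupancy(0, sp, geom), 0)
  expect_lt(spine_occupancy(1e12, sp, geom), cap)
  expect_gt(spine_occupancy(1e12, sp, geom), 0.9999 * cap)
  # the distal filling condition: at the boundary shaft density
  # ((nu+lambda)/u)(phi/(1-phi)) rho eta, occupancy is exactly phi
  p_bc <- (sp$nu_p + sp$lambda_p) / sp$u_p *
    (geom$phi / (1 - geom$phi)) * cap
  expect_equal(spine_occupancy(p_bc, sp, geom), geom$phi * cap,
               tolerance = 1e-12)
})

test_that("dendritic mRNA matches the closed-form diffusion-decay profile", {
  sp <- fast_species()
  geom <- small_geom(L = 200)
  prof <- solve_steady(sp, geom, "dendritic", r_soma = 0.3)
  l <- sqrt(prof$D_m_eff / sp$lambda_m)
  ref <- cosh((geom$L - prof$x) / l) / cosh(geom$L / l)
  expect_lt(max(abs(prof$m / prof$m[1] - ref)), 1e-6)
})

test_that("synthesis balances degradation at steady state", {
  sp <- fast_species()
  for (scen in list(list("somatic", NULL), list("dendritic", 0.2),
                    list("dendritic", 0.8))) {
    geom <- small_geom(L = 150)
    prof <- solve_steady(sp, geom, scen[[1]], r_soma = scen[[2]])
    tc <- total_counts(prof, geom)
    synthesis <- sp$tau * tc$M_total
    degradation <- sp$lambda_p * tc$P_total
    expect_lt(abs(synthesis - degradation) / synthesis, 1e-3)
    expect_true(all(prof$p >= 0) && all(prof$m >= 0) &&
                  all(prof$p_spine >= 0))
    expect_true(all(prof$p_spine <= geom$rho * sp$eta_p * (1 + 1e-12)))
    # distal spine filled to exactly phi of capacity
    expect_equal(min(prof$p_spine) / (geom$rho * sp$eta_p), geom$phi,
                 tolerance = 1e-6)
  }
})

test_that("Newton solver agrees with an independent dense Picard oracle", {
  sp <- fast_species(eta_p = 800, D_p = 0.05)
  geom <- small_geom(L = 80)
  r <- 0.4
  prof <- solve_steady(sp, geom, "dendritic", r_soma = r)
  oracle <- dense_oracle_profile(sp, geom, r)
  expect_lt(max(abs(prof$p - oracle$p)) / max(oracle$p), 1e-8)
  expect_lt(max(abs(prof$p_spine - oracle$ps)) / max(oracle$ps), 1e-8)
})

test_that("solved profiles are fixed points under time integration", {
  skip_if_not_installed("deSolve")
  sp <- fast_species()
  geom <- small_geom(L = 100)
  prof <- solve_steady(sp, geom, "dendritic", r_soma = 0.3)
  J_m0 <- sp$lambda_m * dendrocost:::trapz(prof$x, prof$m)
  y0 <- c(prof$m, prof$p, prof$p_spine)
  out <- deSolve::ode(
    y = y0, times = c(0, 1e5),
    func = function(t, y, parms)
      list(model_rhs(y, sp, geom, J_m0, prof$J0, prof$D_m_eff)),
    rtol = 1e-9, atol = 1e-9 * max(y0))
  yT <- out[nrow(out), -1]
  n <- length(prof$x)
  # protein fields sit on the solver's own discrete operator: no drift
  expect_lt(max(abs(yT[(n + 1):(3 * n)] - y0[(n + 1):(3 * n)])) /
              max(y0[(n + 1):(2 * n)]), 1e-5)
  # the analytic mRNA profile drifts only by the O(dx^2) discretisation gap
  expect_lt(max(abs(yT[1:n] - y0[1:n])) / max(y0[1:n]), 5e-3)
})

test_that("total counts integrate densities plus somatic pools", {
  sp <- fast_species()
  geom <- small_geom(L = 100)
  blank <- structure(list(x = seq(0, 100), m = rep(0, 101), p = rep(0, 101),
                          p_spine = rep(0, 101), m_soma = 0, p_soma = 0,
                          geom = geom), class = "spatial_profile")
  expect_equal(total_counts(blank, geom)$M_total, 0)
  expect_equal(total_counts(blank, geom)$P_total, 0)
  uni <- blank
  uni$p <- rep(3, 101)
  expect_equal(total_counts(uni, geom)$P_total, 300)
})

test_that("doubling spine capacity doubles every molecule count", {
  geom <- small_geom(L = 100)
  t1 <- total_counts(solve_steady(fast_species(eta_p = 400), geom,
                                  "dendritic", r_soma = 0.3), geom)
  t2 <- total_counts(solve_steady(fast_species(eta_p = 800), geom,
                                  "dendritic", r_soma = 0.3), geom)
  expect_equal(t2$P_total / t1$P_total, 2, tolerance = 1e-9)
  expect_equal(t2$M_total / t1$M_total, 2, tolerance = 1e-9)
})

test_that("solution is stable under grid refinement", {
  sp <- fast_species()
  p1 <- solve_steady(sp, small_geom(L = 100, dx = 1), "dendritic",
                     r_soma = 0.3)
  p2 <- solve_steady(sp, small_geom(L = 100, dx = 0.5), "dendritic",
                     r_soma = 0.3)
  t1 <- total_counts(p1)
  t2 <- total_counts(p2)
  expect_lt(abs(t1$P_total - t2$P_total) / t2$P_total, 1e-3)
  expect_lt(abs(t1$M_total - t2$M_total) / t2$M_total, 1e-3)
})

test_that("invalid scenarios are rejected", {
  sp <- fast_species()
  geom <- small_geom()
  expect_error(solve_steady(sp, geom, "dendritic"),
               class = "dendrocost_config_error")
  expect_error(solve_steady(sp, geom, "dendritic", r_soma = 1),
               class = "dendrocost_config_error")
})
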