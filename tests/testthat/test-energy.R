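fake_profile <- function(x, m, m_soma = 0, scenario = "dendritic") {
  structure(list(x = x, m = m, p = rep(0, length(x)),
                 p_spine = rep(0, length(x)), m_soma = m_soma, p_soma = 0,
                 scenario = scenario, r_soma = 0.5), class = "spatial_profile")
}

test_that("cost terms implement the ATP bookkeeping constants", {
  x <- seq(0, 100)
  sp <- fast_species(N_aa = 478, N_nt = 4900, halflife_m = log(2) / 0.5,
                     tau = 0.01)
  # a somatic pool decaying at 0.5/s in total: lambda_m * m_soma = 0.5
  prof <- fake_profile(x, rep(0, 101), m_soma = 1)
  expect_equal(transcription_cost(prof, sp), 2.17 * 4900 * 0.5)
  # one synthesised protein per second costs C_aa per residue
  sp2 <- fast_species(N_aa = 478, tau = 1)
  expect_equal(translation_cost(fake_profile(x, rep(0, 101), m_soma = 1), sp2),
               5 * 478)
  # no mRNA anywhere: nothing to pay
  none <- fake_profile(x, rep(0, 101), m_soma = 0)
  expect_equal(transcription_cost(none, sp), 0)
  expect_equal(translation_cost(none, sp), 0)
  expect_equal(transport_cost(none, sp), 0)
})

test_that("transport cost counts moving granules at the reference speed", {
  x <- seq(0, 100)
  sp <- fast_species(transport = transport_params(v = 1, beta = 0.5,
                                                  theta = 0.5))
  # 20 dendritic mRNAs, half in transit -> 10 moving cargoes
  prof <- fake_profile(x, rep(0.2, 101))
  expect_equal(transport_cost(prof, sp), 125 * 10)
  # granule packaging divides the cargo count
  sp10 <- fast_species(transport = transport_params(v = 1, beta = 0.5,
                                                    theta = 0.5),
                       mrnas_per_granule = 10)
  expect_equal(transport_cost(prof, sp10), 125 * 1)
  # cost scales linearly with run velocity
  sp2v <- fast_species(transport = transport_params(v = 2, beta = 0.5,
                                                    theta = 0.5))
  expect_equal(transport_cost(prof, sp2v), 2 * 125 * 10)
  # theta = 0: nothing moves
  sp0 <- fast_species(transport = transport_params(v = 1, beta = 0.5,
                                                   theta = 0))
  expect_equal(transport_cost(prof, sp0), 0)
})

test_that("budgets are additive and somatic scenarios pay no transport", {
  sp <- fast_species()
  geom <- small_geom(L = 120)
  for (scen in list(list("somatic", NULL), list("dendritic", 0.3))) {
    prof <- solve_steady(sp, geom, scen[[1]], r_soma = scen[[2]])
    b <- energy_budget(prof, sp)
    expect_equal(b$total, b$transcription + b$translation + b$transport)
    expect_true(all(c(b$transcription, b$translation, b$transport) >= 0))
    if (scen[[1]] == "somatic") expect_equal(b$transport, 0)
  }
})

test_that("spine capacity rescales budgets but never the decision", {
  geom <- small_geom(L = 120)
  d1 <- decide(fast_species(eta_p = 300), geom)
  d2 <- decide(fast_species(eta_p = 3000), geom)
  expect_equal(d1$preferred, d2$preferred)
  expect_equal(d1$cost_ratio, d2$cost_ratio, tolerance = 1e-9)
  expect_equal(d1$r_soma_opt, d2$r_soma_opt)
  expect_equal(d2$budget_somatic$total / d1$budget_somatic$total, 10,
               tolerance = 1e-9)
})

test_that("decision picks the cheaper strategy over the r_soma sweep", {
  sp <- fast_species()
  geom <- small_geom(L = 120)
  d <- decide(sp, geom)
  expect_true(d$preferred %in% c("somatic", "dendritic"))
  expect_equal(d$cost_ratio,
               d$budget_somatic$total / d$budget_dendritic$total)
  if (d$preferred == "dendritic") expect_gt(d$cost_ratio, 1)
  else expect_lte(d$cost_ratio, 1)
  # the reported dendritic budget is the sweep minimum
  totals <- vapply(seq(0.1, 0.9, by = 0.1), function(r)
    energy_budget(solve_steady(sp, geom, "dendritic", r_soma = r), sp)$total,
    numeric(1))
  expect_equal(d$budget_dendritic$total, min(totals), tolerance = 1e-12)
  expect_error(decide(sp, geom, r_soma_grid = c(0, 0.5)),
               class = "dendrocost_config_error")
})

test_that("cumulative dendritic cost profile is a normalised CDF", {
  sp <- fast_species()
  x <- seq(0, 100)
  # uniform dendritic mRNA: cost accrues linearly with distance
  cc <- cumulative_cost_profile(fake_profile(x, rep(1, 101)), sp)
  expect_equal(cc$cumulative[length(x)], 1)
  expect_equal(cc$cumulative, x / 100, tolerance = 1e-12)
  # decaying mRNA: concave curve, half the cost within the proximal part
  m <- exp(-x / 20)
  cc2 <- cumulative_cost_profile(fake_profile(x, m), sp)
  expect_equal(cc2$cumulative[length(x)], 1)
  expect_true(all(diff(cc2$cumulative, differences = 2) < 1e-12))
  expect_gt(cc2$cumulative[which(x == 50)[1]], 0.5)
  expect_lt(approx(cc2$cumulative, x, 0.5)$y, 50)
  # somatic profiles carry no dendritic cost to attribute
  expect_error(cumulative_cost_profile(fake_profile(x, rep(0, 101)), sp),
               class = "dendrocost_config_error")
})
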