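# Shared fixtures: fast-to-solve species and geometries for unit tests.

fast_species <- function(...) {
  args <- utils::modifyList(list(
    name = "fast", D_m0 = 0.01, D_p = 0.1,
    halflife_m = 3600 * 5, halflife_p = 86400 * 4,
    tau = 0.01, eta_p = 500, u_p = 1e-3, nu_p = 2e-4,
    N_aa = 400, noncoding_ratio = 1,
    transport = transport_params(v = 1, beta = 0.5, theta = 0.05)),
    list(...))
  do.call(species_params, args)
}

small_geom <- function(L = 100, dx = 1, phi = 0.95) {
  dendrite_geometry(L = L, rho = 1, phi = phi, grid_dx = dx)
}

# Independent dense fixed-point solver for the shaft-protein equilibrium,
# used as a linear-algebra oracle against the package's Newton solver. Same
# continuum model, different numerics: base-R dense solves plus damped
# Picard iteration on the spine term, amplitude found by outer bisection on
# the distal filling condition.
dense_oracle_profile <- function(species, geom, r_soma) {
  x <- seq(0, geom$L, by = geom$grid_dx)
  n <- length(x)
  dx <- geom$grid_dx
  w <- c(dx / 2, rep(dx, n - 2), dx / 2)
  cap <- geom$rho * species$eta_p
  lam <- species$lambda_p
  nulam <- species$nu_p + lam
  D_m <- species_D_m_eff(species, geom)
  lm <- sqrt(D_m / species$lambda_m)
  cshape <- cosh((geom$L - x) / lm) / cosh(geom$L / lm)
  Ic <- sum(w * cshape)
  c_r <- r_soma / (1 - r_soma)
  p_target <- (geom$phi / (1 - geom$phi)) * nulam / species$u_p * cap

  K <- matrix(0, n, n)
  for (i in 2:(n - 1)) {
    K[i, i - 1] <- species$D_p / dx
    K[i, i + 1] <- species$D_p / dx
    K[i, i] <- -2 * species$D_p / dx - w[i] * lam
  }
  K[1, 1] <- -species$D_p / dx - w[1] * lam
  K[1, 2] <- species$D_p / dx
  K[n, n] <- -species$D_p / dx - w[n] * lam
  K[n, n - 1] <- species$D_p / dx

  solve_given_A <- function(A) {
    # Picard iteration: spine degradation lagged
    src <- species$tau * A * cshape
    J0 <- species$tau * c_r * A * Ic
    p <- rep(p_target, n)
    for (it in 1:400) {
      ps <- species$u_p * p * cap / (species$u_p * p + nulam * cap)
      rhs <- -(w * src) + lam * w * ps   # spine degradation is a sink
      rhs[1] <- rhs[1] - J0
      p_new <- solve(K, rhs)
      if (max(abs(p_new - p)) < 1e-12 * max(p)) {
        p <- p_new
        break
      }
      p <- 0.5 * p + 0.5 * p_new
    }
    p
  }
  f <- function(A) solve_given_A(A)[n] - p_target
  lo <- 1e-12
  hi <- 1
  while (f(hi) < 0) hi <- hi * 4
  A <- uniroot(f, c(lo, hi), tol = 1e-13)$root
  p <- solve_given_A(A)
  list(x = x, p = p, A = A,
       ps = species$u_p * p * cap / (species$u_p * p + nulam * cap))
}
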