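#' Steady-state fraction of molecules in motor-driven transit
#'
#' In the three-state run-and-pause model, resting molecules re-enter each of
#' the two moving states with rate `alpha` and runs terminate with rate
#' `beta`; at steady state the occupancy balance `beta * m_pm = alpha * m_0`
#' gives a transported fraction `2*alpha / (2*alpha + beta)`.
#'
#' @param alpha re-entry rate into each moving state (1/s), `>= 0`.
#' @param beta run termination rate (1/s), `> 0`.
#' @return the transported fraction in `[0, 1)`.
#' @export
transported_fraction <- function(alpha, beta) {
  if (alpha < 0) stop_config("alpha must be >= 0")
  if (beta <= 0) stop_config("beta must be > 0 (runs would never terminate)")
  2 * alpha / (2 * alpha + beta)
}

#' Steady state of the three-state transport model
#'
#' Solves the stationary run-and-pause system for a molecular species injected
#' at the soma: anterograde and retrograde populations move with speed `v`,
#' stop with rate `beta`, are re-populated from the resting state with rate
#' `alpha`, and the resting state diffuses with `D_m0` and decays with
#' `lambda_m`. Boundary conditions: moving molecules reflect (reverse
#' direction) at both ends, the diffusive flux vanishes at the tip, and a
#' point source at `x = 0` feeds the resting state. Because the system is
#' linear with constant coefficients the solution is computed in closed form
#' from the characteristic exponents.
#'
#' @param transport a [transport_params()] object.
#' @param lambda_m mRNA decay rate (1/s).
#' @param D_m0 diffusion constant of the resting state (um^2/s).
#' @param L domain length (um).
#' @param dx evaluation grid step (um).
#' @return an object of class `three_state_profile`: list with `x`, `m_plus`,
#'   `m_minus`, `m_zero`, `total` (unit-integral normalised).
#' @export
solve_three_state <- function(transport, lambda_m, D_m0, L, dx = 0.5) {
  if (lambda_m <= 0 || D_m0 <= 0 || L <= 0 || dx <= 0)
    stop_config("lambda_m, D_m0, L, dx must all be > 0")
  v <- transport$v; a <- transport$alpha; b <- transport$beta
  x <- seq(0, L, by = dx)
  if (abs(x[length(x)] - L) > 1e-9) x <- c(x, L)

  if (v == 0 || a == 0) {
    # moving states carry no flux: collapses to 1-state diffusion-decay
    l <- sqrt(D_m0 / lambda_m)
    m0 <- cosh_profile(x, L, l)
    ratio <- if (v == 0) a / b else 0
    mp <- ratio * m0; mm <- ratio * m0
  } else {
    lam <- lambda_m
    # characteristic exponents: D v^2 s^2 - [(2a+lam) v^2 + D b^2] s + lam b^2 = 0,
    # s = mu^2
    repeat {
      A2 <- D_m0 * v^2
      B2 <- -((2 * a + lam) * v^2 + D_m0 * b^2)
      C2 <- lam * b^2
      disc <- B2^2 - 4 * A2 * C2
      s <- c((-B2 - sqrt(disc)) / (2 * A2), (-B2 + sqrt(disc)) / (2 * A2))
      if (all(abs(b^2 - v^2 * s) > 1e-10 * b^2)) break
      lam <- lam * (1 + 1e-9)   # nudge off the resonant exponent
    }
    mu <- sqrt(s)
    # basis k = 1..4: exponents -mu1, +mu1, -mu2, +mu2 with overflow-safe
    # scalings exp(-mu x) and exp(-mu (L - x))
    mue <- c(-mu[1], mu[1], -mu[2], mu[2])
    f0 <- c(1, exp(-mu[1] * L), 1, exp(-mu[2] * L))       # basis at x = 0
    fL <- c(exp(-mu[1] * L), 1, exp(-mu[2] * L), 1)       # basis at x = L
    rp <- a / (b + v * mue)   # m_plus / m_zero per basis
    rm <- a / (b - v * mue)   # m_minus / m_zero per basis
    M <- rbind((rp - rm) * f0,          # reflection at soma
               (rp - rm) * fL,          # reflection at tip
               mue * fL,                # sealed diffusive flux at tip
               -D_m0 * mue * f0)        # unit point source at soma
    rhs <- c(0, 0, 0, 1)
    co <- tryCatch(solve(M, rhs), error = function(e)
      stop_numeric("three-state solve failed (singular basis): ",
                   conditionMessage(e)))
    basis <- function(x) cbind(exp(-mu[1] * x), exp(-mu[1] * (L - x)),
                               exp(-mu[2] * x), exp(-mu[2] * (L - x)))
    Bx <- basis(x)
    m0 <- as.vector(Bx %*% co)
    mp <- as.vector(Bx %*% (co * rp))
    mm <- as.vector(Bx %*% (co * rm))
    if (any(!is.finite(m0)))
      stop_numeric("three-state solution not finite; parameters: v=", v,
                   " alpha=", a, " beta=", b, " lambda=", lambda_m)
    # clip negligible negative undershoot from cancellation
    tol <- 1e-10 * max(abs(m0))
    if (min(m0, mp, mm) < -1e-6 * max(abs(m0)))
      stop_numeric("three-state solution substantially negative")
    m0 <- pmax(m0, 0); mp <- pmax(mp, 0); mm <- pmax(mm, 0)
  }
  tot <- m0 + mp + mm
  z <- trapz(x, tot)
  structure(list(x = x, m_plus = mp / z, m_minus = mm / z, m_zero = m0 / z,
                 total = tot / z),
            class = "three_state_profile")
}

#' Effective (ensemble) diffusion constant of transported mRNA
#'
#' Summarises mixed diffusive and motor-driven movement by the single
#' diffusion constant whose one-state diffusion-decay steady profile best
#' matches the total density of the three-state model. Two matching
#' strategies: `"profile"` minimises the squared deviation between the two
#' unit-normalised profiles; `"length"` matches the mean molecule position
#' (the spatial decay length).
#'
#' @inheritParams solve_three_state
#' @param strategy `"profile"` (default) or `"length"`.
#' @param dx evaluation grid step (um).
#' @return the fitted diffusion constant (um^2/s), with attributes
#'   `"residual"` (root-mean-square profile mismatch relative to the peak
#'   density) and `"theta"` (transported fraction).
#' @export
effective_diffusion <- function(transport, lambda_m, D_m0, L, dx = 0.5,
                                strategy = c("profile", "length")) {
  strategy <- match.arg(strategy)
  prof <- solve_three_state(transport, lambda_m, D_m0, L, dx = dx)
  x <- prof$x; target <- prof$total
  if (max(target) - min(target) < 1e-9 * max(target))
    stop_numeric("flat transport profile: effective diffusion unidentifiable")
  one_state <- function(D) {
    l <- sqrt(D / lambda_m)
    y <- cosh_profile(x, L, l)
    y / trapz(x, y)
  }
  lo <- D_m0 / 10
  hi <- 100 * (D_m0 + transport$v^2 * max(transport$theta, 1e-3) / transport$beta)
  D_hat <- if (strategy == "profile") {
    obj <- function(logD) sum((one_state(exp(logD)) - target)^2)
    exp(optimize(obj, c(log(lo), log(hi)), tol = 1e-8)$minimum)
  } else {
    xbar <- trapz(x, x * target)
    g <- function(D) trapz(x, x * one_state(D)) - xbar
    while (g(hi) < 0) hi <- hi * 10
    uniroot(g, c(lo, hi), tol = 1e-10)$root
  }
  res <- sqrt(mean((one_state(D_hat) - target)^2)) / max(target)
  structure(D_hat, residual = res, theta = transport$theta)
}

#' Stochastic particle simulation of run-and-pause transport
#'
#' Independent Monte-Carlo realisation of the three-state transport rules,
#' used as an oracle for [solve_three_state()]: particles diffuse in the
#' resting state, run ballistically in the moving states, reverse direction at
#' both domain ends, decay (resting state only) and are re-injected at the
#' soma, which realises the steady state of a point source at `x = 0`.
#'
#' @inheritParams solve_three_state
#' @param n_particles number of particles.
#' @param burn_in equilibration time (s) before sampling.
#' @param n_snapshots number of position snapshots collected.
#' @param snapshot_every interval between snapshots (s).
#' @param dt simulation time step (s).
#' @param seed RNG seed (randomness is local to this call).
#' @return list with `positions` (list of numeric vectors, one per snapshot)
#'   and the simulation settings.
#' @export
simulate_transport_particles <- function(transport, lambda_m, D_m0, L,
                                         n_particles = 5000, burn_in = 400,
                                         n_snapshots = 12,
                                         snapshot_every = 150, dt = 0.02,
                                         seed = 1) {
  v <- transport$v; alpha <- transport$alpha; beta <- transport$beta
  old <- .Random.seed_exists()
  on.exit(old(), add = TRUE)
  set.seed(seed)
  xs <- numeric(n_particles)            # all start at the soma
  st <- integer(n_particles)            # 0 rest, +1 antero, -1 retro
  p_decay <- 1 - exp(-lambda_m * dt)
  p_go <- 1 - exp(-2 * alpha * dt)      # rest -> either moving state
  p_stop <- 1 - exp(-beta * dt)
  sig_half <- sqrt(2 * D_m0 * dt / 2)
  t_total <- burn_in + n_snapshots * snapshot_every
  n_steps <- ceiling(t_total / dt)
  snap_steps <- round((burn_in + seq_len(n_snapshots) * snapshot_every) / dt)
  positions <- vector("list", n_snapshots)
  k <- 1L
  # Strang splitting: half movement step, reactions, half movement step --
  # particles that switch state mid-interval travel half the interval in
  # each state, removing the O(dt) switching bias of naive stepping.
  half_move <- function() {
    rest <- st == 0L
    nr <- sum(rest)
    if (nr) xs[rest] <<- xs[rest] + rnorm(nr, 0, sig_half)
    mov <- !rest
    if (any(mov)) xs[mov] <<- xs[mov] + v * (dt / 2) * st[mov]
    lo <- xs < 0
    if (any(lo)) { xs[lo] <<- -xs[lo]; st[lo] <<- -st[lo] }
    hi <- xs > L
    if (any(hi)) { xs[hi] <<- 2 * L - xs[hi]; st[hi] <<- -st[hi] }
  }
  for (step in seq_len(n_steps)) {
    half_move()
    r <- runif(n_particles)
    rest <- st == 0L
    # decay & re-injection (resting state only)
    dead <- rest & (r < p_decay)
    xs[dead] <- 0
    # state switching
    go <- rest & !dead & (r < p_decay + p_go)
    if (any(go)) st[go] <- sample(c(1L, -1L), sum(go), replace = TRUE)
    stopping <- !rest & (r < p_stop)
    st[stopping] <- 0L
    half_move()
    if (k <= n_snapshots && step == snap_steps[k]) {
      positions[[k]] <- xs
      k <- k + 1L
    }
  }
  list(positions = positions, n_particles = n_particles, dt = dt,
       burn_in = burn_in, snapshot_every = snapshot_every, L = L)
}

# Save/restore the global RNG state so that seeded helpers leave no trace.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
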