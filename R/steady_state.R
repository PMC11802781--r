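# Solver cache: steady profiles depend on the species only through a handful
# of shape parameters, so factorial populations re-use most solves.
.solver_cache <- new.env(parent = emptyenv())

#' Clear the internal steady-state solver cache
#' @return invisibly, the number of entries removed.
#' @export
clear_solver_cache <- function() {
  n <- length(ls(.solver_cache))
  rm(list = ls(.solver_cache), envir = .solver_cache)
  invisible(n)
}

#' Quasi-steady spine occupancy
#'
#' At equilibrium the spine balance (entry `u_p p (1 - p_spine/(rho eta_p))`,
#' exit `nu_p p_spine`, degradation `lambda_p p_spine`) gives
#' `p_spine = u_p p rho eta_p / (u_p p + (nu_p + lambda_p) rho eta_p)`,
#' which saturates below the capacity density `rho * eta_p`.
#'
#' @param p shaft protein density (per um), scalar or vector.
#' @param species a [species_params()] object.
#' @param geom a [dendrite_geometry()] object.
#' @return spine protein density (per um).
#' @export
spine_occupancy <- function(p, species, geom) {
  if (any(p < 0)) stop_config("shaft density must be >= 0")
  cap <- geom$rho * species$eta_p
  species$u_p * p * cap /
    (species$u_p * p + (species$nu_p + species$lambda_p) * cap)
}

# Normalised occupancy g(ptilde) = p_spine/(rho eta_p) given ptilde = p/(rho eta_p),
# and its derivative. Independent of eta_p and rho.
occ_norm <- function(pt, u, nulam) u * pt / (u * pt + nulam)
occ_norm_d <- function(pt, u, nulam) u * nulam / (u * pt + nulam)^2

# Analytic dendritic mRNA shape with m(0) = 1: solves
# 0 = D m'' - v_bias m' - lambda m, m'(L) = 0. Overflow-safe.
mrna_shape <- function(x, L, D, lambda, v_bias = 0) {
  if (v_bias == 0) return(cosh_profile(x, L, sqrt(D / lambda)))
  disc <- sqrt(v_bias^2 + 4 * D * lambda)
  mup <- (v_bias + disc) / (2 * D)   # > 0
  mum <- (v_bias - disc) / (2 * D)   # < 0
  # m = a exp(mup (x - L)) + b exp(mum x); m'(L) = 0, m(0) = 1
  ratio <- -(mum / mup) * exp(mum * L)       # a in terms of b
  b <- 1 / (1 + ratio * exp(-mup * L))
  a <- b * ratio
  a * exp(mup * (x - L)) + b * exp(mum * x)
}

# Effective mRNA diffusion constant for a species (memoised).
species_D_m_eff <- function(species, geom, dx = NULL) {
  tr <- species$transport
  if (tr$v == 0 || tr$alpha == 0) return(species$D_m0)
  key <- solve_key(tr$v, tr$alpha, tr$beta, species$D_m0, species$lambda_m,
                   geom$L)
  hit <- .solver_cache[[paste0("Dm|", key)]]
  if (!is.null(hit)) return(hit)
  dx <- dx %||% min(0.5, geom$L / 400)
  D <- as.numeric(effective_diffusion(tr, species$lambda_m, species$D_m0,
                                      geom$L, dx = dx))
  assign(paste0("Dm|", key), D, envir = .solver_cache)
  D
}

# Core Newton solve in normalised variables. Returns list(pt, z, node).
# Unknowns: pt (shaft density / (rho*eta_p)) on the grid, and z, the source
# scale (z = tau*A/(rho*eta_p) for the dendritic scenario, the normalised
# somatic influx for the somatic scenario). Constraint: pt at the limiting
# node equals the filling target.
solve_protein_core <- function(cshape, Ic, c_r, somatic, D_p, lambda_p,
                               u_p, nu_p, phi, x, tol = 1e-8, max_iter = 80) {
  n <- length(x)
  dx <- x[2] - x[1]
  w <- trapz_weights(x)
  nulam <- nu_p + lambda_p
  p_target <- (phi / (1 - phi)) * nulam / u_p   # normalised BC value
  # source pattern: volumetric (per node) and point influx at the soma
  if (somatic) {
    svol <- numeric(n); sflux <- 1
  } else {
    svol <- cshape; sflux <- c_r * Ic
  }
  # residual of the finite-volume system given (pt, z)
  resid <- function(pt, z) {
    flux <- D_p * diff(pt) / dx                    # at cell interfaces
    r <- numeric(n)
    r[1] <- flux[1] + z * sflux +
      w[1] * (z * svol[1] - lambda_p * (pt[1] + occ_norm(pt[1], u_p, nulam)))
    if (n > 2) {
      i <- 2:(n - 1)
      r[i] <- diff(flux) +
        w[i] * (z * svol[i] - lambda_p * (pt[i] + occ_norm(pt[i], u_p, nulam)))
    }
    r[n] <- -flux[n - 1] +
      w[n] * (z * svol[n] - lambda_p * (pt[n] + occ_norm(pt[n], u_p, nulam)))
    r
  }
  node <- n   # constraint node: distal tip unless the minimum sits elsewhere
  for (pass in 1:6) {
    pt <- rep(p_target, n)
    z <- lambda_p * (p_target + occ_norm(p_target, u_p, nulam)) *
      (x[n] - x[1]) / max(Ic * (!somatic) + 1 * somatic, 1e-12)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      r <- c(resid(pt, z), pt[node] - p_target)
      # relative to the largest reaction-term magnitude, which sets the
      # cancellation floor of the residual for steep profiles
      scale <- max(lambda_p * max(pt) * dx, 1e-300)
      if (max(abs(r[1:n])) / scale < tol && abs(r[n + 1]) < tol * p_target) {
        converged <- TRUE
        break
      }
      # Jacobian: tridiagonal in pt, one dense column (z), one constraint row
      dg <- occ_norm_d(pt, u_p, nulam)
      dmain <- -w * lambda_p * (1 + dg)
      dmain[1] <- dmain[1] - D_p / dx
      dmain[n] <- dmain[n] - D_p / dx
      if (n > 2) dmain[2:(n - 1)] <- dmain[2:(n - 1)] - 2 * D_p / dx
      doff <- rep(D_p / dx, n - 1)
      zcol <- w * svol
      zcol[1] <- zcol[1] + sflux
      J <- Matrix::sparseMatrix(
        i = c(1:n, 1:(n - 1), 2:n, 1:n, rep(n + 1L, 1L)),
        j = c(1:n, 2:n, 1:(n - 1), rep(n + 1L, n), node),
        x = c(dmain, doff, doff, zcol, 1),
        dims = c(n + 1L, n + 1L))
      step <- tryCatch(as.vector(Matrix::solve(J, -r)),
                       error = function(e) NULL)
      if (is.null(step))
        stop_numeric("steady-state Newton step failed (singular Jacobian)")
      lam_ls <- 1
      for (h in 1:30) {
        pt_new <- pt + lam_ls * step[1:n]
        z_new <- z + lam_ls * step[n + 1]
        if (all(pt_new > 0) && z_new > 0) {
          r_new <- c(resid(pt_new, z_new), pt_new[node] - p_target)
          if (sum(r_new^2) < sum(r^2) || lam_ls < 1e-3) break
        }
        lam_ls <- lam_ls / 2
      }
      pt <- pt_new; z <- z_new
    }
    if (!converged)
      stop_numeric("steady-state solver did not converge in ", max_iter,
                   " iterations (|r|/scale = ",
                   signif(max(abs(resid(pt, z))) / scale, 3), ")")
    jmin <- which.min(pt)
    if (pt[jmin] >= p_target * (1 - 1e-9)) break
    if (pass == 6)
      stop_numeric("spine filling constraint infeasible: occupancy dips ",
                   "below the target away from the constraint node")
    node <- jmin
  }
  list(pt = pt, z = z, node = node, p_target = p_target, iterations = it)
}

#' Steady-state mRNA/protein/spine profile for one species
#'
#' Solves the coupled equilibrium of the dendritic reaction-diffusion system
#' for a given localisation scenario. The dendritic mRNA profile follows the
#' closed-form diffusion-decay solution with the species' effective transport
#' diffusion constant; the shaft-protein equation (with the exact quasi-steady
#' spine term) is solved by Newton iteration on a finite-volume grid, with the
#' source amplitude as an additional unknown fixed by the requirement that
#' every spine reaches the filling ratio `phi` of its capacity (binding at the
#' spatial minimum of the occupancy, the distal tip for monotone profiles).
#'
#' Scenarios: `"somatic"` keeps all mRNA in the soma (no dendritic mRNA, no
#' transport); `"dendritic"` places a share `1 - r_soma` of transcripts in the
#' dendrite, with somatically translated protein entering at `x = 0` as a
#' diffusive flux.
#'
#' @param species a [species_params()] object.
#' @param geom a [dendrite_geometry()] object.
#' @param scenario `"somatic"` or `"dendritic"`.
#' @param r_soma somatic mRNA share in `(0, 1)`; required for the dendritic
#'   scenario.
#' @param D_m_eff optional pre-computed effective mRNA diffusion constant;
#'   computed from the species' transport parameters when `NULL`.
#' @param cache use the internal solver cache (default `TRUE`).
#' @return an object of class `spatial_profile`: list with grid `x`, densities
#'   `m`, `p`, `p_spine` (per um), somatic pools `m_soma`, `p_soma`, the share
#'   `r_soma`, the somatic protein influx `J0` (proteins/s), the effective
#'   mRNA diffusion constant `D_m_eff` and solver diagnostics.
#' @export
solve_steady <- function(species, geom, scenario = c("somatic", "dendritic"),
                         r_soma = NULL, D_m_eff = NULL, cache = TRUE) {
  scenario <- match.arg(scenario)
  somatic <- scenario == "somatic"
  if (!somatic) {
    if (is.null(r_soma) || r_soma <= 0 || r_soma >= 1)
      stop_config("dendritic scenario requires r_soma strictly in (0, 1)")
  }
  x <- seq(0, geom$L, by = geom$grid_dx)
  cap <- geom$rho * species$eta_p
  if (is.null(D_m_eff)) D_m_eff <- species_D_m_eff(species, geom)

  if (somatic) {
    cshape <- numeric(length(x)); Ic <- 0; c_r <- 0
  } else {
    cshape <- mrna_shape(x, geom$L, D_m_eff, species$lambda_m,
                         species$transport$v_bias)
    Ic <- trapz(x, cshape)
    c_r <- r_soma / (1 - r_soma)
  }

  key <- solve_key(as.numeric(somatic), if (somatic) 0 else r_soma,
                   D_m_eff, species$lambda_m, species$transport$v_bias,
                   species$D_p, species$lambda_p, species$u_p, species$nu_p,
                   geom$phi, geom$L, geom$grid_dx)
  core <- if (cache) .solver_cache[[paste0("ss|", key)]] else NULL
  if (is.null(core)) {
    core <- solve_protein_core(cshape, Ic, c_r, somatic,
                               species$D_p, species$lambda_p,
                               species$u_p, species$nu_p, geom$phi, x)
    if (cache) assign(paste0("ss|", key), core, envir = .solver_cache)
  }

  p <- core$pt * cap
  p_spine <- occ_norm(core$pt, species$u_p, species$nu_p + species$lambda_p) * cap
  if (somatic) {
    m <- numeric(length(x))
    J0 <- core$z * cap
    m_soma <- J0 / species$tau
    A <- 0
  } else {
    A <- core$z * cap / species$tau
    m <- A * cshape
    m_soma <- c_r * A * Ic
    J0 <- species$tau * m_soma
  }
  p_soma <- (species$tau * m_soma - J0) / species$lambda_p  # 0 by construction
  structure(
    list(x = x, m = m, p = p, p_spine = p_spine,
         m_soma = m_soma, p_soma = p_soma,
         r_soma = if (somatic) 1 else r_soma,
         scenario = scenario, species = species$name,
         J0 = J0, D_m_eff = D_m_eff,
         constraint_node = core$node, iterations = core$iterations,
         geom = geom),
    class = "spatial_profile")
}

#' @export
print.spatial_profile <- function(x, ...) {
  tc <- total_counts(x, x$geom)
  cat(sprintf("<spatial_profile> %s, %s scenario (r_soma = %.2f)\n",
              x$species, x$scenario, x$r_soma))
  cat(sprintf("  L = %g um; mRNA total %.4g (somatic %.4g), protein total %.4g\n",
              x$geom$L, tc$M_total, x$m_soma, tc$P_total))
  invisible(x)
}

#' Total molecule counts of a solved profile
#'
#' Integrates the mRNA and protein densities over the dendrite (trapezoidal
#' rule on the solver grid) and adds the somatic pools.
#'
#' @param profile a [solve_steady()] result.
#' @param geom the matching [dendrite_geometry()].
#' @return list with `M_total` (mRNA), `P_total` (protein incl. spines),
#'   `M_dend`, `P_shaft`, `P_spine`.
#' @export
total_counts <- function(profile, geom = profile$geom) {
  M_dend <- trapz(profile$x, profile$m)
  P_shaft <- trapz(profile$x, profile$p)
  P_spine <- trapz(profile$x, profile$p_spine)
  list(M_total = profile$m_soma + M_dend,
       P_total = profile$p_soma + P_shaft + P_spine,
       M_dend = M_dend, P_shaft = P_shaft, P_spine = P_spine)
}

#' Time derivative of the full dendritic system (method of lines)
#'
#' The right-hand side of the dynamical model on the solver grid, with
#' constant somatic influxes: mRNA enters at `x = 0` with rate `J_m0`
#' (molecules/s) and somatically synthesised protein with rate `J_p0`. Used to
#' verify that [solve_steady()] profiles are fixed points under independent
#' time integration.
#'
#' @param y state vector `c(m, p, p_spine)` stacked on the grid.
#' @param species a [species_params()] object.
#' @param geom a [dendrite_geometry()] object.
#' @param J_m0,J_p0 constant somatic influxes (molecules/s).
#' @param D_m_eff effective mRNA diffusion constant.
#' @return the stacked time derivative.
#' @export
model_rhs <- function(y, species, geom, J_m0, J_p0, D_m_eff) {
  x <- seq(0, geom$L, by = geom$grid_dx)
  n <- length(x)
  dx <- geom$grid_dx
  w <- trapz_weights(x)
  m <- y[1:n]; p <- y[(n + 1):(2 * n)]; ps <- y[(2 * n + 1):(3 * n)]
  cap <- geom$rho * species$eta_p
  lap <- function(u, D, influx) {
    flux <- D * diff(u) / dx
    d <- numeric(n)
    d[1] <- (flux[1] + influx) / w[1]
    if (n > 2) d[2:(n - 1)] <- diff(flux) / w[2:(n - 1)]
    d[n] <- -flux[n - 1] / w[n]
    d
  }
  entry <- species$u_p * p * pmax(1 - ps / cap, 0)
  dm <- lap(m, D_m_eff, J_m0) - species$lambda_m * m
  dp <- species$tau * m + lap(p, species$D_p, J_p0) -
    entry + species$nu_p * ps - species$lambda_p * p
  dps <- entry - species$nu_p * ps - species$lambda_p * ps
  c(dm, dp, dps)
}
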