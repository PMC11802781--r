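#' Photoactivation pulse-chase simulation of somatic protein spread
#'
#' Rides a labelled protein subpopulation on top of a solved steady state:
#' from `t = 0`, the somatic source emits only labelled protein while the
#' total pool (labelled + unlabelled) stays at equilibrium, mimicking
#' continuous somatic photoactivation. The labelled shaft and spine fields
#' follow the same diffusion / spine-exchange / degradation operators as the
#' steady-state model with the spine entry factor frozen at the equilibrium
#' occupancy, which makes the labelled dynamics linear; time stepping is
#' implicit Euler (unconditionally stable) with a single sparse factorisation.
#'
#' @param species a [species_params()] object (e.g. [shank3_preset()]).
#' @param geom a [dendrite_geometry()] object.
#' @param spine_positions distances from the soma (um) of the spines of
#'   interest.
#' @param t_end simulated time (s).
#' @param dt time step (s).
#' @param scenario localisation scenario of the underlying steady state
#'   (default `"somatic"`: all mRNA in the soma).
#' @param r_soma somatic share for a dendritic steady state.
#' @param save_every store every k-th step (1 = all).
#' @return an object of class `labeling_series`: `times` (s), `positions`
#'   (um), `labelled` (time x spine matrix of labelled spine occupancy, per
#'   um), `asymptote` (equilibrium spine occupancy at the positions, the
#'   analytic fixed point of the labelling dynamics), `shaft` (labelled shaft
#'   density at the positions) and the steady profile.
#' @export
simulate_labeling <- function(species, geom, spine_positions = c(25, 50, 75, 105),
                              t_end = 8 * 3600, dt = 10,
                              scenario = c("somatic", "dendritic"),
                              r_soma = NULL, save_every = 1) {
  scenario <- match.arg(scenario)
  if (dt <= 0 || t_end <= dt) stop_config("need 0 < dt < t_end")
  if (any(spine_positions < 0 | spine_positions > geom$L))
    stop_config("spine positions must lie inside [0, L]")
  steady <- solve_steady(species, geom, scenario, r_soma = r_soma)
  x <- steady$x
  n <- length(x)
  dx <- geom$grid_dx
  w <- trapz_weights(x)
  cap <- geom$rho * species$eta_p
  entry <- species$u_p * (1 - steady$p_spine / cap)  # frozen entry rate field
  exit <- species$nu_p + species$lambda_p

  # generator A of d/dt (p*, ps*) = A y + b, finite-volume identical to the
  # steady-state solver
  ip <- 1:n; is <- n + (1:n)
  di <- species$D_p / dx / w
  diag_p <- -c(di[1], 2 * di[2:(n - 1)], di[n]) - entry - species$lambda_p
  A <- Matrix::sparseMatrix(
    i = c(ip[-n], ip[-1], ip, ip, is, is),
    j = c(ip[-1], ip[-n], ip, is, ip, is),
    x = c(di[-n], di[-1], diag_p, rep(species$nu_p, n), entry,
          rep(-exit, n)),
    dims = c(2 * n, 2 * n))
  # Continuous photoactivation: the somatic pool is fully labelled from t = 0
  # and exchanges diffusively with the shaft, so the labelled shaft
  # concentration at x = 0 is pinned to the steady value (Dirichlet), and
  # unlabelled protein diffusing back into the soma joins the labelled pool.
  # Implemented as a fast relaxation row, keeping -A nonsingular so the
  # labelling asymptote is the system's algebraic fixed point. Dendritic
  # synthesis (tau * m) stays unlabelled: newly made protein carries no label
  # until it visits the soma.
  A[1, ] <- 0
  A[1, 1] <- -1
  b <- numeric(2 * n)
  b[1] <- steady$p[1]
  M <- Matrix::Diagonal(2 * n) - dt * A
  fac <- Matrix::lu(M)
  y_inf <- as.vector(Matrix::solve(A, -b))   # labelling fixed point

  n_steps <- floor(t_end / dt)
  keep <- seq(0, n_steps, by = save_every)
  idx <- vapply(spine_positions, function(s) which.min(abs(x - s)), 1L)
  times <- keep * dt
  lab_sp <- matrix(0, length(keep), length(idx))
  lab_sh <- matrix(0, length(keep), length(idx))
  y <- numeric(2 * n)
  k <- 2L   # the t = 0 row stays all zero
  for (step in seq_len(n_steps)) {
    y <- as.vector(Matrix::solve(fac, y + dt * b))
    if (k <= length(keep) && step == keep[k]) {
      lab_sh[k, ] <- y[idx]
      lab_sp[k, ] <- y[n + idx]
      k <- k + 1L
    }
  }
  structure(
    list(times = times, positions = spine_positions,
         labelled = lab_sp, shaft = lab_sh,
         asymptote = y_inf[n + idx],
         asymptote_shaft = y_inf[idx],
         asymptote_full = y_inf,
         steady = steady, dt = dt),
    class = "labeling_series")
}

#' @export
print.labeling_series <- function(x, ...) {
  cat(sprintf("<labeling_series> %d steps of %g s, spines at %s um\n",
              length(x$times) - 1, x$dt,
              paste(x$positions, collapse = ", ")))
  frac <- x$labelled[nrow(x$labelled), ] / x$asymptote
  cat(sprintf("  labelled/steady at t_end: %s\n",
              paste(sprintf("%.2f", frac), collapse = ", ")))
  invisible(x)
}

#' Normalise labelling traces to the proximal-most spine
#'
#' @param series a [simulate_labeling()] result.
#' @param mode `"matched"` divides each trace by the proximal trace at the
#'   same time point; `"terminal"` divides by the proximal trace's final
#'   value. `0/0` (at `t = 0`) is defined as 0.
#' @return the series with a `normalised` matrix added.
#' @export
normalise_to_proximal <- function(series, mode = c("matched", "terminal")) {
  mode <- match.arg(mode)
  prox <- which.min(series$positions)
  ref <- if (mode == "matched") series$labelled[, prox]
         else rep(series$labelled[nrow(series$labelled), prox],
                  nrow(series$labelled))
  norm <- series$labelled / ref
  norm[!is.finite(norm)] <- 0
  series$normalised <- norm
  series$normalise_mode <- mode
  series
}

#' Time for a monotone saturating trace to reach a level of its asymptote
#'
#' @param times time points (s).
#' @param trace the trace values, rising toward `asymptote`.
#' @param asymptote the limiting value (for labelling traces: the equilibrium
#'   spine occupancy, i.e. the analytic fixed point, not the last sample).
#' @param level fraction of the asymptote defining saturation (default 0.95).
#' @return the first time the trace reaches `level * asymptote`, linearly
#'   interpolated between samples; `NA` (with a `"status"` attribute
#'   `"not-reached"`) if the level is not reached by the end.
#' @export
saturation_time <- function(times, trace, asymptote, level = 0.95) {
  if (asymptote <= 0) stop_config("asymptote must be > 0")
  target <- level * asymptote
  hit <- which(trace >= target)
  if (!length(hit))
    return(structure(NA_real_, status = "not-reached"))
  i <- hit[1]
  if (i == 1) return(times[1])
  t0 <- times[i - 1]; t1 <- times[i]
  y0 <- trace[i - 1]; y1 <- trace[i]
  t0 + (target - y0) / (y1 - y0) * (t1 - t0)
}

#' Saturation times of every spine in a labelling series
#'
#' @param series a [simulate_labeling()] result.
#' @param level see [saturation_time()].
#' @return named numeric vector (s), `NA` where not reached.
#' @export
spine_saturation_times <- function(series, level = 0.95) {
  out <- vapply(seq_along(series$positions), function(j)
    as.numeric(saturation_time(series$times, series$labelled[, j],
                               series$asymptote[j], level)), numeric(1))
  names(out) <- paste0(series$positions, "um")
  out
}
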