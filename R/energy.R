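# ATP cost constants: chain elongation + posttranscriptional modification per
# nucleotide; synthesis + degradation per amino acid; motor transport per
# cargo at the reference speed.
COST_PER_NT <- 2.17
COST_PER_AA <- 5
COST_PER_CARGO <- 125
V_REF_CARGO <- 1

#' Transcription cost of a steady-state profile
#'
#' ATP spent per second to replace degraded transcripts:
#' `C_nt * N_nt * lambda_m * (m_soma + integral of m)`.
#'
#' @param profile a [solve_steady()] result.
#' @param species the matching [species_params()].
#' @param C_nt ATP per transcribed nucleotide.
#' @return ATP/s.
#' @export
transcription_cost <- function(profile, species, C_nt = COST_PER_NT) {
  M_total <- profile$m_soma + trapz(profile$x, profile$m)
  C_nt * species$N_nt * species$lambda_m * M_total
}

#' Translation cost of a steady-state profile
#'
#' ATP spent per second on protein synthesis and degradation (folded into one
#' per-amino-acid constant): `C_aa * N_aa * tau * (m_soma + integral of m)`.
#'
#' @inheritParams transcription_cost
#' @param C_aa ATP per amino acid (synthesis + degradation).
#' @return ATP/s.
#' @export
translation_cost <- function(profile, species, C_aa = COST_PER_AA) {
  M_total <- profile$m_soma + trapz(profile$x, profile$m)
  C_aa * species$N_aa * species$tau * M_total
}

#' Active transport cost of a steady-state profile
#'
#' ATP spent per second to keep the transported share of dendritic mRNA
#' granules moving: `C_cargo * theta_m * (integral of m / mrnas_per_granule)`,
#' scaled linearly with the run velocity relative to the reference speed.
#'
#' @inheritParams transcription_cost
#' @param C_cargo ATP/s to move one cargo at the reference speed.
#' @param v_ref reference cargo speed (um/s).
#' @return ATP/s.
#' @export
transport_cost <- function(profile, species, C_cargo = COST_PER_CARGO,
                           v_ref = V_REF_CARGO) {
  M_dend <- trapz(profile$x, profile$m)
  if (M_dend == 0) return(0)
  C_cargo * species$transport$theta * (M_dend / species$mrnas_per_granule) *
    (species$transport$v / v_ref)
}

#' ATP budget of a solved scenario
#'
#' @inheritParams transcription_cost
#' @return an object of class `energy_budget` with components `transcription`,
#'   `translation`, `transport`, `total` (ATP/s), plus `scenario` and
#'   `r_soma`.
#' @export
energy_budget <- function(profile, species) {
  tc <- transcription_cost(profile, species)
  tl <- translation_cost(profile, species)
  tp <- transport_cost(profile, species)
  structure(list(transcription = tc, translation = tl, transport = tp,
                 total = tc + tl + tp, scenario = profile$scenario,
                 r_soma = profile$r_soma, species = species$name),
            class = "energy_budget")
}

#' @export
print.energy_budget <- function(x, ...) {
  cat(sprintf("<energy_budget> %s, %s (r_soma = %.2f)\n", x$species,
              x$scenario, x$r_soma))
  cat(sprintf("  transcription %.4g + translation %.4g + transport %.4g = %.4g ATP/s\n",
              x$transcription, x$translation, x$transport, x$total))
  invisible(x)
}

#' Energy-optimal mRNA localisation decision for one species
#'
#' Solves the somatic scenario and the dendritic scenario across a grid of
#' somatic mRNA shares, takes the cost-minimising dendritic configuration, and
#' prefers whichever strategy has the lower total ATP/s (ties broken toward
#' somatic, which needs no transport machinery).
#'
#' @param species a [species_params()] object.
#' @param geom a [dendrite_geometry()] object.
#' @param r_soma_grid candidate somatic mRNA shares for the dendritic
#'   scenario.
#' @param cache use the internal solver cache.
#' @return an object of class `localisation_decision`: species name, both
#'   budgets, the optimal `r_soma`, `preferred` (`"somatic"`/`"dendritic"`),
#'   `cost_ratio` (somatic/dendritic total) and the molecule counts of both
#'   scenarios.
#' @export
decide <- function(species, geom, r_soma_grid = seq(0.1, 0.9, by = 0.1),
                   cache = TRUE) {
  if (!length(r_soma_grid) || any(r_soma_grid <= 0 | r_soma_grid >= 1))
    stop_config("r_soma_grid values must lie strictly in (0, 1)")
  prof_som <- tryCatch(
    solve_steady(species, geom, "somatic", cache = cache),
    error = function(e) stop_numeric("species '", species$name,
                                     "', somatic scenario: ",
                                     conditionMessage(e)))
  bud_som <- energy_budget(prof_som, species)
  D_m_eff <- species_D_m_eff(species, geom)
  best <- NULL
  for (r in r_soma_grid) {
    prof <- tryCatch(
      solve_steady(species, geom, "dendritic", r_soma = r,
                   D_m_eff = D_m_eff, cache = cache),
      error = function(e) stop_numeric("species '", species$name,
                                       "', dendritic scenario (r_soma = ", r,
                                       "): ", conditionMessage(e)))
    bud <- energy_budget(prof, species)
    if (is.null(best) || bud$total < best$budget$total)
      best <- list(budget = bud, profile = prof)
  }
  preferred <- if (best$budget$total < bud_som$total) "dendritic" else "somatic"
  structure(
    list(species = species$name,
         budget_somatic = bud_som, budget_dendritic = best$budget,
         r_soma_opt = best$budget$r_soma, preferred = preferred,
         cost_ratio = bud_som$total / best$budget$total,
         counts_somatic = total_counts(prof_som, geom),
         counts_dendritic = total_counts(best$profile, geom),
         labels = species$labels, L = geom$L),
    class = "localisation_decision")
}

#' @export
print.localisation_decision <- function(x, ...) {
  cat(sprintf("<localisation_decision> %s (L = %g um)\n", x$species, x$L))
  cat(sprintf("  somatic %.4g ATP/s vs dendritic %.4g ATP/s (r_soma = %.2f)\n",
              x$budget_somatic$total, x$budget_dendritic$total, x$r_soma_opt))
  cat(sprintf("  preferred: %s (cost ratio somatic/dendritic = %.3f)\n",
              x$preferred, x$cost_ratio))
  invisible(x)
}

#' Cumulative dendritic cost density along the dendrite
#'
#' Attributes the spatially resolved dendritic expenditures (local translation
#' proportional to `C_aa N_aa tau m(x)`, transport proportional to
#' `C_cargo theta m(x)/granule`) to position and returns the normalised
#' cumulative curve, which rises from 0 at the soma to 1 at the tip.
#'
#' @inheritParams transcription_cost
#' @param C_aa,C_cargo,v_ref cost constants, see [translation_cost()] and
#'   [transport_cost()].
#' @return data.frame with columns `x` and `cumulative`.
#' @export
cumulative_cost_profile <- function(profile, species, C_aa = COST_PER_AA,
                                    C_cargo = COST_PER_CARGO,
                                    v_ref = V_REF_CARGO) {
  if (all(profile$m == 0))
    stop_config("cumulative cost profile requires a dendritic scenario")
  dens <- C_aa * species$N_aa * species$tau * profile$m +
    C_cargo * species$transport$theta * (species$transport$v / v_ref) *
    profile$m / species$mrnas_per_granule
  x <- profile$x
  cum <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(x)))
  data.frame(x = x, cumulative = cum / cum[length(cum)])
}
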