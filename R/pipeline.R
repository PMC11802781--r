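# Minimal polynomial rolling hash for provenance stamps (config fingerprints,
# not cryptography; avoids an external digest dependency).
fnv1a <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance <- function(config, seed) {
  list(package = "dendrocost",
       version = as.character(utils::packageVersion("dendrocost")),
       seed = seed,
       config_hash = fnv1a(paste(deparse(config), collapse = "")))
}

write_csv_prov <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s %s seed=%s config=%s", prov$package, prov$version,
                     prov$seed, prov$config_hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

default_run_config <- function(overrides = list()) {
  def <- read_config("defaults.yaml")
  cfg <- list(
    geometry = def$geometry,
    r_soma_grid = as.numeric(def$scenario$r_soma_grid),
    lengths = c(250, 500, 750, 1000),
    stats = list(n_boot = 1000, alpha = 0.05),
    seed = 1)
  utils::modifyList(cfg, overrides)
}

geom_from_config <- function(cfg, L = NULL) {
  g <- cfg$geometry
  dendrite_geometry(L = L %||% g$L, rho = g$rho, phi = g$phi,
                    grid_dx = g$grid_dx)
}

#' Solve steady states and energy budgets for a species table
#'
#' Batch front end: reads a species table (path or list), solves both
#' localisation scenarios per species, writes per-species profile CSVs and a
#' budget/decision JSON, and reports failures per species without aborting
#' the batch.
#'
#' @param species a species table path (see [read_species_table()]) or a list
#'   of [species_params()].
#' @param out_dir output directory (created if missing).
#' @param config list of overrides of the bundled defaults (see
#'   `inst/extdata/defaults.yaml`); honoured keys: `geometry`,
#'   `r_soma_grid`, `seed`.
#' @return invisibly, a list with `decisions` and `failures` (named character
#'   vector of error messages).
#' @export
run_solve <- function(species, out_dir, config = list()) {
  cfg <- default_run_config(config)
  if (is.character(species)) species <- read_species_table(species)
  if (!length(species)) stop_config("empty species table")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenance(cfg, cfg$seed)
  geom <- geom_from_config(cfg)
  decisions <- list(); failures <- character()
  for (sp in species) {
    res <- tryCatch(decide(sp, geom, cfg$r_soma_grid), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[sp$name]] <- conditionMessage(res)
      message("species '", sp$name, "' failed: ", conditionMessage(res))
      next
    }
    decisions[[sp$name]] <- res
    prof <- solve_steady(sp, geom,
                         if (res$preferred == "dendritic") "dendritic" else "somatic",
                         r_soma = if (res$preferred == "dendritic")
                           res$r_soma_opt else NULL)
    write_csv_prov(data.frame(x = prof$x, m = prof$m, p = prof$p,
                              p_spine = prof$p_spine),
                   file.path(out_dir, paste0("profile_", sp$name, ".csv")),
                   prov)
  }
  budgets <- lapply(decisions, function(d) list(
    species = d$species, preferred = d$preferred,
    r_soma_opt = d$r_soma_opt, cost_ratio = d$cost_ratio,
    somatic = unclass(d$budget_somatic)[c("transcription", "translation",
                                          "transport", "total")],
    dendritic = unclass(d$budget_dendritic)[c("transcription", "translation",
                                              "transport", "total")]))
  jsonlite::write_json(list(provenance = prov, budgets = budgets),
                       file.path(out_dir, "budgets.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(failures))
    warning(length(failures), " species failed; see budgets.json siblings")
  invisible(list(decisions = decisions, failures = failures))
}

#' Run the full synthetic-grid population analysis
#'
#' Generates the factorial species grid, computes localisation decisions for
#' every dendrite length in the config, and writes the decision table,
#' per-dimension preference panels and rank-abundance summaries.
#'
#' @param out_dir output directory.
#' @param config overrides; honoured keys: `lengths`, `geometry`,
#'   `r_soma_grid`, `levels` (passed to [grid_sample()]), `seed`.
#' @param progress report solver progress.
#' @return invisibly, a named list of [population_decisions()] per length.
#' @export
run_grid <- function(out_dir, config = list(), progress = FALSE) {
  cfg <- default_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenance(cfg, cfg$seed)
  grid <- grid_sample(levels = cfg$levels)
  out <- list()
  summary <- list(provenance = prov, grid_size = length(grid))
  for (L in cfg$lengths) {
    geom <- geom_from_config(cfg, L = L)
    dec <- population_decisions(grid, geom, cfg$r_soma_grid,
                                progress = progress)
    out[[as.character(L)]] <- dec
    write_csv_prov(as.data.frame(dec),
                   file.path(out_dir, sprintf("decisions_L%d.csv", L)), prov)
    panels <- do.call(rbind, lapply(names(attr(grid, "grid_labels")),
                                    function(dim) {
      p <- preference_panel(dec, dim)
      cbind(dimension = dim, as.data.frame(p))
    }))
    write_csv_prov(panels,
                   file.path(out_dir, sprintf("preference_panels_L%d.csv", L)),
                   prov)
    ra_m <- rank_abundance(dec$M_total)
    ra_p <- rank_abundance(dec$P_total)
    write_csv_prov(data.frame(rank = ra_m$rank, mrna = ra_m$count,
                              protein = ra_p$count),
                   file.path(out_dir, sprintf("rank_abundance_L%d.csv", L)),
                   prov)
    summary[[sprintf("L%d", L)]] <- list(
      dendritic_fraction = preference_fraction(dec),
      mrna_median = ra_m$median, protein_median = ra_p$median,
      mrna_rank_r2 = ra_m$r_squared_exponential,
      protein_rank_r2 = ra_p$r_squared_exponential)
  }
  jsonlite::write_json(summary, file.path(out_dir, "grid_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Run the enrichment-screen comparison pipeline
#'
#' Either analyses a provided screen table (path or data.frame) or generates
#' a synthetic screen, then writes the panel statistics report as JSON.
#'
#' @param out_dir output directory.
#' @param screen path or data.frame; `NULL` for synthetic mode.
#' @param synthetic list of [synthetic_screen()] arguments for synthetic
#'   mode.
#' @param column_map for external tables, see [read_screen_table()].
#' @param config overrides; honoured keys: `stats` (`n_boot`), `seed`,
#'   `threshold_fold`.
#' @return invisibly, the [screen_report()] list.
#' @export
run_screens <- function(out_dir, screen = NULL, synthetic = list(),
                        column_map = NULL, config = list()) {
  cfg <- default_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(screen)) {
    screen <- do.call(synthetic_screen,
                      utils::modifyList(list(seed = cfg$seed), synthetic))
  } else if (is.character(screen)) {
    screen <- read_screen_table(screen, column_map)
  }
  rep <- screen_report(screen, threshold_fold = cfg$threshold_fold %||% 2,
                       n_boot = cfg$stats$n_boot, seed = cfg$seed)
  jsonlite::write_json(list(provenance = provenance(cfg, cfg$seed),
                            report = rep),
                       file.path(out_dir, "screen_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}

#' Run the photoactivation simulation and export spine traces
#'
#' @param out_dir output directory.
#' @param species a [species_params()]; default [shank3_preset()].
#' @param config overrides; honoured keys: `geometry`, `spine_positions`,
#'   `t_end`, `dt`, `seed`.
#' @return invisibly, the [simulate_labeling()] series.
#' @export
run_photoactivation <- function(out_dir, species = shank3_preset(),
                                config = list()) {
  cfg <- default_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- geom_from_config(cfg)
  series <- simulate_labeling(
    species, geom,
    spine_positions = cfg$spine_positions %||% c(25, 50, 75, 105),
    t_end = cfg$t_end %||% 8 * 3600, dt = cfg$dt %||% 10)
  series <- normalise_to_proximal(series)
  long <- do.call(rbind, lapply(seq_along(series$positions), function(j)
    data.frame(time_s = series$times, position_um = series$positions[j],
               labelled = series$labelled[, j],
               normalised = series$normalised[, j])))
  write_csv_prov(long, file.path(out_dir, "photoactivation_traces.csv"),
                 provenance(cfg, cfg$seed))
  invisible(series)
}
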