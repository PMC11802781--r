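#' Localisation decisions for a species population
#'
#' Runs [decide()] for every species in a list (typically a [grid_sample()]
#' output). Solves are memoised internally, so factorial populations that
#' share profile-shape parameters are far cheaper than the species count
#' suggests.
#'
#' @param species_list list of [species_params()].
#' @param geom a [dendrite_geometry()] object.
#' @param r_soma_grid candidate somatic shares, see [decide()].
#' @param progress print a progress line every 500 species.
#' @return a `population_decisions` object: a data.frame with one row per
#'   species (costs, preferred strategy, counts, group labels) and the list of
#'   `localisation_decision` objects as an attribute.
#' @export
population_decisions <- function(species_list, geom,
                                 r_soma_grid = seq(0.1, 0.9, by = 0.1),
                                 progress = FALSE) {
  if (!length(species_list)) stop_config("empty species population")
  decisions <- vector("list", length(species_list))
  for (i in seq_along(species_list)) {
    decisions[[i]] <- decide(species_list[[i]], geom, r_soma_grid)
    if (progress && i %% 500 == 0)
      message(sprintf("  solved %d / %d species", i, length(species_list)))
  }
  df <- do.call(rbind, lapply(decisions, function(d) {
    counts <- if (d$preferred == "dendritic") d$counts_dendritic else
      d$counts_somatic
    row <- data.frame(
      species = d$species, preferred = d$preferred,
      cost_somatic = d$budget_somatic$total,
      cost_dendritic = d$budget_dendritic$total,
      cost_ratio = d$cost_ratio, r_soma_opt = d$r_soma_opt,
      txn_txl_somatic = d$budget_somatic$transcription +
        d$budget_somatic$translation,
      txn_txl_dendritic = d$budget_dendritic$transcription +
        d$budget_dendritic$translation,
      cost_preferred = min(d$budget_somatic$total, d$budget_dendritic$total),
      M_total = counts$M_total, P_total = counts$P_total,
      stringsAsFactors = FALSE)
    if (!is.null(d$labels))
      row <- cbind(row, as.data.frame(as.list(d$labels),
                                      stringsAsFactors = FALSE))
    row
  }))
  structure(df, decisions = decisions, L = geom$L,
            class = c("population_decisions", "data.frame"))
}

#' Fraction of a population preferring dendritic mRNA
#'
#' @param decisions a [population_decisions()] result (or any data.frame with
#'   a `preferred` column).
#' @return fraction in `[0, 1]`.
#' @export
preference_fraction <- function(decisions) {
  if (!nrow(decisions)) stop_config("empty decision population")
  mean(decisions$preferred == "dendritic")
}

#' Preference ratios along one parameter dimension
#'
#' Groups the population by the low/medium/high level of one grid dimension,
#' takes the group median of the per-species cost ratio (somatic total /
#' dendritic total) and normalises by the medium group, so the medium bar is
#' exactly 1 and values above 1 indicate a stronger dendritic preference.
#'
#' @param decisions a [population_decisions()] result carrying group labels.
#' @param dimension label column name (e.g. `"mrna_halflife"`).
#' @return a `preference_panel` object: data.frame with `group`, `median_ratio`,
#'   `normalised`, `n`.
#' @export
preference_panel <- function(decisions, dimension) {
  if (!dimension %in% names(decisions))
    stop_config("no group labels for dimension '", dimension, "'")
  groups <- c("low", "medium", "high")
  if (!all(groups %in% decisions[[dimension]]))
    stop_config("dimension '", dimension, "' misses a low/medium/high group")
  med <- vapply(groups, function(g)
    median(decisions$cost_ratio[decisions[[dimension]] == g]), numeric(1))
  n <- vapply(groups, function(g) sum(decisions[[dimension]] == g), integer(1))
  structure(
    data.frame(group = groups, median_ratio = med,
               normalised = med / med["medium"], n = n,
               row.names = NULL, stringsAsFactors = FALSE),
    dimension = dimension, class = c("preference_panel", "data.frame"))
}

#' Rank-abundance curve of predicted copy numbers
#'
#' Rank-sorts per-species total counts (each species under its energetically
#' preferred localisation strategy) in decreasing order and summarises the
#' distribution, including the goodness of an exponential fit (R-squared of
#' log-count against rank).
#'
#' @param counts numeric vector of per-species total copy numbers (> 0 for
#'   the exponential fit).
#' @return list with `rank`, `count` (sorted non-increasing), `median`,
#'   `quartiles`, and `r_squared_exponential`.
#' @export
rank_abundance <- function(counts) {
  counts <- sort(counts, decreasing = TRUE)
  rank <- seq_along(counts)
  r2 <- NA_real_
  if (length(counts) > 2 && all(counts > 0)) {
    fit <- lm(log(counts) ~ rank)
    r2 <- summary(fit)$r.squared
  }
  list(rank = rank, count = counts, median = median(counts),
       quartiles = quantile(counts, c(0.25, 0.75), names = FALSE),
       r_squared_exponential = r2)
}

#' Abundance comparison between localisation strategy groups
#'
#' Splits per-species counts by energetically preferred strategy and compares
#' the two distributions with the two-sided Wilcoxon rank-sum test
#' ([ranksum_test()]).
#'
#' @param decisions a [population_decisions()] result.
#' @param counts numeric vector aligned with `decisions` rows (e.g.
#'   `decisions$M_total`).
#' @return list with per-group `n`, `median`, the rank-sum `p_value`, and
#'   `status` (`"ok"` or `"group-empty"`).
#' @export
strategy_split_abundance <- function(decisions, counts) {
  stopifnot(length(counts) == nrow(decisions))
  den <- counts[decisions$preferred == "dendritic"]
  som <- counts[decisions$preferred == "somatic"]
  if (!length(den) || !length(som))
    return(list(n = c(somatic = length(som), dendritic = length(den)),
                median = c(somatic = median(som), dendritic = median(den)),
                p_value = NA_real_, status = "group-empty"))
  list(n = c(somatic = length(som), dendritic = length(den)),
       median = c(somatic = median(som), dendritic = median(den)),
       p_value = ranksum_test(som, den), status = "ok")
}

#' Population energy demand excluding the most cost-intense species
#'
#' Drops species above the given total-cost percentile and scales the mean
#' per-species demand of the remainder to a nominal population size.
#'
#' @param decisions a [population_decisions()] result.
#' @param keep_quantile cost percentile defining the retained group
#'   (default 0.95: drop the most cost-intense 5%).
#' @param n_species nominal population size (default 10000).
#' @return list with `mean_per_species` (ATP/s), `total` (ATP/s for
#'   `n_species`), `cutoff` and `n_kept`.
#' @export
population_energy_demand <- function(decisions, keep_quantile = 0.95,
                                     n_species = 10000) {
  cost <- decisions$cost_preferred
  cutoff <- quantile(cost, keep_quantile, names = FALSE)
  kept <- cost[cost <= cutoff]
  list(mean_per_species = mean(kept), total = mean(kept) * n_species,
       cutoff = cutoff, n_kept = length(kept))
}
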