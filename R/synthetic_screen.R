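#' Synthetic soma/neurite enrichment screen
#'
#' Generates a reproducible stand-in for compartment-resolved sequencing and
#' proteomics screens: two latent gene groups (soma-destined and
#' neurite-destined transcripts) whose molecular properties differ by
#' configurable multiplicative effect sizes, with lognormal biological
#' scatter, and lognormal enrichment scores centred on each group's fold
#' level. Default effect directions follow the energy model's predictions:
#' the neurite group has longer-lived mRNAs, longer transcripts,
#' shorter-lived proteins, longer proteins, equal spine copy numbers and
#' higher abundances.
#'
#' @param n_soma,n_neurite genes per latent group (>= 1).
#' @param effects named list of relative differences of the neurite group's
#'   median vs. the soma group (0 = no difference; 0.5 = 50% larger). Names:
#'   `mrna_halflife_h`, `transcript_nt`, `protein_halflife_d`, `protein_aa`,
#'   `spine_copies`, `mrna_abundance`, `protein_abundance`.
#' @param base named list of soma-group medians (units: hours, nucleotides,
#'   days, amino acids, copies, molecule counts).
#' @param noise_sdlog lognormal scatter (sd of log) of every property.
#' @param enrichment_folds latent median enrichment per group
#'   (c(soma, neurite)); soma below 1, neurite above.
#' @param enrichment_sdlog lognormal scatter of enrichment scores.
#' @param seed RNG seed; the table is byte-identical across calls with the
#'   same arguments and seed.
#' @return data.frame with columns `gene`, `group`, `enrichment`,
#'   `mrna_halflife_h`, `transcript_nt`, `protein_halflife_d`, `protein_aa`,
#'   `spine_copies`, `mrna_abundance`, `protein_abundance`.
#' @export
synthetic_screen <- function(n_soma = 200, n_neurite = 200,
                             effects = list(),
                             base = list(),
                             noise_sdlog = 0.6,
                             enrichment_folds = c(soma = 0.35, neurite = 3.2),
                             enrichment_sdlog = 0.35,
                             seed = 1) {
  if (n_soma < 1 || n_neurite < 1) stop_config("group sizes must be >= 1")
  eff <- utils::modifyList(list(
    mrna_halflife_h = 0.5, transcript_nt = 0.3, protein_halflife_d = -0.3,
    protein_aa = 0.25, spine_copies = 0,
    mrna_abundance = 0.5, protein_abundance = 0.5), effects)
  bas <- utils::modifyList(list(
    mrna_halflife_h = 10, transcript_nt = 2700, protein_halflife_d = 8,
    protein_aa = 450, spine_copies = 1000,
    mrna_abundance = 50, protein_abundance = 5e5), base)
  if (any(unlist(eff) <= -1))
    stop_config("effects must be > -1 (multiplicative medians stay positive)")
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(seed)
  n <- n_soma + n_neurite
  group <- rep(c("soma", "neurite"), c(n_soma, n_neurite))
  is_neu <- group == "neurite"
  df <- data.frame(
    gene = sprintf("gene%05d", seq_len(n)),
    group = group, stringsAsFactors = FALSE)
  df$enrichment <- rlnorm(
    n,
    meanlog = log(ifelse(is_neu, enrichment_folds[["neurite"]],
                         enrichment_folds[["soma"]])),
    sdlog = enrichment_sdlog)
  for (prop in names(bas)) {
    med <- bas[[prop]] * ifelse(is_neu, 1 + eff[[prop]], 1)
    df[[prop]] <- rlnorm(n, meanlog = log(med), sdlog = noise_sdlog)
  }
  df
}

#' Write a synthetic screen to CSV
#'
#' @param screen a [synthetic_screen()] table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_screen_csv <- function(screen, path) {
  write.csv(screen, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a screen table from delimited text
#'
#' Reads CSV/TSV with an optional column-mapping so external tables with
#' different headers can be ingested (`column_map = c(gene = "GeneName",
#' enrichment = "log2FC", ...)`).
#'
#' @param path CSV or TSV file.
#' @param column_map optional named character vector mapping canonical column
#'   names to the file's column names.
#' @return data.frame with canonical columns.
#' @export
read_screen_table <- function(path, column_map = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    miss <- setdiff(unname(column_map), names(df))
    if (length(miss))
      stop_config("mapped column(s) absent from ", path, ": ",
                  paste(miss, collapse = ", "))
    for (canon in names(column_map)) {
      df[[canon]] <- df[[column_map[[canon]]]]
    }
  }
  if (!all(c("gene", "enrichment") %in% names(df)))
    stop_config("screen table needs 'gene' and 'enrichment' columns ",
                "(supply a column_map)")
  df
}
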