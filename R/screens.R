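#' Classify screen records by neurite/soma enrichment
#'
#' Labels each gene `"neurite"` if its enrichment score (neurite/soma fold)
#' is at least `threshold_fold`, `"somata"` if it is at most
#' `1/threshold_fold`, and `"unclassified"` otherwise (the middle band is
#' excluded from group comparisons). Records with non-positive enrichment are
#' dropped with a warning.
#'
#' @param records data.frame with at least `gene` and `enrichment` columns.
#' @param threshold_fold classification threshold (>= 1); 2 is the strict
#'   default, 1 the permissive variant (no middle band).
#' @return the records with a `label` column; dropped rows are reported in
#'   the `"n_rejected"` attribute.
#' @export
classify_enrichment <- function(records, threshold_fold = 2) {
  if (threshold_fold < 1) stop_config("threshold_fold must be >= 1")
  if (!all(c("gene", "enrichment") %in% names(records)))
    stop_config("records need 'gene' and 'enrichment' columns")
  bad <- !is.finite(records$enrichment) | records$enrichment <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive enrichment rejected")
    records <- records[!bad, , drop = FALSE]
  }
  records$label <- ifelse(records$enrichment >= threshold_fold, "neurite",
                   ifelse(records$enrichment <= 1 / threshold_fold, "somata",
                          "unclassified"))
  structure(records, n_rejected = sum(bad))
}

normalise_gene <- function(g) tolower(trimws(as.character(g)))

#' Cross-match two screens by gene name
#'
#' Inner join on case-folded, whitespace-stripped gene identifiers,
#' optionally routed through a homologue table (e.g. mouse-to-rat gene
#' names). One-to-many homologue matches resolve to the first listed
#' homologue with a warning.
#'
#' @param records_a,records_b data.frames with a `gene` column.
#' @param homologue_table optional two-column data.frame mapping `records_a`
#'   gene names (first column) to `records_b` gene names (second column).
#' @return joined data.frame (columns suffixed `.a`/`.b` on clashes) with a
#'   `"status"` attribute, `"ok"` or `"empty"`.
#' @export
crossmatch <- function(records_a, records_b, homologue_table = NULL) {
  a <- records_a; b <- records_b
  a$.gene_key <- normalise_gene(a$gene)
  b$.gene_key <- normalise_gene(b$gene)
  if (!is.null(homologue_table)) {
    h <- data.frame(from = normalise_gene(homologue_table[[1]]),
                    to = normalise_gene(homologue_table[[2]]),
                    stringsAsFactors = FALSE)
    if (anyDuplicated(h$from)) {
      warning("one-to-many homologue matches resolved to the first listed")
      h <- h[!duplicated(h$from), , drop = FALSE]
    }
    idx <- match(a$.gene_key, h$from)
    a$.gene_key[!is.na(idx)] <- h$to[idx[!is.na(idx)]]
  }
  joined <- merge(a, b, by = ".gene_key", suffixes = c(".a", ".b"))
  joined$.gene_key <- NULL
  structure(joined, status = if (nrow(joined)) "ok" else "empty")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact permutation enumeration (correct under ties, via midranks) when the
#' pooled sample size does not exceed `exact_limit`; otherwise the normal
#' approximation with tie-corrected variance. The two-sided exact p-value is
#' the permutation probability of a rank sum at least as far from its mean as
#' the observed one.
#'
#' @param group1,group2 numeric vectors (non-empty).
#' @param exact_limit largest pooled size for exact enumeration.
#' @return two-sided p-value.
#' @export
ranksum_test <- function(group1, group2, exact_limit = 12) {
  if (!length(group1) || !length(group2))
    stop_config("both groups must be non-empty")
  n1 <- length(group1); n2 <- length(group2); N <- n1 + n2
  r <- rank(c(group1, group2))
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (N + 1) / 2
  if (max(r) - min(r) < .Machine$double.eps) return(1)  # all values tied
  if (N <= exact_limit) {
    sets <- utils::combn(N, n1)
    Wperm <- colSums(matrix(r[sets], nrow = n1))
    mean(abs(Wperm - EW) >= abs(W - EW) - 1e-9)
  } else {
    ties <- table(r)
    varW <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (varW <= 0) return(1)
    2 * pnorm(-abs(W - EW) / sqrt(varW))
  }
}

#' Bootstrap summaries per enrichment group
#'
#' Resamples each labelled group with replacement and returns the resampled
#' means/medians with percentile intervals. Deterministic for a given seed;
#' the global RNG state is left untouched.
#'
#' @param records a classified data.frame (see [classify_enrichment()]).
#' @param value name of the numeric column to summarise.
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param seed RNG seed.
#' @param groups labels to include.
#' @return named list per group: `n`, `mean`, `median`, `boot_means`,
#'   `boot_medians`, `ci_mean` (2.5/97.5 percentiles).
#' @export
bootstrap_groups <- function(records, value, n_boot = 10000, seed = 1,
                             groups = c("somata", "neurite")) {
  if (n_boot < 1) stop_config("n_boot must be >= 1")
  if (!value %in% names(records)) stop_config("no column '", value, "'")
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(seed)
  out <- list()
  for (g in groups) {
    v <- records[[value]][records$label == g]
    v <- v[is.finite(v)]
    if (!length(v)) next
    bm <- numeric(n_boot); bmed <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      s <- v[sample.int(length(v), replace = TRUE)]
      bm[b] <- mean(s); bmed[b] <- median(s)
    }
    out[[g]] <- list(n = length(v), mean = mean(v), median = median(v),
                     boot_means = bm, boot_medians = bmed,
                     ci_mean = quantile(bm, c(0.025, 0.975), names = FALSE))
  }
  out
}

#' Correct molecule counts for detection probability
#'
#' Sequencing screens detect only a fraction of the molecules present;
#' observed counts are rescaled by the reciprocal of the detection
#' probability (e.g. 25% detection scales counts by 4, 20% by 5).
#'
#' @param counts numeric vector of observed counts.
#' @param detection_probability in `(0, 1]`.
#' @return corrected counts.
#' @export
rescale_counts <- function(counts, detection_probability) {
  if (!is.numeric(detection_probability) || length(detection_probability) != 1 ||
      detection_probability <= 0 || detection_probability > 1)
    stop_config("detection_probability must lie in (0, 1]")
  counts / detection_probability
}

#' Enrichment-screen comparison report
#'
#' Runs the panel comparisons between somata- and neurite-enriched genes on a
#' (synthetic or real) screen table: per molecular property, group sizes and
#' medians, the two-sided rank-sum p-value and a bootstrap interval of the
#' group means.
#'
#' @param screen data.frame with `gene`, `enrichment` and property columns.
#' @param properties property columns to compare.
#' @param threshold_fold classification threshold, see [classify_enrichment()].
#' @param n_boot bootstrap resamples per group (0 disables bootstrapping).
#' @param seed RNG seed for the bootstrap.
#' @return a list of per-property results plus the group sizes.
#' @export
screen_report <- function(screen,
                          properties = c("mrna_halflife_h", "transcript_nt",
                                         "spine_copies", "protein_halflife_d",
                                         "protein_aa"),
                          threshold_fold = 2, n_boot = 1000, seed = 1) {
  labelled <- classify_enrichment(screen, threshold_fold)
  properties <- intersect(properties, names(labelled))
  if (!length(properties)) stop_config("no requested property column present")
  som <- labelled[labelled$label == "somata", , drop = FALSE]
  neu <- labelled[labelled$label == "neurite", , drop = FALSE]
  panels <- list()
  for (prop in properties) {
    v1 <- som[[prop]][is.finite(som[[prop]])]
    v2 <- neu[[prop]][is.finite(neu[[prop]])]
    if (!length(v1) || !length(v2)) {
      panels[[prop]] <- list(status = "group-empty")
      next
    }
    boot <- if (n_boot > 0)
      bootstrap_groups(labelled, prop, n_boot = n_boot, seed = seed)
    panels[[prop]] <- list(
      status = "ok",
      n = c(somata = length(v1), neurite = length(v2)),
      median = c(somata = median(v1), neurite = median(v2)),
      direction = if (median(v2) > median(v1)) "neurite-higher"
                  else if (median(v2) < median(v1)) "somata-higher" else "equal",
      p_value = ranksum_test(v1, v2),
      ci_mean = if (!is.null(boot))
        lapply(boot, function(g) g$ci_mean))
  }
  list(threshold_fold = threshold_fold,
       n = c(somata = nrow(som), neurite = nrow(neu),
             unclassified = sum(labelled$label == "unclassified")),
       panels = panels)
}
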