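test_that("enrichment classification applies the fold threshold with a middle band", {
  rec <- data.frame(gene = c("a", "b", "c", "d"),
                    enrichment = c(2.5, 0.4, 1.5, 1 / 2.5))
  out <- classify_enrichment(rec, 2)
  expect_equal(out$label, c("neurite", "somata", "unclassified", "somata"))
  # permissive 1-fold variant has no middle band
  out1 <- classify_enrichment(rec, 1)
  expect_false(any(out1$label == "unclassified"))
  expect_warning(classify_enrichment(
    data.frame(gene = "x", enrichment = -1), 2), "rejected")
  expect_error(classify_enrichment(rec, 0.5),
               class = "dendrocost_config_error")
})

test_that("cross-matching joins case-folded gene names, optionally via homologues", {
  a <- data.frame(gene = c("Camk2a", "Shank3"), val_a = 1:2)
  b <- data.frame(gene = c("CAMK2A", "Grin1"), val_b = 3:4)
  m <- crossmatch(a, b)
  expect_equal(nrow(m), 1)
  expect_equal(m$val_a, 1)
  expect_equal(attr(crossmatch(a, data.frame(gene = "Dlg4")), "status"),
               "empty")
  ident <- crossmatch(b, b)
  expect_equal(nrow(ident), 2)
  # homologue routing with a one-to-many warning
  h <- data.frame(mouse = c("Shank3", "Shank3"), rat = c("SHANK3b", "SHANK3c"))
  b2 <- data.frame(gene = "shank3b", val_b = 9)
  expect_warning(m2 <- crossmatch(a, b2, h), "one-to-many")
  expect_equal(nrow(m2), 1)
  expect_equal(m2$val_b, 9)
})

test_that("exact rank-sum enumerates permutations, including the textbook case", {
  expect_equal(ranksum_test(1:3, 4:6), 0.1)
  expect_equal(ranksum_test(4:6, 1:3), 0.1)   # symmetric in group order
  expect_equal(ranksum_test(c(2, 2, 2), c(2, 2)), 1)
})

test_that("exact rank-sum matches the full enumeration oracle for all n <= 6", {
  # independent oracle: direct enumeration over group assignments
  enum_p <- function(g1, g2) {
    n1 <- length(g1)
    r <- rank(c(g1, g2))
    W <- sum(r[seq_len(n1)])
    E <- n1 * (length(r) + 1) / 2
    sets <- utils::combn(length(r), n1)
    Wp <- apply(sets, 2, function(s) sum(r[s]))
    mean(abs(Wp - E) >= abs(W - E) - 1e-9)
  }
  set.seed(11)
  for (n1 in 2:6) for (n2 in 2:6) {
    g1 <- sample(1:8, n1, replace = TRUE)   # ties included
    g2 <- sample(1:8, n2, replace = TRUE)
    expect_equal(ranksum_test(g1, g2), enum_p(g1, g2),
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
  # tie-free exact cases agree with the classic distribution
  for (i in 1:5) {
    g1 <- runif(4); g2 <- runif(5)
    expect_equal(ranksum_test(g1, g2),
                 wilcox.test(g1, g2, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(4)
  g1 <- round(rnorm(40, 0, 2))
  g2 <- round(rnorm(55, 0.8, 2))
  ref <- wilcox.test(g1, g2, exact = FALSE, correct = FALSE)$p.value
  expect_equal(ranksum_test(g1, g2), ref, tolerance = 1e-12)
})

test_that("bootstrap summaries are seeded, deterministic and consistent", {
  rec <- classify_enrichment(synthetic_screen(n_soma = 40, n_neurite = 40,
                                              seed = 5), 2)
  b1 <- bootstrap_groups(rec, "protein_aa", n_boot = 200, seed = 9)
  b2 <- bootstrap_groups(rec, "protein_aa", n_boot = 200, seed = 9)
  expect_identical(b1, b2)
  b3 <- bootstrap_groups(rec, "protein_aa", n_boot = 200, seed = 10)
  expect_false(identical(b1$somata$boot_means, b3$somata$boot_means))
  # a constant-valued group bootstraps to that constant
  const <- data.frame(gene = letters[1:6], enrichment = 3,
                      label = "neurite", v = 7)
  bc <- bootstrap_groups(const, "v", n_boot = 50, seed = 1)
  expect_true(all(bc$neurite$boot_means == 7))
  # CLT sanity: bootstrap mean of means close to the sample mean
  v <- rec$protein_aa[rec$label == "neurite"]
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(b1$neurite$boot_means) - mean(v)), 3 * se)
})

test_that("detection-probability rescaling is reciprocal", {
  expect_equal(rescale_counts(c(1, 2, 3), 1), c(1, 2, 3))
  expect_equal(rescale_counts(10, 0.25), 40)
  expect_equal(rescale_counts(10, 0.2), 50)
  expect_error(rescale_counts(1, 0), class = "dendrocost_config_error")
  expect_error(rescale_counts(1, 1.2), class = "dendrocost_config_error")
})

test_that("screen report reproduces the predicted panel directions", {
  scr <- synthetic_screen(n_soma = 250, n_neurite = 250, seed = 21)
  rep <- screen_report(scr, n_boot = 200, seed = 3)
  p <- rep$panels
  expect_equal(p$mrna_halflife_h$direction, "neurite-higher")
  expect_equal(p$transcript_nt$direction, "neurite-higher")
  expect_equal(p$protein_halflife_d$direction, "somata-higher")
  expect_equal(p$protein_aa$direction, "neurite-higher")
  for (nm in c("mrna_halflife_h", "transcript_nt", "protein_halflife_d",
               "protein_aa"))
    expect_lt(p[[nm]]$p_value, 0.01)
  # spine copies carry no effect by construction
  expect_gt(p$spine_copies$p_value, 0.05)
})
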