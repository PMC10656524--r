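sim_universe <- function(n, set_rate = 0.1, disease_rate = 0.05,
                         log_odds = 0) {
  u <- data.frame(gene = sprintf("g%05d", seq_len(n)),
                  gc_content = stats::runif(n, 0.3, 0.7),
                  gene_length = round(stats::rlnorm(n, 7, 0.5)),
                  mean_expression = stats::rlnorm(n, 1, 1))
  u$in_set <- stats::runif(n) < set_rate
  eta <- stats::qlogis(disease_rate) + log_odds * u$in_set
  u$in_disease <- stats::runif(n) < stats::plogis(eta)
  u
}

test_that("Bonferroni thresholds reproduce the published cutoffs", {
  expect_equal(signif(bonferroni_threshold(0.05, 88), 3), 5.68e-4)
  expect_equal(signif(bonferroni_threshold(0.05, 42), 3), 1.19e-3)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("unassigned-module exclusion drops the set and its exclusive genes", {
  u <- data.frame(gene = letters[1:5],
                  gray = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                  blue = c(FALSE, TRUE, TRUE, FALSE, FALSE),
                  red = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  out <- exclude_unassigned(u, c("gray", "blue", "red"))
  expect_setequal(attr(out, "tested_sets"), c("blue", "red"))
  expect_false("a" %in% out$gene)       # gray-only gene leaves the universe
  expect_true("b" %in% out$gene)        # gray gene kept via blue
  expect_false("gray" %in% names(out))
  # no unassigned set present: identity
  out2 <- exclude_unassigned(u[, -2], c("blue", "red"))
  expect_equal(nrow(out2), 5L)
})

test_that("null universes give near-zero coefficients and uniform p", {
  set.seed(91)
  p_vals <- coefs <- numeric(60)
  for (i in seq_len(60)) {
    u <- sim_universe(1500)
    f <- fit_enrichment(u, "in_set", "in_disease", orientation = "module")
    p_vals[i] <- f$p
    coefs[i] <- f$coefficient
  }
  expect_lt(abs(mean(coefs)), 0.1)
  ks <- suppressWarnings(stats::ks.test(p_vals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted log-odds of 1.5 is recovered within its interval", {
  set.seed(92)
  u <- sim_universe(5000, set_rate = 0.15, disease_rate = 0.08,
                    log_odds = 1.5)
  f <- fit_enrichment(u, "in_set", "in_disease", orientation = "module")
  expect_lt(abs(f$coefficient - 1.5), 3 * f$se)
  expect_lt(f$p, 1e-4)
})

test_that("degenerate indicators and separation are explicit", {
  u <- sim_universe(500)
  u$all_in <- TRUE
  expect_error(fit_enrichment(u, "all_in", "in_disease"), "whole")
  # complete separation: disease exactly equals set membership
  u2 <- sim_universe(500, set_rate = 0.2)
  u2$in_disease <- u2$in_set
  expect_error(fit_enrichment(u2, "in_set", "in_disease", firth = FALSE),
               "separation")
  f <- fit_enrichment(u2, "in_set", "in_disease", firth = TRUE)
  expect_true(f$firth)
  expect_true(is.finite(f$coefficient))
  expect_lt(f$p, 1e-6)
})

test_that("with no covariates the indicator sign matches the 2x2 odds ratio", {
  set.seed(93)
  for (i in 1:10) {
    u <- sim_universe(2000, log_odds = stats::runif(1, -1.5, 1.5))
    f <- fit_enrichment(u, "in_set", "in_disease", covariates = character(0))
    tab <- table(u$in_set, u$in_disease)
    or <- (tab[2, 2] * tab[1, 1]) / (tab[1, 2] * tab[2, 1])
    expect_equal(sign(f$coefficient), sign(log(or)))
    # and the Wald test agrees directionally with Fisher's exact
    ft <- stats::fisher.test(tab)
    expect_equal(f$p < 0.05 && or > 1, ft$p.value < 0.05 && or > 1)
  }
})

test_that("results are invariant to gene order and covariate rescaling", {
  set.seed(94)
  u <- sim_universe(2000, log_odds = 1)
  f1 <- fit_enrichment(u, "in_set", "in_disease")
  f2 <- fit_enrichment(u[sample(nrow(u)), ], "in_set", "in_disease")
  expect_equal(f1$coefficient, f2$coefficient, tolerance = 1e-8)
  u3 <- u
  u3$gc_content <- u3$gc_content * 100 - 17
  f3 <- fit_enrichment(u3, "in_set", "in_disease")
  expect_equal(f1$coefficient, f3$coefficient, tolerance = 1e-8)
  expect_equal(f1$p, f3$p, tolerance = 1e-8)
})

test_that("permuting disease labels yields uniform p-values", {
  set.seed(95)
  u <- sim_universe(600, set_rate = 0.2, disease_rate = 0.1, log_odds = 2)
  p_perm <- numeric(1000)
  for (i in seq_len(1000)) {
    up <- u
    up$in_disease <- sample(up$in_disease)
    p_perm[i] <- fit_enrichment(up, "in_set", "in_disease",
                                firth = TRUE)$p
  }
  ks <- suppressWarnings(stats::ks.test(p_perm, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("both model orientations are available and recorded", {
  set.seed(96)
  u <- sim_universe(1500, log_odds = 1)
  fm <- fit_enrichment(u, "in_set", "in_disease", orientation = "module")
  fc <- fit_enrichment(u, "in_set", "in_disease", orientation = "celltype",
                       covariates = c("gc_content", "gene_length"))
  expect_equal(fm$orientation, "module")
  expect_equal(fc$orientation, "celltype")
  expect_gt(fc$coefficient, 0)
  m <- enrichment_matrix(u, "in_set", "in_disease", n_tests = 88)
  expect_equal(attr(m, "threshold"), 0.05 / 88)
})
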