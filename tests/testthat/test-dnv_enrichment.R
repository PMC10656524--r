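test_that("Poisson upper tail is exact and monotone", {
  expect_equal(poisson_upper_p(0, 5), 1)
  expect_equal(poisson_upper_p(3, 1), 1 - exp(-1) * (1 + 1 + 0.5),
               tolerance = 1e-14)
  expect_error(poisson_upper_p(2, 0), "expected")
  expect_error(poisson_upper_p(-1, 1), "observed")
  # nonincreasing in observed, nondecreasing in expected
  lam <- 2.7
  p_obs <- poisson_upper_p(0:30, lam)
  expect_true(all(diff(p_obs) <= 0))
  obs <- 4
  p_lam <- poisson_upper_p(obs, seq(0.1, 20, by = 0.1))
  expect_true(all(diff(p_lam) >= -1e-15))
})

test_that("enrichment results keep observed = enrichment x expected", {
  r <- enrichment_result(c("a", "b"), c(5, 0), c(2.5, 3), 90)
  expect_equal(r$enrichment * r$expected, r$observed)
  expect_equal(r$enrichment[2], 0)
  expect_equal(r$p[2], 1)
  # zero expectation with nonzero observation is flagged, not a p-value
  r0 <- enrichment_result("c", 2, 0, 90)
  expect_true(r0$zero_expectation)
  expect_true(is.na(r0$p))
})

test_that("the class table reproduces rates and per-gene threshold", {
  # rate per subject: 107 DNVs among 90 trios
  r <- enrichment_result("total", 107, 99.7, 90)
  expect_equal(round(r$rate, 2), 1.19)
  fx <- fixture_suite()
  g <- fx$fx$universe$genes
  dnvs <- data.frame(gene = g$gene_id[1:3],
                     class = c("synonymous", "missense", "stopgain"),
                     metasvm = c(".", "D", "."), mpc = c(NA, 3, NA))
  tab <- class_enrichment_table(dnvs, g, 3)
  expect_setequal(unique(tab$subset), c("all", "pli"))
  all_block <- tab[tab$subset == "all", ]
  expect_equal(all_block$observed[all_block$unit == "total"], 3)
  expect_equal(all_block$observed[all_block$unit == "dmis"], 1)
  expect_equal(all_block$observed[all_block$unit == "protein_damaging"], 2)
  # expectations add up: total = syn + tmis + dmis + lof
  parts <- all_block$expected[match(c("syn", "tmis", "dmis", "lof"),
                                    all_block$unit)]
  expect_equal(sum(parts),
               all_block$expected[all_block$unit == "total"],
               tolerance = 1e-12)

  pg <- per_gene_dnv_test(dnvs, g, 3, n_genes = 19347)
  expect_equal(signif(attr(pg, "threshold"), 2), 8.6e-7)
  # small-lambda closed form: p for 2 hits is ~ lambda^2 / 2
  lam <- 1e-3
  expect_equal(poisson_upper_p(2, lam), lam^2 / 2, tolerance = 1e-3)
  # a gene with zero observed is never significant
  zero_genes <- pg$gene[pg$observed == 0]
  expect_false(any(pg$significant[pg$gene %in% zero_genes]))
})

test_that("attributable fraction matches the excess over expectation", {
  expect_equal(attributable_fraction(33, 22, 90), 11 / 90)
  expect_equal(attributable_fraction(10, 10, 90), 0)
  expect_warning(af <- attributable_fraction(5, 10, 90), "floored")
  expect_equal(af, 0)
  expect_error(attributable_fraction(33, 22, 0), "n_probands")
  # simulation recovery at a 15% planted fraction
  set.seed(71)
  n_trios <- 90
  lam <- rep(22 / 2000, 2000)                 # null damaging expectations
  fold <- rep(1, 2000)
  fold[1] <- 1 + 0.15 * n_trios / lam[1]      # one risk gene carries the excess
  reps <- 400
  cnt <- simulate_dnv_counts(lam, reps, fold)
  af_hat <- (rowSums(cnt) - sum(lam)) / n_trios
  mc_se <- sd(af_hat) / sqrt(reps)
  expect_lt(abs(mean(af_hat) - 0.15), 4 * mc_se)
})

test_that("risk-gene estimation is self-consistent and saturation is monotone", {
  set.seed(72)
  n_genes <- 800
  lam <- rep(30 / n_genes, n_genes) * exp(rnorm(n_genes, 0, 0.4))
  names(lam) <- sprintf("G%03d", seq_len(n_genes))
  # zero excess: degenerate estimate
  r0 <- estimate_risk_genes_and_saturation(
    stats::setNames(integer(0), character(0)), lam, 90,
    replicates = 100, seed = 1)
  expect_equal(r0$estimate, 0)
  expect_equal(unname(r0$saturation$saturation), c(0, 0))

  # cohort drawn from 66 planted risk genes: interval covers the truth
  m_true <- 66
  risk <- sample(names(lam), m_true, prob = lam)
  excess <- 11
  obs <- stats::rpois(n_genes, lam)
  names(obs) <- names(lam)
  extra <- stats::rmultinom(1, excess, lam[risk])[, 1]
  obs[risk] <- obs[risk] + extra
  est <- estimate_risk_genes_and_saturation(obs[obs > 0], lam, 90,
                                            future_sizes = c(250, 1000),
                                            replicates = 150, seed = 9,
                                            m_max = 400)
  expect_true(est$interval[1] <= m_true && m_true <= est$interval[2])
  # saturation nondecreasing in cohort size, and in [0, 1]
  expect_true(all(diff(est$saturation$saturation) >= 0))
  expect_true(all(est$saturation$saturation >= 0 &
                    est$saturation$saturation <= 1))
})

test_that("per-gene null p-values are super-uniform", {
  set.seed(73)
  lam <- rep(25 / 2000, 2000) * exp(rnorm(2000, 0, 0.5))
  cnt <- simulate_dnv_counts(lam, 50)
  p <- matrix(poisson_upper_p(as.vector(cnt), rep(lam, each = 50)),
              nrow = 50)
  n <- length(p)
  for (alpha in c(0.001, 0.01, 0.05)) {
    frac <- mean(p <= alpha)
    expect_lte(frac, alpha + 3 * sqrt(alpha * (1 - alpha) / n))
  }
})
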