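#' One-sided Poisson upper-tail probability
#'
#' P(X >= observed) for X ~ Poisson(expected), at full numeric precision
#' (no normal approximation).
#'
#' @param observed nonnegative integer count(s).
#' @param expected positive expected count(s).
#' @return upper-tail probability in (0, 1].
#' @export
poisson_upper_p <- function(observed, expected) {
  if (any(observed < 0)) stop("observed must be >= 0")
  if (any(expected <= 0)) stop("expected must be > 0")
  stats::ppois(observed - 1, expected, lower.tail = FALSE)
}

#' Enrichment summary for observed vs expected counts
#'
#' @param unit label (gene id or functional class).
#' @param observed observed count(s).
#' @param expected model-expected count(s); a zero expectation with nonzero
#'   observation is flagged rather than assigned a p-value.
#' @param n_subjects cohort size for the per-subject rate columns.
#' @return data.frame: unit, observed, rate, expected, rate_expected,
#'   enrichment, p, zero_expectation.
#' @export
enrichment_result <- function(unit, observed, expected, n_subjects) {
  zero <- expected <= 0
  enr <- ifelse(zero, NA_real_, observed / expected)
  p <- rep(NA_real_, length(observed))
  p[!zero] <- poisson_upper_p(observed[!zero], expected[!zero])
  data.frame(unit = unit, observed = observed,
             rate = observed / n_subjects, expected = expected,
             rate_expected = expected / n_subjects, enrichment = enr, p = p,
             zero_expectation = zero & observed > 0, stringsAsFactors = FALSE)
}

.class_rows <- c("total", "syn", "tmis", "dmis", "lof",
                 "protein_altering", "protein_damaging")

# observed DNV counts per summary class, using the per-variant damaging calls
.observed_by_class <- function(dnvs) {
  lof <- dnvs$class %in% .lof_classes
  mis <- dnvs$class == "missense"
  dmis <- mis & is_damaging(dnvs$class, dnvs$metasvm, dnvs$mpc)
  c(total = nrow(dnvs), syn = sum(dnvs$class == "synonymous"),
    tmis = sum(mis & !dmis), dmis = sum(dmis), lof = sum(lof),
    protein_altering = sum(mis | lof), protein_damaging = sum(dmis | lof))
}

# expected DNV counts per summary class from gene model columns
.expected_by_class <- function(gene_models, n_trios) {
  pm <- gene_models
  lof <- pm$p_stopgain + pm$p_stoploss + pm$p_startloss +
    pm$p_splice_canonical + pm$p_frameshift
  dmis <- pm$dmis_fraction * pm$p_missense
  e <- function(p) sum(expected_dnv_count(p, n_trios))
  c(total = e(pm$p_synonymous + pm$p_missense + lof),
    syn = e(pm$p_synonymous), tmis = e(pm$p_missense - dmis), dmis = e(dmis),
    lof = e(lof), protein_altering = e(pm$p_missense + lof),
    protein_damaging = e(dmis + lof))
}

#' Cohort-level DNV enrichment by functional class
#'
#' Observed versus model-expected de novo counts for the summary classes
#' (Total, synonymous, tolerated and damaging missense, LoF,
#' protein-altering, protein-damaging), for all genes and separately for the
#' constrained subset (pLI >= 0.9), each with a per-subject rate, fold
#' enrichment and one-sided Poisson p.
#'
#' @param dnvs data.frame of filtered DNVs with columns `gene`, `class`,
#'   `metasvm`, `mpc`.
#' @param gene_models data.frame with `gene_id`, `pLI`, `dmis_fraction` and
#'   `p_<class>` probability columns.
#' @param n_trios number of complete trios.
#' @param pli_min constraint threshold for the restricted block.
#' @return data.frame with a `subset` column (`all`, `pli`) over the class
#'   rows of [enrichment_result()].
#' @export
class_enrichment_table <- function(dnvs, gene_models, n_trios, pli_min = 0.9) {
  block <- function(d, g, label) {
    obs <- .observed_by_class(d)
    exp <- .expected_by_class(g, n_trios)
    cbind(subset = label, enrichment_result(.class_rows, unname(obs[.class_rows]),
                                            unname(exp[.class_rows]), n_trios))
  }
  keep <- !is.na(gene_models$pLI) & gene_models$pLI >= pli_min
  in_pli <- dnvs$gene %in% gene_models$gene_id[keep]
  out <- rbind(block(dnvs, gene_models, "all"),
               block(dnvs[in_pli, , drop = FALSE],
                     gene_models[keep, , drop = FALSE], "pli"))
  rownames(out) <- NULL
  out
}

.test_families <- list(
  protein_altering = function(pm) pm$p_missense + pm$p_stopgain + pm$p_stoploss +
    pm$p_startloss + pm$p_splice_canonical + pm$p_frameshift,
  protein_damaging = function(pm) pm$dmis_fraction * pm$p_missense + pm$p_stopgain +
    pm$p_stoploss + pm$p_startloss + pm$p_splice_canonical + pm$p_frameshift,
  lof = function(pm) pm$p_stopgain + pm$p_stoploss + pm$p_startloss +
    pm$p_splice_canonical + pm$p_frameshift
)

#' Per-gene de novo burden tests
#'
#' One-sided Poisson test of observed versus expected DNVs per gene, run for
#' three class families (protein-altering, protein-damaging, LoF), with the
#' Bonferroni threshold 0.05 / (3 x number of genes). Genes with zero
#' expectation are excluded from testing and reported in the `excluded`
#' attribute.
#'
#' @param dnvs filtered DNV data.frame (columns `gene`, `class`, `metasvm`,
#'   `mpc`).
#' @param gene_models gene model data.frame (see [class_enrichment_table()]).
#' @param n_trios number of trios.
#' @param n_genes number of genes tested (defaults to `nrow(gene_models)`).
#' @param alpha family-wise error target.
#' @return data.frame per (gene, family): observed, expected, enrichment, p,
#'   significant; attribute `threshold` holds the Bonferroni cutoff.
#' @export
per_gene_dnv_test <- function(dnvs, gene_models, n_trios,
                              n_genes = nrow(gene_models), alpha = 0.05) {
  threshold <- alpha / (3 * n_genes)
  lof <- dnvs$class %in% .lof_classes
  dmis <- is_damaging(dnvs$class, dnvs$metasvm, dnvs$mpc) &
    dnvs$class == "missense"
  mis <- dnvs$class == "missense"
  obs_of <- function(sel) {
    t <- table(factor(dnvs$gene[sel], levels = gene_models$gene_id))
    as.numeric(t)
  }
  observed <- list(protein_altering = obs_of(mis | lof),
                   protein_damaging = obs_of(dmis | lof),
                   lof = obs_of(lof))
  out <- list()
  excluded <- list()
  for (fam in names(.test_families)) {
    expg <- expected_dnv_count(.test_families[[fam]](gene_models), n_trios)
    obs <- observed[[fam]]
    zero <- expg <= 0
    excluded[[fam]] <- data.frame(gene = gene_models$gene_id[zero],
                                  family = rep(fam, sum(zero)),
                                  observed = obs[zero],
                                  stringsAsFactors = FALSE)
    r <- enrichment_result(gene_models$gene_id[!zero], obs[!zero],
                           expg[!zero], n_trios)
    out[[fam]] <- data.frame(gene = r$unit, family = fam,
                             observed = r$observed, expected = r$expected,
                             enrichment = r$enrichment, p = r$p,
                             significant = r$p <= threshold,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "threshold") <- threshold
  attr(res, "excluded") <- do.call(rbind, excluded)
  res
}

#' Attributable fraction of cases explained by damaging DNVs
#'
#' The excess of observed over expected damaging de novo variants divided by
#' the number of probands; floored at 0 with a warning when observed falls
#' below expected.
#'
#' @param observed_damaging observed damaging DNV count.
#' @param expected_damaging model-expected damaging DNV count.
#' @param n_probands cohort size (> 0).
#' @param conf_level if non-NULL, attach an exact Poisson confidence interval
#'   on the observed count propagated to the fraction scale (attribute `ci`).
#' @return attributable fraction in \[0, 1\].
#' @export
attributable_fraction <- function(observed_damaging, expected_damaging,
                                  n_probands, conf_level = NULL) {
  if (n_probands == 0) stop("n_probands must be > 0")
  if (observed_damaging < expected_damaging) {
    warning("observed below expected; attributable fraction floored at 0")
    frac <- 0
  } else frac <- (observed_damaging - expected_damaging) / n_probands
  if (!is.null(conf_level)) {
    a <- (1 - conf_level) / 2
    lo <- if (observed_damaging == 0) 0 else
      stats::qgamma(a, observed_damaging)
    hi <- stats::qgamma(1 - a, observed_damaging + 1)
    attr(frac, "ci") <- pmax(0, c(lo, hi) - expected_damaging) / n_probands
  }
  frac
}

#' Risk-gene count and gene-discovery saturation by Monte Carlo
#'
#' Estimates how many genes contribute to the disorder through damaging de
#' novo variants, from the excess of observed damaging DNVs and the number
#' of genes hit more than once, then projects the fraction of those risk
#' genes that future cohorts would detect. For a candidate count M, risk
#' genes are drawn with probability proportional to their damaging
#' mutability, background counts are Poisson at the model expectation, and
#' the excess DNVs are scattered multinomially over the risk genes; the
#' likelihood of the observed multi-hit gene count is evaluated against the
#' simulated expectation (Poisson approximation), giving a maximum-likelihood
#' M and a profile-likelihood interval. Saturation at a future cohort of S
#' trios is the expected fraction of risk genes attaining at least
#' `hits_required` damaging DNVs when all rates scale by S / n_trios.
#'
#' @param dnv_gene_multiplicities named integer vector: observed damaging
#'   DNV count per gene (genes with zero hits may be omitted).
#' @param gene_lambda named numeric vector: per-gene expected damaging DNV
#'   count for the current cohort (2 x n_trios x damaging mutability).
#' @param n_trios current cohort size.
#' @param future_sizes integer vector of future trio counts.
#' @param replicates Monte Carlo replicates per grid point (>= 100).
#' @param seed integer seed (required).
#' @param hits_required hits needed to call a risk gene detected (1 or 2).
#' @param m_max largest risk-gene count on the likelihood grid.
#' @return list: `estimate`, `interval`, `excess`, `multi_hit`,
#'   `saturation` (data.frame size x saturation), `replicates`, `seed`.
#' @export
estimate_risk_genes_and_saturation <- function(dnv_gene_multiplicities,
                                               gene_lambda, n_trios,
                                               future_sizes = c(250, 1000),
                                               replicates = 500, seed,
                                               hits_required = 1,
                                               m_max = 300) {
  if (missing(seed)) stop("seed is required")
  if (replicates < 100) stop("replicates must be >= 100")
  set.seed(seed)
  genes <- names(gene_lambda)
  obs <- stats::setNames(rep(0, length(genes)), genes)
  hit <- intersect(names(dnv_gene_multiplicities), genes)
  obs[hit] <- dnv_gene_multiplicities[hit]
  excess <- sum(obs) - sum(gene_lambda)
  multi <- sum(obs >= 2)

  if (excess <= 0 || round(excess) == 0) {
    sat <- data.frame(size = future_sizes, saturation = 0)
    return(list(estimate = 0, interval = c(0, 0), excess = max(0, excess),
                multi_hit = multi, saturation = sat,
                replicates = replicates, seed = seed))
  }

  w <- gene_lambda / sum(gene_lambda)
  n_excess <- round(excess)
  m_grid <- seq_len(min(m_max, length(genes)))

  sim_multi <- function(m) {
    mh <- numeric(replicates)
    for (r in seq_len(replicates)) {
      risk <- sample.int(length(genes), m, prob = w)
      cnt <- stats::rpois(length(genes), gene_lambda)
      extra <- stats::rmultinom(1L, n_excess, w[risk])[, 1L]
      cnt[risk] <- cnt[risk] + extra
      mh[r] <- sum(cnt >= 2L)
    }
    mean(mh)
  }
  e_multi <- vapply(m_grid, sim_multi, numeric(1L))
  loglik <- stats::dpois(multi, pmax(e_multi, 1e-12), log = TRUE)
  estimate <- m_grid[which.max(loglik)]
  keep <- loglik >= max(loglik) - stats::qchisq(0.95, 1) / 2
  interval <- range(m_grid[keep])

  sat <- vapply(future_sizes, function(s) {
    scale <- s / n_trios
    det <- numeric(replicates)
    for (r in seq_len(replicates)) {
      risk <- sample.int(length(genes), estimate, prob = w)
      cnt <- stats::rpois(estimate, gene_lambda[risk] * scale) +
        stats::rmultinom(1L, stats::rpois(1L, n_excess * scale),
                         w[risk])[, 1L]
      det[r] <- mean(cnt >= hits_required)
    }
    mean(det)
  }, numeric(1L))
  list(estimate = estimate, interval = interval, excess = excess,
       multi_hit = multi,
       saturation = data.frame(size = future_sizes, saturation = sat),
       replicates = replicates, seed = seed)
}
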