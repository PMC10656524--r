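.pli_breaks <- c(6.4e-8, 1.9e-3, 0.48)

#' Stratify genes by pLI for the transmitted-variant expectation
#'
#' Genes are partitioned into five strata by published pLI boundaries:
#' pLI < 6.4e-8; [6.4e-8, 1.9e-3); [1.9e-3, 0.48); [0.48, 1.0]; and genes
#' without a pLI score. Boundary values are assigned upward (inclusive lower
#' bounds).
#'
#' @param gene_models data.frame with `gene_id` and `pLI` (NA allowed).
#' @return integer vector of stratum indices 1-5, named by gene.
#' @export
assign_strata <- function(gene_models) {
  pli <- gene_models$pLI
  if (any(!is.na(pli) & (pli < 0 | pli > 1))) stop("pLI outside [0, 1]")
  k <- ifelse(is.na(pli), 5L,
       ifelse(pli < .pli_breaks[1L], 1L,
       ifelse(pli < .pli_breaks[2L], 2L,
       ifelse(pli < .pli_breaks[3L], 3L, 4L))))
  stats::setNames(as.integer(k), gene_models$gene_id)
}

#' Expected rare transmitted variants per gene within a stratum
#'
#' Within stratum k holding L_k rare damaging (or LoF) heterozygous variants
#' in total, the expectation for gene j is L_k x mutability_j divided by the
#' summed mutability of the stratum. The expectations conserve the stratum
#' total exactly. Genes with zero mutability are excluded and reported.
#'
#' @param mutability named numeric vector of per-gene damaging mutabilities
#'   for the genes of one stratum.
#' @param L_k total observed variant count in the stratum (0 allowed).
#' @return named numeric vector of expected counts; attribute
#'   `zero_mutability` lists excluded genes.
#' @export
expected_transmitted <- function(mutability, L_k) {
  if (L_k < 0) stop("L_k must be >= 0")
  zero <- names(mutability)[mutability <= 0]
  mu <- mutability[mutability > 0]
  exp_j <- if (L_k == 0 || !length(mu))
    stats::setNames(rep(0, length(mu)), names(mu))
  else L_k * mu / sum(mu)
  structure(exp_j, zero_mutability = zero)
}

#' One-sided binomial test of per-gene transmitted burden
#'
#' Observed counts are compared with Binomial(n = L_k, p = mutability share
#' of the gene within its stratum), whose mean equals the stratum
#' expectation formula exactly; the test is upper-tailed. The genome-wide
#' threshold is `alpha / n_genes`.
#'
#' @param observed named integer vector: observed qualifying variant count
#'   per gene (de novo damaging variants included, per the study's counting).
#' @param mutability named numeric damaging mutability for the same stratum.
#' @param L_k stratum variant total; every observed count must be <= L_k.
#' @param n_genes total genes for the Bonferroni threshold.
#' @param alpha family-wise error target.
#' @return data.frame: gene, observed, expected, enrichment, p, significant;
#'   attribute `threshold`.
#' @export
per_gene_binomial_test <- function(observed, mutability, L_k,
                                   n_genes = 19347, alpha = 0.05) {
  if (any(observed > L_k)) stop("observed exceeds the stratum total L_k")
  threshold <- alpha / n_genes
  exp_j <- expected_transmitted(mutability, L_k)
  genes <- names(exp_j)
  obs <- stats::setNames(rep(0, length(genes)), genes)
  hit <- intersect(names(observed), genes)
  obs[hit] <- observed[hit]
  share <- if (L_k > 0) exp_j / L_k else
    mutability[genes] / sum(mutability[genes])
  p <- stats::pbinom(obs - 1, size = L_k, prob = share, lower.tail = FALSE)
  res <- data.frame(gene = genes, observed = unname(obs),
                    expected = unname(exp_j),
                    enrichment = unname(ifelse(exp_j > 0, obs / exp_j, NA_real_)),
                    p = unname(p), significant = unname(p <= threshold),
                    stringsAsFactors = FALSE)
  attr(res, "threshold") <- threshold
  res
}

#' Case-control burden by one-sided Fisher's exact test
#'
#' Compares case versus control alternative-allele counts in a 2x2 table
#' (alt alleles vs reference alleles). The p-value is the exact
#' hypergeometric upper tail (alternative "greater"); the odds ratio is the
#' sample odds ratio; the one-sided 95% interval is (exact conditional lower
#' bound, Inf).
#'
#' @param case_ac,case_an case alternative-allele count and allele number.
#' @param ctrl_ac,ctrl_an control alternative-allele count and allele number.
#' @param conf if FALSE, skip the confidence bound (fast path for sweeps).
#' @param conf_level confidence level of the one-sided interval.
#' @return data.frame: counts, `or` (sample odds ratio, NA when undefined),
#'   `ci_lower`, `p`.
#' @export
fisher_burden <- function(case_ac, case_an, ctrl_ac, ctrl_an,
                          conf = TRUE, conf_level = 0.95) {
  if (any(case_ac > case_an) || any(ctrl_ac > ctrl_an))
    stop("allele count exceeds allele number")
  a <- case_ac; b <- case_an - case_ac
  c_ <- ctrl_ac; d <- ctrl_an - ctrl_ac
  m <- a + c_                      # total alt alleles
  degenerate <- case_an == 0 | ctrl_an == 0 | m == 0 | (b + d) == 0
  # P(X >= a) for X ~ Hypergeom drawing case_an from m alt, b+d ref alleles
  p <- ifelse(degenerate, 1,
              stats::phyper(a - 1, m, b + d, case_an, lower.tail = FALSE))
  or <- ifelse(a == 0, 0, ifelse(b == 0 | c_ == 0, Inf, (a * d) / (b * c_)))
  or[degenerate] <- NA_real_
  ci_lower <- rep(NA_real_, length(a))
  if (conf) {
    for (i in which(!degenerate)) {
      ft <- stats::fisher.test(matrix(c(a[i], c_[i], b[i], d[i]), 2L),
                               alternative = "greater",
                               conf.level = conf_level)
      ci_lower[i] <- ft$conf.int[1L]
    }
  }
  data.frame(case_ac = case_ac, case_an = case_an, ctrl_ac = ctrl_ac,
             ctrl_an = ctrl_an, or = or, ci_lower = ci_lower, p = p,
             or_undefined = degenerate)
}

#' Full stratified transmitted enrichment analysis
#'
#' Assigns strata, tallies the stratum totals L_k from the observed variant
#' genes, and runs the per-gene binomial test within each stratum.
#'
#' @param observed named integer vector of qualifying variant counts per gene.
#' @param gene_models data.frame with `gene_id`, `pLI` and mutability inputs.
#' @param mutability named damaging mutability per gene (see
#'   [damaging_mutability()]).
#' @param n_genes Bonferroni divisor (defaults to number of modeled genes).
#' @return data.frame over all genes with a `stratum` column; attribute
#'   `L_k` holds the stratum totals.
#' @export
transmitted_enrichment <- function(observed, gene_models, mutability,
                                   n_genes = nrow(gene_models)) {
  strata <- assign_strata(gene_models)
  obs <- stats::setNames(rep(0, nrow(gene_models)), gene_models$gene_id)
  hit <- intersect(names(observed), names(obs))
  obs[hit] <- observed[hit]
  L_k <- tapply(obs, strata[names(obs)], sum)
  out <- list()
  for (k in sort(unique(strata))) {
    g <- names(strata)[strata == k]
    lk <- if (as.character(k) %in% names(L_k)) L_k[[as.character(k)]] else 0
    r <- per_gene_binomial_test(obs[g], mutability[g], lk, n_genes = n_genes)
    r$stratum <- k
    out[[as.character(k)]] <- r
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "L_k") <- L_k
  res
}
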