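---
title: "Mutability-based rare-variant enrichment in trio exome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutability-based rare-variant enrichment in trio exome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioburden)
```

## The problem

Severe, sporadic congenital malformations — here the motivating case is
vein of Galen malformation, an arteriovenous malformation of the neonatal
brain — are poorly served by linkage or association designs. The standard
gene-discovery strategy is to exome-sequence proband–parent trios and ask
whether any gene accumulates more rare, damaging variants than chance
allows. "Chance" must be modeled carefully: genes differ enormously in
size, sequence context and coverage, so the null expectation has to be
built per gene. `trioburden` implements that machinery end to end: a
trinucleotide-context de novo expectation model, the variant filter
cascades and kinship QC of a trio study, one-sided Poisson and binomial
burden tests, attributable-fraction and gene-discovery saturation
estimation, case-control Fisher burden, and covariate-adjusted gene-set
enrichment — plus a fully synthetic cohort generator so every stage can be
exercised and validated without access to patient data.

## The de novo expectation model

For every base of the captured coding sequence, the probability that it
mutates to each alternative base in one generation is read from a 192-entry
table indexed by the trinucleotide context (64 contexts × 3 alternative
middle bases). Each possible substitution is classified by its coding
consequence — synonymous, missense, canonical splice (the ±2 intronic bases
at each internal exon boundary), stop-gain, stop-loss, start-loss — and the
per-substitution probabilities are summed per gene and class:

$$p_{g,c} \;=\; d_g \sum_{i \in \text{captured}(g)} \;\sum_{b \neq
\text{ref}_i} r(\text{ctx}_i, b)\; \mathbf{1}\{\text{class}(i,b)=c\}$$

where $d_g \in [0,1]$ is a per-gene sequencing-depth multiplier. Indels
cannot be modeled from substitution rates; following the model this package
re-implements, the frameshift probability is fixed at 1.25 × the stop-gain
probability, and in-frame indels are not modeled at all. The expected
number of de novo events of class $c$ in a cohort of $N$ trios is
$2 N p_{g,c}$ (two haploid genomes per proband).

Three modeling choices were genuinely open and are resolved as follows:

* **Depth adjustment.** No formula is published for the depth adjustment,
  only that one was applied; the published coverage QC statistic is the
  fraction of targeted bases with ≥ 8 independent reads. We therefore take
  $d_g$ = the fraction of the gene's captured coding bases attaining ≥ K
  reads in ≥ F of samples (defaults K = 8, F = 0.9), supplied as a per-gene
  summary table, with $d_g = 1$ when no summary is given.
* **Damaging missense.** The context model cannot know which individual
  missense changes MetaSVM or MPC would call damaging, so a per-gene
  `dmis_fraction` (default 0.30, an input column) partitions the missense
  probability mass into damaging and tolerated parts.
* **Splice model.** Canonical ±2 intronic positions only, with rates taken
  from the same context table; no splicing-strength score. CpG methylation
  tiers are not modeled — the 192-entry table is the interface, and a
  methylation-aware model can be supplied as alternative tables.

## Filter cascades

Three record-level cascades reproduce the published criteria, each
returning a verdict plus the first failing rule (the rules are conjunctive,
so the verdict itself is order-independent):

* **De novo**: exonic/splice class; DP ≥ 10 in all trio members; proband
  alternative reads ≥ 5; proband allele ratio ≥ 0.28 below 10 alternative
  reads, else ≥ 0.20; parental allele ratio ≤ 3.5%; reference-population
  MAF ≤ 4×10⁻⁴. When no external de novo caller output is available the
  pre-screen is the naive Mendelian one (proband het, parents
  homozygous-reference).
* **Transmitted dominant**: VQSR pass, reference MAF ≤ 5×10⁻⁵, in-cohort
  MAF ≤ 5×10⁻³, proband DP ≥ 8, GQ ≥ 20, class LoF or damaging missense
  (MetaSVM D or MPC ≥ 2).
* **Recessive**: homozygotes and parent-phased compound heterozygotes (one
  allele from each parent), reference MAF ≤ 10⁻³, in-cohort MAF ≤ 10⁻²,
  VQSR pass, DP ≥ 8, GQ ≥ 20; probands without parental data contribute
  homozygotes only.

All printed thresholds are inclusive exactly as printed, and every one is a
configuration key, so a typo in an override is an error rather than a
silently ignored setting. The in-cohort allele frequency is computed over
founders only (parents plus singleton probands, duplicates excluded) to
avoid proband-enrichment bias. Missing FORMAT values propagate as missing
and fail a dedicated `missing_support` rule — never silently as zero. One
published step is not implementable: removal of false positives by manual
in-silico visualization; it is simply absent.

Kinship QC uses two statistics: a Jaccard sharing fraction over
rare-variant carrier sets (pairs ≥ 0.80 are duplicates; the higher-coverage
sample is retained) and an IBD proxy at common biallelic sites — a robust
method-of-moments kinship estimate from het–het sharing and opposite
homozygotes, scaled so parent–offspring pairs expect ≈ 0.5 — flagged
outside [0.45, 0.55]. The proxy reproduces the published acceptance band on
simulated trios; it is not PLINK's pi-hat.

## Burden statistics

Cohort-level and per-gene de novo tests are one-sided Poisson upper tails
at the model expectation, computed exactly (`ppois`, no normal
approximation); the per-gene threshold is $0.05/(3 \times
n_\text{genes})$ because three class families are tested (protein-altering,
protein-damaging, LoF). The attributable fraction is the excess of observed
over expected damaging DNVs divided by the number of probands, with an
exact Poisson interval on the observed count propagated to the fraction
scale.

For rare transmitted heterozygotes the expectation is stratified: genes are
split into five strata at the published pLI boundaries (6.4×10⁻⁸, 1.9×10⁻³,
0.48, plus a missing-pLI stratum; boundary values assigned upward), and
within stratum $k$ holding $L_k$ observed variants gene $j$ expects
$L_k \cdot \mu_j / \sum_{k} \mu_j$ — conserving $\sum_j E_j = L_k$ exactly.
The per-gene test is the one-sided Binomial($n = L_k$, $p$ = mutability
share), the only reading under which the test's mean equals the published
expectation formula; $\mu_j$ defaults to the damaging mutability (LoF
classes + `dmis_fraction` × missense), switchable to LoF-only. Case-control
burden is the one-sided hypergeometric (Fisher) tail on allele counts, with
the sample odds ratio and an exact conditional one-sided lower confidence
bound (upper bound unbounded, matching the published convention).

The risk-gene count estimator re-creates a Monte Carlo approach whose
details live outside the main text of the source study: the number of
contributing genes $M$ is fit by maximum likelihood to the observed count
of multi-hit genes, simulating excess damaging DNVs scattered over $M$
mutability-weighted risk genes on top of Poisson background, with a
profile-likelihood interval; saturation at a future cohort size is the
expected fraction of risk genes attaining ≥ 1 (configurable ≥ 2) damaging
hit when all rates scale with cohort size. With ~11 excess DNVs and a
single multi-hit gene the likelihood is extremely flat, so the interval is
honest but wide; the published point estimates of saturation at specific
future sizes depend on unpublished parameters and are treated as
qualitative context only.

## Gene-set enrichment

Enrichment of disease gene lists in co-expression modules or cell-type
marker sets is an indicator logistic regression with gene covariates (GC
fraction raw; gene length and mean expression log10-transformed, then
z-scored — the transform choice is ours and is recorded here). The two
published analyses orient the model differently (`is.disease ~ is.module +
covariates` for modules; `is.cell.type ~ is.disease + covariates` for cell
types); both orientations are implemented and the choice is explicit per
call — no attempt is made to reconcile them. The unassigned ("gray")
module is excluded from testing and its exclusive genes leave the
background, yet the Bonferroni divisor remains the full module count
(88 → α = 5.68×10⁻⁴), matching the published convention. Complete
separation is detected and is an explicit error unless the Firth-penalized
fallback is enabled, in which case the fit is flagged. The Firth fit is a
standard hat-value-adjusted IRLS written in the package.

## The synthetic cohort generator

`cohort_spec()` defaults encode the study conditions at desk scale: 90
trios, 13 duos, 11 singletons over 2,000 genes, with context rates scaled
so the expected cohort-wide DNV count is ~100 (the study observed 107 over
19,347 genes; 2,000 genes keep per-gene expectations on the study's scale
while staying tractable). Genes are random ORFs over 1–3 exons with short
introns, log-normal coding length (the main driver of mutability
dispersion), CpG-elevated strand-symmetric context rates, bimodal
gnomAD-like pLI with an 8% missing fraction. De novo counts follow the
Poisson process implied by the model's own mutabilities (fold-enriched in
spiked risk genes, with the risk gene chosen so the target attributable
fraction is realized); transmitted damaging heterozygotes are multinomial
over damaging mutability within pLI strata with fixed totals $L_k$
(defaults 200/250/250/200/100); true-het allele balance is Beta(20, 20)
(centred at 0.5) and homozygous-reference error alleles arise at rate
0.005, so unplanted records pass the filters and planted violations are
the only failures. Every planted record — filter violations with their
rule ids, duplicate samples, risk genes with folds, the realized
attributable fraction — is written to a ground-truth JSON.

What the generator does *not* emulate: real human sequence, linkage
disequilibrium, population structure, batch effects, caller artifacts
beyond the simple error model, or indel alignment ambiguity. Passing tests
on synthetic data therefore validate the statistical machinery and the
filter contracts, not robustness to real-data messiness. One scale caveat:
with only a handful of families (the unit-test fixture has five), any
variant carried by a single founder already exceeds the 5×10⁻³ in-cohort
MAF cap, so the transmitted cascade only behaves meaningfully at realistic
founder counts — the fixture plants its transmitted-rule violations on
proband-only records for that reason.

## Numerical and reproducibility choices

* All tail probabilities are exact (`ppois`, `pbinom`, `phyper`); tests
  verify agreement with brute-force enumeration to 1×10⁻¹² over the
  relevant ranges.
* Coordinates are 0-based half-open internally; VCF (1-based) and BED
  (0-based) are converted at the I/O boundary. Indels are normalized by
  suffix-then-prefix trimming before family matching.
* Randomness flows from a single mandatory seed through named substreams
  (rates, genes, pLI, DNVs, transmitted, plants, duplicates …), so adding a
  stage never perturbs earlier draws and regeneration is byte-identical.
* Published statistics are reconstructed from printed inputs; because
  printed expectations are themselves rounded, reconstruction compares
  against the full interval attainable within half a printing unit (both
  the fold and the Poisson tail are monotone in the expectation, so the
  interval endpoints suffice). Under that criterion every cell of the
  published class-level table reconstructs except five cells of the
  control cohort's constrained-gene block, whose printed values cannot
  arise from their printed inputs under any rounding; these are reported
  as discrepancies rather than forced.
* Problem sizes used by the validation suite: the null-calibration study
  runs 500 replicate cohorts of 2,000 genes × 90 trios at the count level;
  the recovery study runs 200 replicates with one fold-2,000 risk gene at a
  12% target attributable fraction; the enumeration sweeps cover all 2×2
  tables with total ≤ 60 and Poisson expectations ≤ 50 with observations
  ≤ 200. Count-level simulation (drawing per-gene event counts directly
  from the generative process) is used for replicate studies; full
  VCF-level simulation is exercised end to end on the desk-scale cohort in
  `analysis/`.

## Known limitations

* The frameshift rate is a fixed multiple of stop-gain, inherited from the
  published model; it cannot capture gene-specific indel propensity.
* `dmis_fraction` is a single per-gene number; a per-substitution
  deleteriousness annotation would be strictly better and can be supplied
  upstream.
* The IBD proxy is a screening statistic, not a genotype-likelihood
  kinship estimate; it is only validated against the published acceptance
  band.
* The risk-gene/saturation estimator is a documented re-creation; with the
  study-scale excess (~11 DNVs) its interval is necessarily wide, and the
  published saturation percentages are not reproduced quantitatively.
* Module assignments, cell-type markers and deleteriousness scores are
  inputs; the package does not construct co-expression networks or query
  annotation services.
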