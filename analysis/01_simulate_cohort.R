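#!/usr/bin/env Rscript
# Stage 1: build the synthetic study — a 2,000-gene universe and a cohort of
# 90 trios, 13 duos and 11 singletons whose DNV process matches the study
# scale (~100 expected DNVs), with one spiked risk gene at fold 2,000 chosen
# so damaging DNVs explain ~12% of probands, planted filter violations and
# one duplicate sample. Writes VCF/PED/BED/TSV/JSON under results/cohort/.

suppressMessages(library(trioburden))

spec <- cohort_spec(
  seed = 20240601,
  n_risk_genes = 1, risk_fold = 2000, target_af = 0.12,
  plant_dnv = c(class = 2L, depth = 2L, alt_reads = 2L, alt_ratio = 2L,
                parent_ratio = 2L, maf = 2L, missing_support = 2L),
  plant_transmitted = c(vqsr = 2L, maf_ref = 2L, maf_cohort = 2L,
                        depth = 2L, gq = 2L, class = 2L,
                        missing_support = 2L),
  n_duplicate_pairs = 2)

message("simulating gene universe (", spec$n_genes, " genes) ...")
universe <- simulate_gene_universe(spec)
g <- universe$genes
total_expected <- sum(expected_dnv_count(
  g$p_synonymous + g$p_missense + g$p_stopgain + g$p_stoploss +
    g$p_startloss + g$p_splice_canonical + g$p_frameshift, spec$n_trios))
cat(sprintf("expected DNVs per cohort: %.1f (damaging: %.1f)\n",
            total_expected, sum(expected_dnv_count(g$p_damaging,
                                                   spec$n_trios))))

message("simulating cohort ...")
cohort <- simulate_cohort(spec, universe, dir = "results/cohort")
write_universe(universe, "results/cohort")
cat(sprintf("emitted %d variant sites over %d samples\n",
            nrow(cohort$variants), length(cohort$samples)))
cat(sprintf("risk gene %s at fold %.0f; realized attributable fraction %.3f\n",
            cohort$truth$risk_genes$gene, cohort$truth$risk_genes$fold,
            cohort$truth$true_af))
cat(sprintf("planted %d filter violations, %d duplicate pair(s)\n",
            length(cohort$truth$plants), length(cohort$truth$duplicates)))
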