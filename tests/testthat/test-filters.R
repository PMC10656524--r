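mk_call <- function(class = "missense", metasvm = "D", mpc = 3,
                    maf_gnomad = 0, maf_bravo = 0, vqsr_pass = TRUE,
                    pro_gt = "0/1", pro_dp = 17, pro_ad_alt = 8, pro_gq = 99,
                    fa_gt = "0/0", fa_dp = 20, fa_ad_alt = 0, fa_gq = 99,
                    mo_gt = "0/0", mo_dp = 20, mo_ad_alt = 0, mo_gq = 99,
                    family_type = "trio", chrom = "g", pos = 1, ref = "A",
                    alt = "G", gene = "g", family_id = "F") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             class = class, metasvm = metasvm, mpc = mpc,
             maf_gnomad = maf_gnomad, maf_bravo = maf_bravo,
             vqsr_pass = vqsr_pass, family_id = family_id,
             family_type = family_type,
             pro_gt = pro_gt, pro_dp = pro_dp, pro_ad_alt = pro_ad_alt,
             pro_gq = pro_gq, fa_gt = fa_gt, fa_dp = fa_dp,
             fa_ad_alt = fa_ad_alt, fa_gq = fa_gq, mo_gt = mo_gt,
             mo_dp = mo_dp, mo_ad_alt = mo_ad_alt, mo_gq = mo_gq,
             stringsAsFactors = FALSE)
}

test_that("DNV cascade applies the published thresholds", {
  v <- dnv_filter(mk_call())          # DP 17, AD 8 (0.47), clean parents
  expect_true(v$passed)
  # ratio 0.25 with < 10 alt reads: the 0.28 branch applies
  v2 <- dnv_filter(mk_call(pro_dp = 32, pro_ad_alt = 8))
  expect_false(v2$passed)
  expect_equal(v2$failed_rule, "alt_ratio")
  # the same ratio with >= 10 alt reads passes via the 0.20 branch
  v2b <- dnv_filter(mk_call(pro_dp = 48, pro_ad_alt = 12))
  expect_true(v2b$passed)
  # parent alt ratio above 3.5%
  v3 <- dnv_filter(mk_call(fa_dp = 50, fa_ad_alt = 2))
  expect_false(v3$passed)
  expect_equal(v3$failed_rule, "parent_ratio")
  # boundary is inclusive exactly as printed
  v3b <- dnv_filter(mk_call(fa_dp = 40, fa_ad_alt = 1.4))
  expect_true(v3b$passed)
  # population frequency, low depth, low alt reads, non-exonic class
  expect_equal(dnv_filter(mk_call(maf_gnomad = 1e-3))$failed_rule, "maf")
  expect_equal(dnv_filter(mk_call(mo_dp = 9, mo_ad_alt = 0))$failed_rule,
               "depth")
  expect_equal(dnv_filter(mk_call(pro_ad_alt = 3))$failed_rule, "alt_reads")
  expect_equal(dnv_filter(mk_call(class = "other"))$failed_rule, "class")
  # missing read support in any member
  expect_equal(dnv_filter(mk_call(fa_dp = NA, fa_ad_alt = NA))$failed_rule,
               "missing_support")
})

test_that("transmitted cascade keeps rare damaging variants only", {
  caf <- 0
  v <- transmitted_filter(mk_call(maf_bravo = 1.48e-5, pro_dp = 30), caf)
  expect_true(v$passed)
  # tolerated missense fails the class rule
  v2 <- transmitted_filter(mk_call(metasvm = "T", mpc = 1.0), caf)
  expect_false(v2$passed)
  expect_equal(v2$failed_rule, "class")
  # MPC >= 2 rescues a MetaSVM-tolerated missense
  expect_true(transmitted_filter(mk_call(metasvm = "T", mpc = 2.0), caf)$passed)
  # in-cohort frequency cap
  v3 <- transmitted_filter(mk_call(), in_cohort_af = 0.01)
  expect_equal(v3$failed_rule, "maf_cohort")
  expect_equal(transmitted_filter(mk_call(maf_bravo = 1e-4), caf)$failed_rule,
               "maf_ref")
  expect_equal(transmitted_filter(mk_call(vqsr_pass = FALSE), caf)$failed_rule,
               "vqsr")
  expect_equal(transmitted_filter(mk_call(pro_gq = NA), caf)$failed_rule,
               "missing_support")
  expect_equal(transmitted_filter(mk_call(pro_gq = 15), caf)$failed_rule, "gq")
  expect_equal(transmitted_filter(mk_call(pro_dp = 5), caf)$failed_rule,
               "depth")
})

test_that("the verdict is order-independent: pass iff every rule holds", {
  set.seed(61)
  for (i in 1:200) {
    call <- mk_call(pro_dp = sample(5:40, 1), pro_ad_alt = sample(0:12, 1),
                    fa_dp = sample(5:40, 1), fa_ad_alt = sample(0:3, 1),
                    mo_dp = sample(5:40, 1), mo_ad_alt = sample(0:3, 1),
                    maf_gnomad = sample(c(0, 1e-5, 1e-3), 1),
                    class = sample(c("missense", "synonymous", "other"), 1))
    call$pro_ad_alt <- min(call$pro_ad_alt, call$pro_dp)
    v <- dnv_filter(call)
    th <- filter_defaults()
    manual <- call$class %in% c("missense", "synonymous") &&
      all(c(call$pro_dp, call$fa_dp, call$mo_dp) >= 10) &&
      call$pro_ad_alt >= 5 &&
      call$pro_ad_alt / call$pro_dp >=
        (if (call$pro_ad_alt < 10) 0.28 else 0.20) &&
      call$fa_ad_alt / call$fa_dp <= 0.035 &&
      call$mo_ad_alt / call$mo_dp <= 0.035 &&
      call$maf_gnomad <= 4e-4
    expect_equal(v$passed, manual)
  }
})

test_that("tightening thresholds never converts a fail into a pass", {
  set.seed(62)
  th0 <- filter_defaults()
  th1 <- th0
  th1$dnv_min_dp <- 12; th1$dnv_min_alt_reads <- 6
  th1$dnv_parent_ratio_max <- 0.02; th1$dnv_maf_max <- 1e-4
  th1$dnv_ratio_low <- 0.35; th1$dnv_ratio_high <- 0.25
  for (i in 1:200) {
    call <- mk_call(pro_dp = sample(8:40, 1), pro_ad_alt = sample(3:12, 1),
                    fa_dp = sample(8:40, 1), fa_ad_alt = sample(0:2, 1),
                    maf_gnomad = sample(c(0, 5e-5, 2e-4), 1))
    call$pro_ad_alt <- min(call$pro_ad_alt, call$pro_dp)
    loose <- dnv_filter(call, thresholds = th0)$passed
    tight <- dnv_filter(call, thresholds = th1)$passed
    expect_false(!loose && tight)
  }
})

test_that("recessive configurations respect parental phase", {
  caf <- stats::setNames(numeric(0), character(0))
  # two hets, one inherited from each parent: compound het
  a <- mk_call(pos = 1, gene = "G1")
  b <- mk_call(pos = 2, gene = "G1", fa_gt = "0/0", mo_gt = "0/1",
               mo_ad_alt = 10)
  a$fa_gt <- "0/1"; a$fa_ad_alt <- 10
  r <- recessive_filter(rbind(a, b), caf)
  expect_equal(nrow(r), 1L)
  expect_equal(r$config, "comphet")
  # both hets from the mother: cis, no configuration
  a2 <- a; a2$fa_gt <- "0/0"; a2$mo_gt <- "0/1"
  expect_equal(nrow(recessive_filter(rbind(a2, b), caf)), 0L)
  # homozygote passes; singleton proband: homozygous only
  hom <- mk_call(pro_gt = "1/1", pro_ad_alt = 17, family_type = "singleton",
                 fa_gt = NA, fa_dp = NA, fa_ad_alt = NA, mo_gt = NA,
                 mo_dp = NA, mo_ad_alt = NA)
  r2 <- recessive_filter(hom, caf)
  expect_equal(r2$config, "hom")
  het_pair <- rbind(mk_call(pos = 1, family_type = "singleton"),
                    mk_call(pos = 2, family_type = "singleton"))
  expect_equal(nrow(recessive_filter(het_pair, caf)), 0L)
  # recessive frequency cap is looser than the dominant one
  hom_maf <- mk_call(pro_gt = "1/1", pro_ad_alt = 17, maf_bravo = 5e-4)
  expect_equal(recessive_filter(hom_maf, caf)$config, "hom")
})

sim_genotypes <- function(n_sites, freqs, pair = c("parent_offspring",
                                                   "unrelated", "duplicate")) {
  pair <- match.arg(pair)
  draw <- function() stats::rbinom(n_sites, 1, freqs) +
    stats::rbinom(n_sites, 1, freqs)
  g1 <- draw()
  g2 <- switch(pair,
    unrelated = draw(),
    duplicate = g1,
    parent_offspring = {
      from_p <- stats::rbinom(n_sites, 1, g1 / 2)
      from_pop <- stats::rbinom(n_sites, 1, freqs)
      from_p + from_pop
    })
  cbind(s1 = g1, s2 = g2)
}

test_that("the IBD proxy lands near 0.5 for parent-offspring pairs", {
  set.seed(63)
  freqs <- stats::runif(3000, 0.1, 0.5)
  ped <- read_pedigree(write_lines_tmp(c("T1 s2 s1 0 1 2",
                                         "T1 s1 0 0 1 1")))
  g <- sim_genotypes(3000, freqs, "parent_offspring")
  kin <- duplicate_and_kinship(g, ped, ref_maf = freqs)
  expect_gt(kin$ibd$ibd_proxy[1], 0.45)
  expect_lt(kin$ibd$ibd_proxy[1], 0.55)
  expect_false(kin$ibd$flagged[1])
  # unrelated pair is flagged when cast as parent-offspring
  g2 <- sim_genotypes(3000, freqs, "unrelated")
  kin2 <- duplicate_and_kinship(g2, ped, ref_maf = freqs)
  expect_lt(abs(kin2$ibd$ibd_proxy[1]), 0.2)
  expect_true(kin2$ibd$flagged[1])
})

test_that("duplicate pairs are detected by rare-variant sharing", {
  set.seed(64)
  n <- 500
  freqs <- rep(1e-4, n)   # all rare
  g <- matrix(0L, n, 3, dimnames = list(NULL, c("a", "b", "c")))
  g[1:60, "a"] <- 1L
  g[c(1:57, 61:63), "b"] <- 1L       # near-copy of a
  g[101:160, "c"] <- 1L              # disjoint carrier set
  ped <- read_pedigree(write_lines_tmp(c("F1 a 0 0 1 2", "F2 b 0 0 1 2",
                                         "F3 c 0 0 1 2")))
  kin <- duplicate_and_kinship(g, ped, ref_maf = freqs,
                               mean_depth = c(a = 40, b = 20, c = 40))
  expect_equal(nrow(kin$duplicates), 1L)
  expect_setequal(unlist(kin$duplicates[, c("sample1", "sample2")]),
                  c("a", "b"))
  expect_equal(kin$duplicates$retained, "a")   # higher coverage retained
  expect_equal(kin$sharing["a", "a"], 1)
  expect_lt(kin$sharing["a", "c"], 0.8)
  # a sample with no rare variants has undefined sharing and is reported
  g2 <- cbind(g, d = 0L)
  ped2 <- read_pedigree(write_lines_tmp(c("F1 a 0 0 1 2", "F2 b 0 0 1 2",
                                          "F3 c 0 0 1 2", "F4 d 0 0 1 2")))
  kin2 <- duplicate_and_kinship(g2, ped2, ref_maf = freqs)
  expect_equal(kin2$no_rare, "d")
})
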