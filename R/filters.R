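.lof_classes <- c("stopgain", "stoploss", "frameshift", "splice_canonical",
                  "startloss")
.exonic_classes <- c(.lof_classes, "synonymous", "missense", "inframe_indel")

#' Damaging-class resolution
#'
#' LoF classes are always damaging; missense is damaging (D-mis) when
#' MetaSVM calls it deleterious or MPC >= 2.
#'
#' @param class functional class vector.
#' @param metasvm MetaSVM label vector ("D", "T" or NA).
#' @param mpc MPC score vector (NA allowed).
#' @return logical vector.
#' @export
is_damaging <- function(class, metasvm = NULL, mpc = NULL) {
  dmis <- class == "missense" &
    ((!is.null(metasvm) & !is.na(metasvm) & metasvm == "D") |
       (!is.null(mpc) & !is.na(mpc) & mpc >= 2))
  class %in% .lof_classes | (!is.na(dmis) & dmis)
}

#' Default filter thresholds
#'
#' Every threshold of the de novo, transmitted and recessive cascades, at
#' the study's published values. Inclusive comparisons exactly as printed.
#'
#' @return named list of thresholds.
#' @export
filter_defaults <- function() {
  list(
    dnv_min_dp = 10, dnv_min_alt_reads = 5,
    dnv_ratio_low = 0.28, dnv_ratio_high = 0.20, dnv_ratio_switch = 10,
    dnv_parent_ratio_max = 0.035, dnv_maf_max = 4e-4,
    trans_maf_max = 5e-5, trans_cohort_maf_max = 5e-3,
    trans_min_dp = 8, trans_min_gq = 20,
    rec_maf_max = 1e-3, rec_cohort_maf_max = 1e-2,
    rec_min_dp = 8, rec_min_gq = 20,
    dup_sharing_min = 0.80, ibd_band = c(0.45, 0.55),
    rare_maf_max = 1e-3, common_maf_min = 0.05
  )
}

# first failing rule in documented order; verdict itself is order-independent
# because the rules are conjunctive
.verdict <- function(rules) {
  passed <- Reduce(`&`, lapply(rules, function(r) !is.na(r) & r))
  failed <- rep(NA_character_, length(passed))
  for (nm in rev(names(rules))) {
    r <- rules[[nm]]
    failed[is.na(r) | !r] <- nm
  }
  list(passed = passed, failed_rule = failed)
}

#' Naive Mendelian de novo pre-screen
#'
#' When no external de novo caller output is supplied, candidate DNVs are
#' proband-heterozygous sites with both parents homozygous reference, in
#' complete trios.
#'
#' @param calls data.frame from [read_variants()].
#' @return logical vector marking candidates.
#' @export
dnv_candidates <- function(calls) {
  calls$family_type == "trio" &
    !is.na(calls$pro_gt) & calls$pro_gt == "0/1" &
    !is.na(calls$fa_gt) & calls$fa_gt == "0/0" &
    !is.na(calls$mo_gt) & calls$mo_gt == "0/0"
}

#' De novo variant filter cascade
#'
#' Applies the published DNV criteria to candidate calls in complete trios:
#' (class) exonic or splice-site consequence; (depth) DP >= 10 in proband
#' and both parents; (alt_reads) proband alternative reads >= 5;
#' (alt_ratio) proband alternative allele ratio >= 0.28 when carrying < 10
#' alternative reads, else >= 0.20; (parent_ratio) alternative ratio <= 3.5%
#' in both parents; (maf) population MAF <= 4e-4 in the designated reference
#' column. Missing read support in any trio member fails as
#' `missing_support`. A frequency absent from the reference database is
#' treated as 0.
#'
#' @param calls data.frame from [read_variants()] (candidate DNVs).
#' @param maf_column name of the reference-population frequency column.
#' @param thresholds list from [filter_defaults()].
#' @return data.frame with `passed`, `failed_rule` and the computed metric
#'   columns (`pro_ratio`, `fa_ratio`, `mo_ratio`, `maf`).
#' @export
dnv_filter <- function(calls, maf_column = "maf_gnomad",
                       thresholds = filter_defaults()) {
  th <- thresholds
  pro_ratio <- calls$pro_ad_alt / calls$pro_dp
  fa_ratio <- calls$fa_ad_alt / calls$fa_dp
  mo_ratio <- calls$mo_ad_alt / calls$mo_dp
  maf <- calls[[maf_column]]
  maf[is.na(maf)] <- 0
  support_ok <- !is.na(calls$pro_dp) & !is.na(calls$pro_ad_alt) &
    !is.na(calls$fa_dp) & !is.na(calls$fa_ad_alt) &
    !is.na(calls$mo_dp) & !is.na(calls$mo_ad_alt)
  ratio_needed <- ifelse(!is.na(calls$pro_ad_alt) &
                           calls$pro_ad_alt < th$dnv_ratio_switch,
                         th$dnv_ratio_low, th$dnv_ratio_high)
  rules <- list(
    missing_support = support_ok,
    class = !is.na(calls$class) & calls$class %in% .exonic_classes,
    depth = calls$pro_dp >= th$dnv_min_dp & calls$fa_dp >= th$dnv_min_dp &
      calls$mo_dp >= th$dnv_min_dp,
    alt_reads = calls$pro_ad_alt >= th$dnv_min_alt_reads,
    alt_ratio = pro_ratio >= ratio_needed,
    parent_ratio = fa_ratio <= th$dnv_parent_ratio_max &
      mo_ratio <= th$dnv_parent_ratio_max,
    maf = maf <= th$dnv_maf_max
  )
  v <- .verdict(rules)
  data.frame(passed = v$passed, failed_rule = v$failed_rule,
             pro_ratio = pro_ratio, fa_ratio = fa_ratio, mo_ratio = mo_ratio,
             maf = maf, stringsAsFactors = FALSE)
}

#' In-cohort allele frequency over founders
#'
#' Computed over founders only (parents, plus probands of singleton
#' families), excluding flagged duplicate samples, to avoid
#' proband-enrichment bias.
#'
#' @param calls data.frame from [read_variants()].
#' @param pedigree a [read_pedigree()] result.
#' @param exclude sample ids to drop (e.g. flagged duplicates).
#' @return named numeric vector of frequencies keyed "chrom:pos:ref:alt".
#' @export
cohort_af <- function(calls, pedigree, exclude = character(0)) {
  founders <- c(stats::na.omit(pedigree$father_id),
                stats::na.omit(pedigree$mother_id),
                pedigree$proband_id[pedigree$type == "singleton"])
  founders <- setdiff(founders, exclude)
  n_allele <- 2L * length(founders)
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  dose <- function(gt) ifelse(is.na(gt), 0, ifelse(gt == "1/1", 2, gt == "0/1"))
  fam <- match(calls$family_id, pedigree$family_id)
  cnt <- dose(calls$fa_gt) * (!is.na(pedigree$father_id[fam]) &
                                !(pedigree$father_id[fam] %in% exclude)) +
    dose(calls$mo_gt) * (!is.na(pedigree$mother_id[fam]) &
                           !(pedigree$mother_id[fam] %in% exclude)) +
    dose(calls$pro_gt) * (pedigree$type[fam] == "singleton" &
                            !(pedigree$proband_id[fam] %in% exclude))
  tab <- tapply(cnt, key, sum)
  ac <- stats::setNames(as.numeric(tab), names(tab))
  ac / n_allele
}

#' Rare transmitted dominant variant filter
#'
#' Only LoF and D-mis classes qualify. A record passes when it has a VQSR
#' pass flag, reference-population MAF <= 5e-5, in-cohort MAF <= 5e-3,
#' proband DP >= 8 and GQ >= 20. Missing GQ or DP fails as
#' `missing_support`.
#'
#' @param calls data.frame from [read_variants()].
#' @param in_cohort_af named frequency vector from [cohort_af()] (or a
#'   numeric vector aligned with `calls`).
#' @param maf_column reference frequency column (the study used BRAVO here).
#' @param thresholds list from [filter_defaults()].
#' @return data.frame with `passed`, `failed_rule`, `maf`, `cohort_af`.
#' @export
transmitted_filter <- function(calls, in_cohort_af,
                               maf_column = "maf_bravo",
                               thresholds = filter_defaults()) {
  th <- thresholds
  maf <- calls[[maf_column]]
  maf[is.na(maf)] <- 0
  if (!is.null(names(in_cohort_af))) {
    key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
    caf <- unname(in_cohort_af[key])
    caf[is.na(caf)] <- 0
  } else caf <- in_cohort_af
  damaging <- is_damaging(calls$class, calls$metasvm, calls$mpc)
  rules <- list(
    missing_support = !is.na(calls$pro_dp) & !is.na(calls$pro_gq),
    vqsr = calls$vqsr_pass,
    maf_ref = maf <= th$trans_maf_max,
    maf_cohort = caf <= th$trans_cohort_maf_max,
    depth = calls$pro_dp >= th$trans_min_dp,
    gq = calls$pro_gq >= th$trans_min_gq,
    class = !is.na(damaging) & damaging
  )
  v <- .verdict(rules)
  data.frame(passed = v$passed, failed_rule = v$failed_rule,
             maf = maf, cohort_af = caf, stringsAsFactors = FALSE)
}

#' Recessive genotype configurations
#'
#' Per gene and family, returns passing homozygous calls and parent-phased
#' compound-heterozygous pairs (one allele inherited from each parent).
#' Record-level requirements: VQSR pass, reference MAF <= 1e-3, in-cohort
#' MAF <= 1e-2, proband total reads >= 8, GQ >= 20, class LoF, D-mis or
#' in-frame indel. Probands without parental data contribute homozygous
#' configurations only.
#'
#' @param calls data.frame from [read_variants()] for one or more genes.
#' @param in_cohort_af named frequency vector from [cohort_af()].
#' @param maf_column reference frequency column.
#' @param thresholds list from [filter_defaults()].
#' @return data.frame: `family_id`, `gene`, `config` (hom / comphet),
#'   `key1`, `key2` (NA for hom).
#' @export
recessive_filter <- function(calls, in_cohort_af, maf_column = "maf_bravo",
                             thresholds = filter_defaults()) {
  th <- thresholds
  maf <- calls[[maf_column]]
  maf[is.na(maf)] <- 0
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  caf <- unname(in_cohort_af[key])
  caf[is.na(caf)] <- 0
  damaging <- is_damaging(calls$class, calls$metasvm, calls$mpc) |
    calls$class %in% "inframe_indel"
  qc <- calls$vqsr_pass & maf <= th$rec_maf_max & caf <= th$rec_cohort_maf_max &
    !is.na(calls$pro_dp) & calls$pro_dp >= th$rec_min_dp &
    !is.na(calls$pro_gq) & calls$pro_gq >= th$rec_min_gq &
    !is.na(damaging) & damaging

  out <- list()
  idx <- which(qc & !is.na(calls$gene))
  for (grp in split(idx, paste(calls$family_id[idx], calls$gene[idx]))) {
    fam <- calls$family_id[grp[1L]]
    gene <- calls$gene[grp[1L]]
    has_parents <- calls$family_type[grp[1L]] == "trio"
    hom <- grp[!is.na(calls$pro_gt[grp]) & calls$pro_gt[grp] == "1/1"]
    for (h in hom)
      out[[length(out) + 1L]] <- data.frame(
        family_id = fam, gene = gene, config = "hom",
        key1 = key[h], key2 = NA_character_, stringsAsFactors = FALSE)
    if (has_parents) {
      het <- grp[!is.na(calls$pro_gt[grp]) & calls$pro_gt[grp] == "0/1"]
      from_fa <- het[!is.na(calls$fa_gt[het]) & calls$fa_gt[het] != "0/0" &
                       !is.na(calls$mo_gt[het]) & calls$mo_gt[het] == "0/0"]
      from_mo <- het[!is.na(calls$mo_gt[het]) & calls$mo_gt[het] != "0/0" &
                       !is.na(calls$fa_gt[het]) & calls$fa_gt[het] == "0/0"]
      for (a in from_fa) for (b in from_mo)
        out[[length(out) + 1L]] <- data.frame(
          family_id = fam, gene = gene, config = "comphet",
          key1 = key[a], key2 = key[b], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(family_id = character(0), gene = character(0),
                      config = character(0), key1 = character(0),
                      key2 = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Duplicate-sample and kinship QC
#'
#' Computes, for every sample pair, the fraction of rare variants shared
#' (Jaccard index over rare-variant carrier sets); pairs sharing >= 80% are
#' flagged duplicates and the sample with greater mean coverage is retained.
#' For proband-parent pairs an IBD proxy is computed from shared-genotype
#' counts at common biallelic sites (a method-of-moments kinship estimate,
#' scaled so parent-offspring pairs expect ~0.5); pairs outside
#' \[0.45, 0.55\] are flagged.
#'
#' @param dosage integer matrix sites x samples of alternate-allele dosages
#'   (0/1/2, NA for missing).
#' @param pedigree a [read_pedigree()] result.
#' @param ref_maf per-site reference population MAF (NA treated as 0); sites
#'   with MAF <= `rare_maf_max` count as rare.
#' @param mean_depth named per-sample mean depth, used to pick which
#'   duplicate to retain (ties broken by sample order).
#' @param thresholds list from [filter_defaults()].
#' @return list: `sharing` (symmetric matrix), `duplicates` (data.frame of
#'   flagged pairs with the retained id), `ibd` (data.frame of proband-parent
#'   proxies with plausibility flags), `no_rare` (samples with zero rare
#'   variants, whose sharing is undefined).
#' @export
duplicate_and_kinship <- function(dosage, pedigree, ref_maf = NULL,
                                  mean_depth = NULL,
                                  thresholds = filter_defaults()) {
  th <- thresholds
  if (nrow(dosage) < 1L || ncol(dosage) < 2L)
    stop("need >= 2 samples with genotypes")
  samples <- colnames(dosage)
  if (is.null(ref_maf)) ref_maf <- rep(0, nrow(dosage))
  ref_maf[is.na(ref_maf)] <- 0

  rare <- ref_maf <= th$rare_maf_max
  X <- (dosage[rare, , drop = FALSE] >= 1L)
  X[is.na(X)] <- FALSE
  n_carrier <- colSums(X)
  inter <- crossprod(X)                       # pairwise intersections
  uni <- outer(n_carrier, n_carrier, `+`) - inter
  sharing <- ifelse(uni > 0, inter / uni, NA_real_)
  diag(sharing)[n_carrier > 0] <- 1
  no_rare <- samples[n_carrier == 0L]

  pairs <- which(upper.tri(sharing) & sharing >= th$dup_sharing_min,
                 arr.ind = TRUE)
  dup <- data.frame(sample1 = samples[pairs[, 1L]],
                    sample2 = samples[pairs[, 2L]],
                    sharing = sharing[pairs], stringsAsFactors = FALSE)
  if (nrow(dup)) {
    d1 <- if (is.null(mean_depth)) 0 else mean_depth[dup$sample1]
    d2 <- if (is.null(mean_depth)) 0 else mean_depth[dup$sample2]
    dup$retained <- ifelse(!is.na(d1) & !is.na(d2) & d2 > d1,
                           dup$sample2, dup$sample1)
  } else dup$retained <- character(0)

  # IBD proxy at common biallelic sites: robust kinship from het sharing,
  # phi = (N_both_het - 2 N_opposite_hom) / (N_het_i + N_het_j); 2 phi is on
  # the IBD-sharing scale where parent-offspring expect 0.5
  common <- ref_maf >= th$common_maf_min
  G <- dosage[common, , drop = FALSE]
  ibd_pair <- function(i, j) {
    gi <- G[, i]; gj <- G[, j]
    ok <- !is.na(gi) & !is.na(gj)
    gi <- gi[ok]; gj <- gj[ok]
    n11 <- sum(gi == 1L & gj == 1L)
    n02 <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
    denom <- sum(gi == 1L) + sum(gj == 1L)
    if (denom == 0L) return(NA_real_)
    2 * (n11 - 2 * n02) / denom
  }
  rows <- list()
  for (i in seq_len(nrow(pedigree))) {
    for (par in c("father_id", "mother_id")) {
      pid <- pedigree[[par]][i]
      if (is.na(pid) || !(pid %in% samples) ||
          !(pedigree$proband_id[i] %in% samples)) next
      prox <- ibd_pair(match(pedigree$proband_id[i], samples),
                       match(pid, samples))
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = pedigree$family_id[i], proband = pedigree$proband_id[i],
        parent = pid, ibd_proxy = prox,
        flagged = is.na(prox) | prox < th$ibd_band[1L] | prox > th$ibd_band[2L],
        stringsAsFactors = FALSE)
    }
  }
  ibd <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(0), proband = character(0),
               parent = character(0), ibd_proxy = numeric(0),
               flagged = logical(0))
  list(sharing = sharing, duplicates = dup, ibd = ibd, no_rare = no_rare)
}
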