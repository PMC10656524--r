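# Named substreams: every stage draws from its own seed derived from the
# spec seed at a fixed registry position, so adding a stage never perturbs
# the draws of earlier stages.
.substreams <- c(rates = 1L, genes = 2L, pli = 3L, covariates = 4L,
                 dnv = 5L, transmitted = 6L, background = 7L,
                 read_support = 8L, plants = 9L, duplicates = 10L,
                 common = 11L)

.use_substream <- function(seed, stage) {
  set.seed(seed %% 2147483L * 1000L + .substreams[[stage]])
  invisible(NULL)
}

#' Specification of a synthetic trio cohort
#'
#' Generative parameters for the synthetic gene universe and cohort. The
#' defaults mirror the study conditions at desk scale: 90 trios, 13 duos and
#' 11 singletons over a 2,000-gene universe whose context rates are scaled
#' so the expected cohort-wide DNV count is about 100 (the study observed
#' 107 over 19,347 genes). True heterozygote allele balance is Beta-centred
#' at 0.5 and homozygous-reference error alleles arise at rate 0.005, so
#' default records pass the filters and only planted records fail.
#'
#' @param seed mandatory integer seed; all randomness flows from it.
#' @param n_genes number of genes (>= 10).
#' @param n_trios,n_duos,n_singletons family configuration counts.
#' @param target_total_dnv expected cohort-wide DNV count used to scale the
#'   context-rate table.
#' @param mutability_sigma log-normal sigma of gene coding length, the main
#'   driver of between-gene mutability dispersion.
#' @param pli_missing_rate fraction of genes without a pLI score.
#' @param n_risk_genes,risk_fold number of spiked risk genes and their
#'   fold-enrichment for damaging DNVs (recycled over genes).
#' @param target_af target attributable fraction; risk genes are chosen so
#'   the implied excess of damaging DNVs divided by `n_trios` matches it.
#' @param L_k transmitted damaging heterozygote totals for the five pLI
#'   strata.
#' @param depth_mean mean sequencing depth of the read-support model.
#' @param het_beta shape parameters of the Beta allele-balance model for
#'   true heterozygotes.
#' @param err_rate per-read error-allele rate for homozygous-reference
#'   calls.
#' @param rare_per_founder private rare variants per founder (drives
#'   duplicate/kinship sharing).
#' @param n_common common biallelic sites (drives the IBD proxy).
#' @param plant_dnv,plant_transmitted named integer vectors: number of
#'   planted filter-violating records per rule id.
#' @param n_duplicate_pairs duplicated samples to inject.
#' @param dmis_fraction damaging fraction of missense mutability.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(seed, n_genes = 2000, n_trios = 90, n_duos = 13,
                        n_singletons = 11, target_total_dnv = 100,
                        mutability_sigma = 0.6, pli_missing_rate = 0.08,
                        n_risk_genes = 0, risk_fold = 1, target_af = NULL,
                        L_k = c(200, 250, 250, 200, 100),
                        depth_mean = 40, het_beta = c(20, 20),
                        err_rate = 0.005, rare_per_founder = 30,
                        n_common = 1500,
                        plant_dnv = integer(0), plant_transmitted = integer(0),
                        n_duplicate_pairs = 0, dmis_fraction = 0.3) {
  if (missing(seed)) stop("seed is mandatory: no implicit randomness")
  if (n_genes < 10) stop("n_genes < 10: pLI strata unfillable")
  stopifnot(n_trios >= 0, n_duos >= 0, n_singletons >= 0,
            all(risk_fold >= 1), length(L_k) == 5L, all(L_k >= 0),
            n_duplicate_pairs >= 0)
  if (!is.null(target_af) && (target_af < 0 || target_af >= 1))
    stop("target attributable fraction must be in [0, 1)")
  spec <- as.list(environment())
  class(spec) <- "cohort_spec"
  spec
}

# draw a random context-rate table: lognormal around 1e-8 with elevated
# CpG-context rates, exactly strand-complement symmetric
.random_context_rates <- function() {
  tab <- as.data.frame(flat_context_rates(1e-8))
  key <- paste0(tab$context, ">", tab$alt)
  comp <- paste0(revcomp(tab$context), ">", revcomp(tab$alt))
  cpg <- grepl("CG", tab$context, fixed = TRUE)
  rate <- exp(log(1e-8) + stats::rnorm(nrow(tab), 0, 0.3)) *
    ifelse(cpg, 8, 1)
  # symmetrize: each complement pair shares one draw
  first <- pmin(key, comp)
  rate <- rate[match(first, key)]
  tab$rate <- rate
  context_rate_table(tab)
}

.sense_codons <- setdiff(as.vector(outer(as.vector(outer(
  c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
  c("A", "C", "G", "T"), paste0)), c("TAA", "TAG", "TGA"))

.random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# gnomAD-like bimodal pLI: most genes unconstrained near 0, a constrained
# tail near 1, some intermediate
.random_pli <- function(n, missing_rate) {
  comp <- sample.int(3L, n, replace = TRUE, prob = c(0.50, 0.30, 0.20))
  pli <- numeric(n)
  pli[comp == 1L] <- stats::rbeta(sum(comp == 1L), 0.03, 2)   # near 0
  pli[comp == 2L] <- stats::rbeta(sum(comp == 2L), 0.4, 3)    # intermediate
  pli[comp == 3L] <- stats::rbeta(sum(comp == 3L), 4, 0.2)    # near 1
  pli[stats::runif(n) < missing_rate] <- NA_real_
  pli
}

#' Generate a synthetic gene universe
#'
#' Random open reading frames (valid start/stop, no internal stops) split
#' over 1-3 exons with short introns on per-gene contigs, a random
#' strand-symmetric context-rate table with elevated CpG rates, a bimodal
#' pLI distribution with a missing fraction, and gene covariates. Per-gene
#' mutabilities are computed through [gene_mutability()] — the same code
#' path the analysis uses — and the rate table is rescaled so the expected
#' cohort-wide DNV count matches `spec$target_total_dnv`.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `gene_universe`: `genes` (models + covariates +
#'   `p_*` columns), `exons`, `seqs`, `rates`, `capture`, `spec`.
#' @export
simulate_gene_universe <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_genes

  .use_substream(spec$seed, "rates")
  rates <- .random_context_rates()

  .use_substream(spec$seed, "genes")
  gene_id <- sprintf("G%04d", seq_len(n))
  n_codon <- pmin(pmax(round(exp(stats::rnorm(n, log(100),
                                              spec$mutability_sigma))), 40), 500)
  gc_target <- 0.3 + 0.4 * stats::rbeta(n, 5, 5)
  strand <- sample(c("+", "-"), n, replace = TRUE, prob = c(0.85, 0.15))
  n_exon <- sample(1:3, n, replace = TRUE, prob = c(0.2, 0.4, 0.4))

  seqs <- character(n)
  exon_rows <- vector("list", n)
  gc_content <- numeric(n)
  for (i in seq_len(n)) {
    interior <- sample(.sense_codons, n_codon[i] - 2L, replace = TRUE,
                       prob = .codon_weights(gc_target[i]))
    cds <- paste0("ATG", paste(interior, collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    gc_content[i] <- .gc_frac(cds)
    L <- nchar(cds)
    k <- n_exon[i]
    cuts <- if (k == 1L) integer(0) else
      sort(sample(seq(12L, L - 12L, by = 3L), k - 1L))
    bounds <- c(0L, cuts, L)
    pieces <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
    flank <- .random_dna(10L, gc_target[i])
    intron <- replicate(k - 1L, .random_dna(30L, 0.4))
    parts <- character(0)
    starts <- integer(k); ends <- integer(k)
    off <- 10L
    parts <- flank
    for (e in seq_len(k)) {
      starts[e] <- off
      off <- off + nchar(pieces[e])
      ends[e] <- off
      parts <- c(parts, pieces[e])
      if (e < k) {
        parts <- c(parts, intron[e])
        off <- off + 30L
      }
    }
    parts <- c(parts, .random_dna(10L, gc_target[i]))
    contig <- paste(parts, collapse = "")
    if (strand[i] == "-") {
      len <- nchar(contig)
      contig <- revcomp(contig)
      new_starts <- len - ends
      new_ends <- len - starts
      starts <- rev(new_starts); ends <- rev(new_ends)
    }
    seqs[i] <- contig
    exon_rows[[i]] <- data.frame(gene_id = gene_id[i], contig = gene_id[i],
                                 start = starts, end = ends,
                                 stringsAsFactors = FALSE)
  }
  names(seqs) <- gene_id
  exons <- do.call(rbind, exon_rows)

  .use_substream(spec$seed, "pli")
  pli <- .random_pli(n, spec$pli_missing_rate)

  .use_substream(spec$seed, "covariates")
  expr <- exp(stats::rnorm(n, 1, 1))

  capture <- GenomicRanges::reduce(GenomicRanges::GRanges(
    exons$contig,
    IRanges::IRanges(start = pmax(exons$start - 10L, 0L) + 1L,
                     end = exons$end + 10L)))

  pm <- matrix(0, nrow = n, ncol = length(.mutability_classes),
               dimnames = list(gene_id, paste0("p_", .mutability_classes)))
  for (i in seq_len(n)) {
    ex <- exon_rows[[i]][, c("start", "end")]
    pm[i, ] <- gene_mutability(seqs[i], ex, strand[i], rates,
                               capture = capture, contig = gene_id[i])
  }
  total_p <- rowSums(pm[, paste0("p_", setdiff(.mutability_classes,
                                               "frameshift")), drop = FALSE]) +
    pm[, "p_frameshift"]
  scale <- spec$target_total_dnv / (2 * max(spec$n_trios, 1) * sum(total_p))
  pm <- pm * scale
  rates$rate <- rates$rate * scale
  rates <- context_rate_table(as.data.frame(rates))

  genes <- data.frame(gene_id = gene_id, contig = gene_id, strand = strand,
                      pLI = pli, gc_content = gc_content,
                      gene_length = 3L * n_codon,
                      mean_expression = expr,
                      dmis_fraction = spec$dmis_fraction,
                      stringsAsFactors = FALSE)
  genes <- cbind(genes, as.data.frame(pm))
  genes$p_damaging <- apply(pm, 1L, function(p)
    damaging_mutability(stats::setNames(p, .mutability_classes),
                        spec$dmis_fraction))
  universe <- list(genes = genes, exons = exons, seqs = seqs, rates = rates,
                   capture = capture, spec = spec)
  class(universe) <- "gene_universe"
  universe
}

.gc_frac <- function(s) {
  v <- strsplit(s, "")[[1L]]
  mean(v %in% c("G", "C"))
}

.codon_weights <- function(gc) {
  g <- vapply(.sense_codons, .gc_frac, numeric(1L))
  w <- gc ^ (3 * g) * (1 - gc) ^ (3 * (1 - g))
  w / sum(w)
}

# enumerate all possible substitutions of a gene (coding + canonical splice)
# with genomic 1-based positions; used to realize simulated events as sites
gene_site_table <- function(contig_seq, exons, strand) {
  exons <- exons[order(exons$start), , drop = FALSE]
  pos0 <- unlist(Map(function(s, e) seq.int(s, e - 1L), exons$start, exons$end),
                 use.names = FALSE)
  cds <- paste(substring(contig_seq, exons$start + 1L, exons$end),
               collapse = "")
  if (strand == "-") cds <- revcomp(cds)
  cds_idx <- if (strand == "+") seq_along(pos0) else rev(seq_along(pos0))
  ref <- substring(contig_seq, pos0 + 1L, pos0 + 1L)
  bases <- c("A", "C", "G", "T")
  alt <- lapply(ref, function(r) setdiff(bases, r))
  alt_flat <- unlist(alt, use.names = FALSE)
  cds_alt <- if (strand == "+") alt_flat else chartr("ACGT", "TGCA", alt_flat)
  cls <- classify_substitution(cds, rep(cds_idx, each = 3L), cds_alt)
  out <- data.frame(pos = rep(pos0, each = 3L) + 1L,
                    ref = rep(ref, each = 3L), alt = alt_flat,
                    class = cls, stringsAsFactors = FALSE)
  if (nrow(exons) > 1L) {
    m <- nrow(exons)
    sp0 <- sort(unique(c(outer(exons$end[-m], 0:1, `+`),
                         outer(exons$start[-1L], -(2:1), `+`))))
    sp0 <- sp0[!(sp0 %in% pos0)]
    spr <- substring(contig_seq, sp0 + 1L, sp0 + 1L)
    spalt <- unlist(lapply(spr, function(r) setdiff(bases, r)),
                    use.names = FALSE)
    out <- rbind(out, data.frame(pos = rep(sp0, each = 3L) + 1L,
                                 ref = rep(spr, each = 3L), alt = spalt,
                                 class = "splice_canonical",
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Choose the spiked risk genes implied by a cohort spec
#'
#' With a target attributable fraction, picks the genes whose damaging
#' mutability, at the requested fold-enrichments, yields an excess of
#' damaging DNVs closest to the target; without one, samples risk genes
#' mutability-weighted. Errors with the feasible range when the target is
#' unreachable at the given folds. Deterministic given the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @param universe from [simulate_gene_universe()].
#' @return list: `risk` (data.frame gene, fold), `true_af` (the realized
#'   attributable fraction implied by the chosen genes).
#' @export
plan_risk_genes <- function(spec, universe) {
  genes <- universe$genes
  if (spec$n_risk_genes == 0)
    return(list(risk = data.frame(gene = character(0), fold = numeric(0)),
                true_af = 0))
  .use_substream(spec$seed, "dnv")
  folds <- rep(spec$risk_fold, length.out = spec$n_risk_genes)
  p_dmg <- genes$p_damaging
  if (!is.null(spec$target_af)) {
    need <- spec$target_af / (2 * sum(folds - 1))
    ord <- order(abs(p_dmg - need))
    af_max <- 2 * sum((folds - 1) *
                        sort(p_dmg, decreasing = TRUE)[seq_along(folds)])
    af_min <- 2 * sum((folds - 1) * sort(p_dmg)[seq_along(folds)])
    if (spec$target_af > af_max || spec$target_af < af_min)
      stop(sprintf(paste0("target attributable fraction %.3f infeasible; ",
                          "feasible range [%.4f, %.4f]"),
                   spec$target_af, af_min, af_max))
    pick <- ord[seq_len(spec$n_risk_genes)]
  } else {
    pick <- sample.int(nrow(genes), spec$n_risk_genes, prob = p_dmg)
  }
  list(risk = data.frame(gene = genes$gene_id[pick], fold = folds,
                         stringsAsFactors = FALSE),
       true_af = 2 * sum((folds - 1) * p_dmg[pick]))
}

#' Simulate a trio cohort with ground truth
#'
#' Draws de novo variants per trio and gene from the Poisson process implied
#' by the universe's mutabilities (damaging classes fold-enriched in spiked
#' risk genes), rare transmitted damaging heterozygotes multinomially over
#' damaging mutability within pLI strata with stratum totals `L_k`, common
#' biallelic sites in Hardy-Weinberg proportions with Mendelian
#' transmission, and private rare founder variants with 50% transmission.
#' Genotype-level read support follows the cohort spec's
#' depth/allele-balance model. Filter-violating records and duplicate samples are planted as
#' requested and recorded in the returned ground truth.
#'
#' @param spec a [cohort_spec()].
#' @param universe from [simulate_gene_universe()] (same spec).
#' @param dir if non-NULL, write `cohort.vcf`, `cohort.ped`, `capture.bed`
#'   and `truth.json` into this directory.
#' @return list of class `synthetic_cohort`: `variants` (site table),
#'   genotype matrices `gt`, `dp`, `ad_alt`, `gq` (sites x samples), `ped`
#'   (pedigree rows), `samples`, `truth`, and file paths when written.
#' @export
simulate_cohort <- function(spec, universe, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(universe, "gene_universe"))
  genes <- universe$genes
  n_genes <- nrow(genes)

  # family/sample bookkeeping -------------------------------------------------
  fam <- list()
  add_fam <- function(id, type) {
    pro <- paste0(id, "-01")
    fa <- if (type == "trio") paste0(id, "-02") else NA_character_
    mo <- if (type != "singleton") paste0(id, "-03") else NA_character_
    fam[[length(fam) + 1L]] <<- data.frame(family_id = id, proband_id = pro,
                                           father_id = fa, mother_id = mo,
                                           type = type,
                                           stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec$n_trios)) add_fam(sprintf("T%03d", i), "trio")
  for (i in seq_len(spec$n_duos)) add_fam(sprintf("D%03d", i), "duo")
  for (i in seq_len(spec$n_singletons)) add_fam(sprintf("S%03d", i), "singleton")
  fam <- do.call(rbind, fam)
  samples <- unique(stats::na.omit(c(t(fam[, c("proband_id", "father_id",
                                               "mother_id")]))))
  founders <- c(stats::na.omit(fam$father_id), stats::na.omit(fam$mother_id),
                fam$proband_id[fam$type == "singleton"])
  trios <- fam[fam$type == "trio", , drop = FALSE]

  # risk genes ---------------------------------------------------------------
  plan <- plan_risk_genes(spec, universe)
  risk <- plan$risk
  true_af <- plan$true_af

  # site-table cache ----------------------------------------------------------
  site_cache <- new.env(parent = emptyenv())
  sites_of <- function(g) {
    if (is.null(site_cache[[g]])) {
      ex <- universe$exons[universe$exons$gene_id == g, c("start", "end")]
      site_cache[[g]] <- gene_site_table(universe$seqs[[g]], ex,
                                         genes$strand[genes$gene_id == g])
    }
    site_cache[[g]]
  }
  pick_site <- function(g, classes) {
    st <- sites_of(g)
    cand <- which(st$class %in% classes)
    if (!length(cand)) return(NULL)
    st[sample(cand, 1L), ]
  }

  rows <- list()      # one element per variant site
  geno <- list()      # per site: list(sample -> c(gt, dp, ad, gq))
  truth_plants <- list()

  # read-support draws --------------------------------------------------------
  draw_depth <- function(n) pmax(stats::rpois(n, spec$depth_mean), 12L)
  gt_block <- function(gt_vec) {
    n <- length(gt_vec)
    dp <- draw_depth(n)
    ad <- integer(n)
    het <- gt_vec == "0/1"; hom <- gt_vec == "1/1"
    ad[het] <- stats::rbinom(sum(het), dp[het],
                             stats::rbeta(sum(het), spec$het_beta[1L],
                                          spec$het_beta[2L]))
    ad[het] <- pmax(ad[het], 5L)           # callable hets
    ad[hom] <- dp[hom] - stats::rbinom(sum(hom), dp[hom], spec$err_rate)
    ref <- gt_vec == "0/0"
    ad[ref] <- stats::rbinom(sum(ref), dp[ref], spec$err_rate)
    ad[ref] <- pmin(ad[ref], floor(0.03 * dp[ref]))   # below parent-ratio cap
    gq <- pmin(99L, 20L + stats::rpois(n, 40L))
    nm <- names(gt_vec)
    list(gt = gt_vec, dp = stats::setNames(dp, nm),
         ad = stats::setNames(ad, nm), gq = stats::setNames(gq, nm))
  }
  add_variant <- function(gene, site, info, carriers) {
    # carriers: named character gt per sample carrying alt; others hom-ref
    gt_vec <- stats::setNames(rep("0/0", length(samples)), samples)
    gt_vec[names(carriers)] <- carriers
    blk <- gt_block(gt_vec)
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = gene, pos = site$pos, ref = site$ref, alt = site$alt,
      gene = gene, class = site$class, metasvm = info$metasvm,
      mpc = info$mpc, af_gnomad = info$af_gnomad, af_bravo = info$af_bravo,
      filter = info$filter, stringsAsFactors = FALSE)
    geno[[length(geno) + 1L]] <<- blk
    length(rows)
  }
  std_info <- function(metasvm = ".", mpc = NA_real_, af = 0,
                       filter = "PASS")
    list(metasvm = metasvm, mpc = mpc, af_gnomad = af, af_bravo = af,
         filter = filter)

  # (a) de novo variants ------------------------------------------------------
  .use_substream(spec$seed, "dnv")
  dnv_truth <- list()
  if (spec$n_trios > 0) {
    fold <- stats::setNames(rep(1, n_genes), genes$gene_id)
    if (nrow(risk)) fold[risk$gene] <- risk$fold
    class_sets <- list(
      synonymous = "synonymous", tmis = "missense", dmis = "missense",
      splice_canonical = "splice_canonical", stopgain = "stopgain",
      stoploss = "stoploss", startloss = "startloss",
      frameshift = "stopgain")  # frameshift realized at a stopgain-able site
    for (cl in names(class_sets)) {
      lam <- switch(cl,
        tmis = genes$p_missense * (1 - genes$dmis_fraction),
        dmis = genes$p_missense * genes$dmis_fraction * fold,
        synonymous = genes$p_synonymous,
        splice_canonical = genes$p_splice_canonical * fold,
        stopgain = genes$p_stopgain * fold,
        stoploss = genes$p_stoploss * fold,
        startloss = genes$p_startloss * fold,
        frameshift = genes$p_frameshift * fold)
      cnt <- stats::rpois(n_genes, 2 * spec$n_trios * lam)
      for (gi in which(cnt > 0L)) for (k in seq_len(cnt[gi])) {
        g <- genes$gene_id[gi]
        site <- pick_site(g, class_sets[[cl]])
        if (is.null(site)) next
        if (cl == "frameshift") {       # 1-bp deletion at the chosen site
          site$ref <- paste0(site$ref, site$alt)
          site$alt <- substr(site$ref, 1L, 1L)
          site$class <- "frameshift"
        }
        if (cl == "dmis") info <- std_info(metasvm = "D",
                                           mpc = stats::runif(1, 2, 4))
        else if (cl == "tmis") info <- std_info(metasvm = "T",
                                                mpc = stats::runif(1, 0, 1.5))
        else info <- std_info()
        tr <- trios[sample.int(nrow(trios), 1L), ]
        id <- add_variant(g, site, info,
                          stats::setNames("0/1", tr$proband_id))
        dnv_truth[[length(dnv_truth) + 1L]] <-
          list(gene = g, class = site$class,
               damaging = cl %in% c("dmis", "splice_canonical", "stopgain",
                                    "stoploss", "startloss", "frameshift"),
               family = tr$family_id, row = id)
      }
    }
  }

  # (b) transmitted damaging heterozygotes ------------------------------------
  .use_substream(spec$seed, "transmitted")
  strata <- assign_strata(genes)
  trans_truth <- list()
  par_fams <- fam[fam$type %in% c("trio", "duo"), , drop = FALSE]
  if (nrow(par_fams)) {
    for (k in 1:5) {
      gk <- which(strata == k & genes$p_damaging > 0)
      if (!length(gk) || spec$L_k[k] == 0) next
      cnt <- stats::rmultinom(1L, spec$L_k[k],
                              genes$p_damaging[gk])[, 1L]
      for (j in which(cnt > 0L)) for (rep_i in seq_len(cnt[j])) {
        g <- genes$gene_id[gk[j]]
        use_dmis <- stats::runif(1) <
          (genes$dmis_fraction[gk[j]] * genes$p_missense[gk[j]] /
             genes$p_damaging[gk[j]])
        site <- if (use_dmis) pick_site(g, "missense") else
          pick_site(g, c("splice_canonical", "stopgain", "stoploss",
                         "startloss"))
        if (is.null(site)) site <- pick_site(g, "missense")
        if (is.null(site)) next
        info <- if (site$class == "missense")
          std_info(metasvm = "D", mpc = stats::runif(1, 2, 4),
                   af = stats::runif(1, 0, 3e-5))
        else std_info(af = stats::runif(1, 0, 3e-5))
        f <- par_fams[sample.int(nrow(par_fams), 1L), ]
        parent <- if (f$type == "trio" && stats::runif(1) < 0.5)
          f$father_id else f$mother_id
        carriers <- stats::setNames(c("0/1", "0/1"),
                                    c(f$proband_id, parent))
        id <- add_variant(g, site, info, carriers)
        trans_truth[[length(trans_truth) + 1L]] <-
          list(gene = g, stratum = k, family = f$family_id, row = id)
      }
    }
  }

  # (c) common biallelic sites (HWE founders, Mendelian children) -------------
  .use_substream(spec$seed, "common")
  if (spec$n_common > 0) {
    for (i in seq_len(spec$n_common)) {
      g <- genes$gene_id[sample.int(n_genes, 1L)]
      site <- pick_site(g, c("synonymous", "missense"))
      q <- stats::runif(1, 0.1, 0.5)
      # founder allele pairs
      alleles <- stats::setNames(vector("list", length(samples)), samples)
      for (s in founders) alleles[[s]] <- stats::rbinom(2L, 1L, q)
      for (fi in seq_len(nrow(fam))) {
        if (fam$type[fi] == "singleton") next
        pa <- fam$father_id[fi]; ma <- fam$mother_id[fi]
        a1 <- if (!is.na(pa)) sample(alleles[[pa]], 1L) else
          stats::rbinom(1L, 1L, q)
        a2 <- if (!is.na(ma)) sample(alleles[[ma]], 1L) else
          stats::rbinom(1L, 1L, q)
        alleles[[fam$proband_id[fi]]] <- c(a1, a2)
      }
      gts <- vapply(alleles, function(a)
        if (is.null(a)) "0/0" else paste(sort(a), collapse = "/"),
        character(1L))
      carriers <- gts[gts != "0/0"]
      if (!length(carriers)) next
      info <- std_info(af = q)
      info$metasvm <- "T"
      add_variant(g, site, info, carriers)
    }
  }

  # (d) private rare founder variants, transmitted at 1/2 ---------------------
  .use_substream(spec$seed, "background")
  rare_truth <- stats::setNames(vector("list", length(samples)), samples)
  if (spec$rare_per_founder > 0) {
    for (s in founders) {
      for (v in seq_len(spec$rare_per_founder)) {
        g <- genes$gene_id[sample.int(n_genes, 1L)]
        site <- pick_site(g, c("synonymous", "missense"))
        carriers <- stats::setNames("0/1", s)
        fi <- which(fam$father_id == s | fam$mother_id == s)
        if (length(fi) && stats::runif(1) < 0.5)
          carriers[fam$proband_id[fi[1L]]] <- "0/1"
        info <- std_info(metasvm = "T", af = stats::runif(1, 0, 5e-4))
        add_variant(g, site, info, carriers)
      }
    }
  }

  # (e) planted filter violations ---------------------------------------------
  .use_substream(spec$seed, "plants")
  plant_one <- function(filter_name, rule) {
    g <- genes$gene_id[sample.int(n_genes, 1L)]
    tr <- trios[sample.int(max(nrow(trios), 1L), 1L), ]
    site <- pick_site(g, "missense")
    info <- std_info(metasvm = "D", mpc = 3)
    # proband-only carrier: keeps the in-cohort founder AF at zero so the
    # doctored rule is the unique failure even in tiny fixtures
    carriers <- stats::setNames("0/1", tr$proband_id)
    id <- add_variant(g, site, info, carriers)
    # doctor the record to violate exactly one rule
    i <- id
    pro <- tr$proband_id; fa <- tr$father_id; mo <- tr$mother_id
    fix <- function(s, dp = NULL, ad = NULL, gq = NULL) {
      if (!is.null(dp)) geno[[i]]$dp[s] <<- dp
      if (!is.null(ad)) geno[[i]]$ad[s] <<- ad
      if (!is.null(gq)) geno[[i]]$gq[s] <<- gq
    }
    if (filter_name == "dnv") {
      switch(rule,
        class = { rows[[i]]$class <<- "other"; rows[[i]]$metasvm <<- "." },
        depth = fix(fa, dp = 5L, ad = 0L),
        alt_reads = fix(pro, dp = 30L, ad = 3L),
        alt_ratio = fix(pro, dp = 32L, ad = 8L),
        parent_ratio = fix(mo, dp = 40L, ad = 2L),
        maf = { rows[[i]]$af_gnomad <<- 1e-3; rows[[i]]$af_bravo <<- 1e-3 },
        missing_support = { geno[[i]]$dp[fa] <<- NA_integer_
                            geno[[i]]$ad[fa] <<- NA_integer_ },
        stop("unknown dnv rule ", rule))
    } else {
      switch(rule,
        vqsr = rows[[i]]$filter <<- "VQSRTrancheSNP99.90to100.00",
        maf_ref = { rows[[i]]$af_bravo <<- 1e-4; rows[[i]]$af_gnomad <<- 1e-4 },
        maf_cohort = {
          extra <- sample(setdiff(founders, c(fa, mo)), 6L)
          geno[[i]]$gt[extra] <<- "0/1"
          blk <- gt_block(rep("0/1", length(extra)))
          geno[[i]]$dp[extra] <<- blk$dp
          geno[[i]]$ad[extra] <<- blk$ad
        },
        depth = fix(pro, dp = 5L, ad = 3L),
        gq = fix(pro, gq = 10L),
        class = { rows[[i]]$metasvm <<- "T"; rows[[i]]$mpc <<- 0.5 },
        missing_support = fix(pro, gq = NA_integer_),
        stop("unknown transmitted rule ", rule))
    }
    truth_plants[[length(truth_plants) + 1L]] <<-
      list(filter = filter_name, rule = rule,
           key = paste(rows[[i]]$chrom, rows[[i]]$pos, rows[[i]]$ref,
                       rows[[i]]$alt, sep = ":"),
           family = tr$family_id, row = i)
  }
  for (rule in names(spec$plant_dnv))
    for (k in seq_len(spec$plant_dnv[[rule]])) plant_one("dnv", rule)
  for (rule in names(spec$plant_transmitted))
    for (k in seq_len(spec$plant_transmitted[[rule]])) plant_one("transmitted", rule)

  # assemble matrices ----------------------------------------------------------
  n_sites <- length(rows)
  variants <- do.call(rbind, rows)
  gt <- do.call(rbind, lapply(geno, function(b) b$gt))
  dp <- do.call(rbind, lapply(geno, function(b) b$dp))
  ad <- do.call(rbind, lapply(geno, function(b) b$ad))
  gq <- do.call(rbind, lapply(geno, function(b) b$gq))
  colnames(gt) <- colnames(dp) <- colnames(ad) <- colnames(gq) <- samples

  # (f) duplicate samples ------------------------------------------------------
  .use_substream(spec$seed, "duplicates")
  dup_truth <- list()
  if (spec$n_duplicate_pairs > 0) {
    pool <- stats::na.omit(fam$father_id)
    src <- sample(pool, spec$n_duplicate_pairs)
    for (j in seq_along(src)) {
      s <- src[j]
      ds <- paste0("DUP", sprintf("%02d", j))
      gtd <- gt[, s]
      flip <- which(stats::runif(n_sites) < 0.02 & gtd == "0/1")
      gtd[flip] <- "0/0"
      blk <- gt_block(gtd)
      dp2 <- pmax(blk$dp - 15L, 8L)       # lower coverage: original retained
      blk$ad <- pmin(blk$ad, round(blk$ad * dp2 / blk$dp))
      blk$dp <- dp2
      gt <- cbind(gt, stats::setNames(data.frame(gtd), ds)[[1L]])
      dp <- cbind(dp, blk$dp); ad <- cbind(ad, blk$ad); gq <- cbind(gq, blk$gq)
      colnames(gt)[ncol(gt)] <- colnames(dp)[ncol(dp)] <-
        colnames(ad)[ncol(ad)] <- colnames(gq)[ncol(gq)] <- ds
      fam <- rbind(fam, data.frame(family_id = ds, proband_id = ds,
                                   father_id = NA_character_,
                                   mother_id = NA_character_,
                                   type = "singleton",
                                   stringsAsFactors = FALSE))
      dup_truth[[j]] <- list(original = s, duplicate = ds)
      samples <- c(samples, ds)
    }
  }

  truth <- list(
    seed = spec$seed,
    risk_genes = risk,
    true_af = true_af,
    n_dnv = length(dnv_truth),
    dnv = dnv_truth,
    transmitted = trans_truth,
    L_k = spec$L_k,
    plants = truth_plants,
    duplicates = dup_truth
  )
  out <- list(variants = variants, gt = gt, dp = dp, ad_alt = ad, gq = gq,
              ped = fam, samples = samples, truth = truth)
  class(out) <- "synthetic_cohort"
  if (!is.null(dir)) out <- write_cohort(out, universe, dir)
  out
}

#' Write a synthetic cohort to VCF/PED/BED/JSON files
#'
#' @param cohort from [simulate_cohort()].
#' @param universe the matching [simulate_gene_universe()] result.
#' @param dir output directory (created if needed).
#' @return the cohort, with `paths` added.
#' @export
write_cohort <- function(cohort, universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- cohort$variants
  ord <- order(v$chrom, v$pos, v$ref, v$alt)
  v <- v[ord, , drop = FALSE]
  gt <- cohort$gt[ord, , drop = FALSE]
  dp <- cohort$dp[ord, , drop = FALSE]
  ad <- cohort$ad_alt[ord, , drop = FALSE]
  gq <- cohort$gq[ord, , drop = FALSE]

  vcf_path <- file.path(dir, "cohort.vcf")
  con <- file(vcf_path, "w")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=trioburden-synthetic",
    paste0("##contig=<ID=", unique(universe$exons$contig), ">"),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Functional class\">",
    "##INFO=<ID=METASVM,Number=1,Type=String,Description=\"MetaSVM label\">",
    "##INFO=<ID=MPC,Number=1,Type=Float,Description=\"MPC score\">",
    "##INFO=<ID=AF_GNOMAD,Number=1,Type=Float,Description=\"Population AF\">",
    "##INFO=<ID=AF_BRAVO,Number=1,Type=Float,Description=\"Population AF\">",
    "##FILTER=<ID=VQSRTrancheSNP99.90to100.00,Description=\"VQSR tranche\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t")), con)
  info <- paste0("GENE=", v$gene, ";CLASS=", v$class,
                 ifelse(v$metasvm == ".", "", paste0(";METASVM=", v$metasvm)),
                 ifelse(is.na(v$mpc), "", paste0(";MPC=", formatC(v$mpc, format = "g"))),
                 ";AF_GNOMAD=", formatC(v$af_gnomad, format = "g"),
                 ";AF_BRAVO=", formatC(v$af_bravo, format = "g"))
  fmt_cell <- function(g, d, a, q) {
    adr <- ifelse(is.na(a) | is.na(d), ".", paste0(pmax(d - a, 0L), ",", a))
    paste(ifelse(is.na(g), "./.", g), adr,
          ifelse(is.na(d), ".", d), ifelse(is.na(q), ".", q), sep = ":")
  }
  cells <- matrix("", nrow = nrow(v), ncol = ncol(gt))
  for (j in seq_len(ncol(gt)))
    cells[, j] <- fmt_cell(gt[, j], dp[, j], ad[, j], gq[, j])
  lines <- paste(v$chrom, v$pos, ".", v$ref, v$alt, "100", v$filter, info,
                 "GT:AD:DP:GQ", apply(cells, 1L, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  close(con)

  ped_path <- file.path(dir, "cohort.ped")
  ped <- cohort$ped
  lines <- character(0)
  for (i in seq_len(nrow(ped))) {
    lines <- c(lines, paste(ped$family_id[i], ped$proband_id[i],
                            ifelse(is.na(ped$father_id[i]), "0", ped$father_id[i]),
                            ifelse(is.na(ped$mother_id[i]), "0", ped$mother_id[i]),
                            "1", "2", sep = "\t"))
    if (!is.na(ped$father_id[i]))
      lines <- c(lines, paste(ped$family_id[i], ped$father_id[i], "0", "0",
                              "1", "1", sep = "\t"))
    if (!is.na(ped$mother_id[i]))
      lines <- c(lines, paste(ped$family_id[i], ped$mother_id[i], "0", "0",
                              "2", "1", sep = "\t"))
  }
  writeLines(lines, ped_path)

  bed_path <- file.path(dir, "capture.bed")
  write_capture(universe$capture, bed_path)

  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(cohort$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  cohort$paths <- c(vcf = vcf_path, ped = ped_path, bed = bed_path,
                    truth = truth_path)
  cohort
}

#' Emit the small canonical fixture suite
#'
#' A tiny deterministic cohort (20 genes; 3 trios, 1 duo, 1 singleton) with
#' one planted violation per filter rule of the de novo and transmitted
#' cascades, one duplicate sample, and enough clean records that every rule
#' also has passing examples. Used by the unit tests; regenerating with the
#' same seed is byte-identical.
#'
#' @param out_dir output directory.
#' @param seed fixture seed.
#' @return invisible list with the spec, universe, cohort and file paths.
#' @export
emit_fixture_suite <- function(out_dir, seed = 20240501) {
  spec <- cohort_spec(
    seed = seed, n_genes = 20, n_trios = 3, n_duos = 1, n_singletons = 1,
    target_total_dnv = 8, L_k = c(2, 2, 2, 2, 2),
    rare_per_founder = 20, n_common = 120,
    plant_dnv = c(class = 1L, depth = 1L, alt_reads = 1L, alt_ratio = 1L,
                  parent_ratio = 1L, maf = 1L, missing_support = 1L),
    plant_transmitted = c(vqsr = 1L, maf_ref = 1L, maf_cohort = 1L,
                          depth = 1L, gq = 1L, class = 1L,
                          missing_support = 1L),
    n_duplicate_pairs = 1)
  universe <- simulate_gene_universe(spec)
  cohort <- simulate_cohort(spec, universe, dir = out_dir)
  write_universe(universe, out_dir)
  invisible(list(spec = spec, universe = universe, cohort = cohort,
                 paths = cohort$paths))
}

#' Write / read a gene universe as plain-text files
#'
#' `genes.tsv` (models + covariates), `exons.tsv`, `contigs.fa`,
#' `context_rates.tsv` in `dir`.
#'
#' @param universe a `gene_universe`.
#' @param dir directory.
#' @return invisible directory path.
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(universe$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(universe$exons, file.path(dir, "exons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- character(2L * length(universe$seqs))
  fa[c(TRUE, FALSE)] <- paste0(">", names(universe$seqs))
  fa[c(FALSE, TRUE)] <- unname(universe$seqs)
  writeLines(fa, file.path(dir, "contigs.fa"))
  write_context_rates(universe$rates, file.path(dir, "context_rates.tsv"))
  invisible(dir)
}

#' @describeIn write_universe Read the universe back.
#' @export
read_universe <- function(dir) {
  genes <- utils::read.table(file.path(dir, "genes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  exons <- utils::read.table(file.path(dir, "exons.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "contigs.fa"))
  seqs <- stats::setNames(as.character(fa), names(fa))
  rates <- read_context_rates(file.path(dir, "context_rates.tsv"))
  capture <- GenomicRanges::reduce(GenomicRanges::GRanges(
    exons$contig,
    IRanges::IRanges(start = pmax(exons$start - 10L, 0L) + 1L,
                     end = exons$end + 10L)))
  out <- list(genes = genes, exons = exons, seqs = seqs, rates = rates,
              capture = capture, spec = NULL)
  class(out) <- "gene_universe"
  out
}

#' Count-level DNV simulation
#'
#' Draws per-gene de novo counts for whole replicate cohorts directly from
#' the Poisson process, without realizing variant sites — the fast path used
#' for calibration and power studies.
#'
#' @param lambda per-gene expected counts for one cohort.
#' @param replicates number of replicate cohorts.
#' @param fold optional per-gene fold multipliers.
#' @return integer matrix replicates x genes.
#' @export
simulate_dnv_counts <- function(lambda, replicates, fold = 1) {
  lam <- lambda * fold
  matrix(stats::rpois(replicates * length(lam), rep(lam, each = replicates)),
         nrow = replicates)
}

#' Count-level transmitted simulation
#'
#' Scatters a stratum total multinomially over genes by mutability weight.
#'
#' @param weights per-gene weights (need not be normalized).
#' @param L stratum total.
#' @param replicates number of replicates.
#' @return integer matrix genes x replicates.
#' @export
simulate_transmitted_counts <- function(weights, L, replicates) {
  stats::rmultinom(replicates, L, weights)
}
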