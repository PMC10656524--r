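#' Declarative run configuration
#'
#' All file paths and every analysis constant (filter thresholds, pLI
#' stratum boundaries, the frameshift scaling factor, the damaging missense
#' fraction, multiplicity divisors) with the published values as defaults.
#' Unknown keys are rejected so threshold typos cannot pass silently; the
#' effective configuration is echoed into the output directory by
#' [run_pipeline()].
#'
#' @param ... overrides of the default keys.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    vcf = NULL, ped = NULL, beds = NULL, universe_dir = NULL,
    out_dir = "results", seed = 1L,
    thresholds = filter_defaults(),
    pli_breaks = .pli_breaks,
    frameshift_factor = 1.25,
    dmis_fraction = 0.3,
    pli_min = 0.9,
    dnv_test_families = 3L,
    alpha = 0.05,
    dnv_maf_column = "maf_gnomad",
    trans_maf_column = "maf_bravo")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if ("thresholds" %in% names(dots)) {
    bad <- setdiff(names(dots$thresholds), names(cfg$thresholds))
    if (length(bad))
      stop("unknown threshold key(s): ", paste(bad, collapse = ", "))
    cfg$thresholds[names(dots$thresholds)] <- dots$thresholds
    dots$thresholds <- NULL
  }
  cfg[names(dots)] <- dots
  class(cfg) <- c("run_config", "list")
  cfg
}

#' @describeIn run_config Write a configuration as YAML.
#' @param cfg a `run_config`.
#' @param path file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @describeIn run_config Read a configuration back (round-trips losslessly;
#'   unknown keys are errors).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the analysis pipeline on a cohort
#'
#' Executes the stages in dependency order — cohort I/O, kinship/duplicate
#' QC, mutability model, DNV filtering and enrichment, transmitted filtering
#' and stratified enrichment — writing each stage's table under
#' `cfg$out_dir` and returning a manifest of stage statuses, row counts and
#' output checksums. Any stage failure halts with the stage name.
#'
#' @param cfg a [run_config()] with `vcf`, `ped`, `beds` and `universe_dir`
#'   set (as emitted by [simulate_cohort()] / [write_universe()]).
#' @return manifest list; also written as `manifest.yaml`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, stages = list())
  outputs <- character(0)
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- res
    res
  }
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  io <- stage("io", function() {
    ped <- read_pedigree(cfg$ped)
    capture <- union_capture(cfg$beds)
    calls <- read_variants(cfg$vcf, ped)
    universe <- read_universe(cfg$universe_dir)
    list(status = "ok", families = nrow(ped), variants = nrow(calls),
         capture_bases = attr(capture, "total_bases"),
         data = list(ped = ped, capture = capture, calls = calls,
                     universe = universe))
  })
  ped <- io$data$ped; calls <- io$data$calls; universe <- io$data$universe

  qc <- stage("qc", function() {
    vcf <- vcfR::read.vcfR(cfg$vcf, verbose = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dose <- matrix(0L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    dose[gt %in% c("0/1", "0|1", "1|0")] <- 1L
    dose[gt %in% c("1/1", "1|1")] <- 2L
    dose[is.na(gt)] <- NA_integer_
    dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    maf <- as.numeric(vcfR::extract.info(vcf, "AF_GNOMAD"))
    kin <- duplicate_and_kinship(dose, ped, ref_maf = maf,
                                 mean_depth = colMeans(dp, na.rm = TRUE),
                                 thresholds = cfg$thresholds)
    emit(kin$duplicates, "duplicates.tsv")
    emit(kin$ibd, "kinship.tsv")
    list(status = "ok", duplicates = nrow(kin$duplicates),
         flagged_pairs = sum(kin$ibd$flagged),
         data = list(exclude = setdiff(
           unlist(kin$duplicates[, c("sample1", "sample2")]),
           kin$duplicates$retained)))
  })

  mut <- stage("mutability", function() {
    g <- universe$genes
    has_p <- all(paste0("p_", .mutability_classes) %in% names(g))
    if (!has_p) {
      pm <- t(vapply(seq_len(nrow(g)), function(i) {
        ex <- universe$exons[universe$exons$gene_id == g$gene_id[i],
                             c("start", "end")]
        gene_mutability(universe$seqs[[g$contig[i]]], ex, g$strand[i],
                        universe$rates, capture = io$data$capture,
                        contig = g$contig[i])
      }, numeric(length(.mutability_classes))))
      colnames(pm) <- paste0("p_", .mutability_classes)
      g <- cbind(g, pm)
    }
    if (!("dmis_fraction" %in% names(g))) g$dmis_fraction <- cfg$dmis_fraction
    long <- data.frame(gene = rep(g$gene_id, length(.mutability_classes)),
                       class = rep(.mutability_classes, each = nrow(g)),
                       probability = unlist(g[paste0("p_",
                                                     .mutability_classes)]))
    emit(long, "mutability.tsv")
    list(status = "ok", genes = nrow(g), data = list(models = g))
  })
  models <- mut$data$models

  dnv <- stage("dnv", function() {
    cand <- calls[dnv_candidates(calls), , drop = FALSE]
    verdict <- dnv_filter(cand, maf_column = cfg$dnv_maf_column,
                          thresholds = cfg$thresholds)
    emit(cbind(cand[, c("chrom", "pos", "ref", "alt", "gene", "class",
                        "family_id")], verdict), "dnv_filtered.tsv")
    dnvs <- cand[verdict$passed, , drop = FALSE]
    n_trios <- sum(ped$type == "trio")
    tab <- class_enrichment_table(dnvs, models, n_trios,
                                  pli_min = cfg$pli_min)
    emit(tab, "dnv_class_enrichment.tsv")
    pg <- per_gene_dnv_test(dnvs, models, n_trios, alpha = cfg$alpha)
    emit(pg, "dnv_per_gene.tsv")
    dmg <- tab[tab$subset == "all" & tab$unit == "protein_damaging", ]
    af <- attributable_fraction(dmg$observed, dmg$expected, n_trios,
                                conf_level = 0.95)
    list(status = "ok", candidates = nrow(cand), passing = nrow(dnvs),
         attributable_fraction = as.numeric(af),
         data = list(dnvs = dnvs, class_table = tab, per_gene = pg))
  })

  trans <- stage("transmitted", function() {
    caf <- cohort_af(calls, ped, exclude = qc$data$exclude)
    verdict <- transmitted_filter(calls, caf,
                                  maf_column = cfg$trans_maf_column,
                                  thresholds = cfg$thresholds)
    emit(cbind(calls[, c("chrom", "pos", "ref", "alt", "gene", "class",
                         "family_id")], verdict), "transmitted_filtered.tsv")
    hits <- calls[verdict$passed & !dnv_candidates(calls), , drop = FALSE]
    obs <- table(hits$gene)
    mu <- stats::setNames(models$p_damaging, models$gene_id)
    res <- transmitted_enrichment(stats::setNames(as.integer(obs),
                                                  names(obs)),
                                  models, mu)
    emit(res, "transmitted_enrichment.tsv")
    list(status = "ok", qualifying = nrow(hits),
         L_k = as.list(attr(res, "L_k")), data = list(result = res))
  })

  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  write_run_config(cfg, cfg_path)
  manifest$outputs <- as.list(tools::md5sum(outputs))
  manifest$config <- cfg_path
  clean <- manifest
  clean$stages <- lapply(clean$stages, function(s) s[setdiff(names(s), "data")])
  yaml::write_yaml(clean, file.path(cfg$out_dir, "manifest.yaml"))
  invisible(manifest)
}
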