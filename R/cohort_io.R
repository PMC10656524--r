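#' Read a pedigree and resolve family roles
#'
#' Parses a 6-column whitespace-delimited PED file (family, sample, father,
#' mother, sex, phenotype) and classifies each family as a trio (both
#' parents sequenced), duo (one parent) or singleton (no parents). A parent
#' id that references a sample absent from the file demotes the family with
#' a warning; a sample id appearing in two families or twice is an error.
#'
#' @param path PED file path.
#' @return data.frame of class `pedigree` with one row per family:
#'   `family_id`, `proband_id`, `father_id`, `mother_id` (NA when absent),
#'   `proband_sex`, `affected`, `type` in trio/duo/singleton. Attribute
#'   `samples` maps every sequenced sample to its role.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family_id", "sample_id", "father_id",
                                         "mother_id", "sex", "phenotype"),
                           colClasses = c(rep("character", 4L), "integer", "integer"))
  if (anyDuplicated(ped$sample_id)) {
    dup <- unique(ped$sample_id[duplicated(ped$sample_id)])
    stop("duplicated sample id(s) in pedigree: ", paste(dup, collapse = ", "))
  }
  ped$father_id[ped$father_id == "0"] <- NA_character_
  ped$mother_id[ped$mother_id == "0"] <- NA_character_

  is_child <- !is.na(ped$father_id) | !is.na(ped$mother_id) | ped$phenotype == 2L
  fams <- split(ped, ped$family_id)
  rows <- lapply(fams, function(f) {
    child <- f[is_child[match(f$sample_id, ped$sample_id)], , drop = FALSE]
    if (nrow(child) == 0L && nrow(f) == 1L) child <- f  # lone unflagged sample
    if (nrow(child) != 1L)
      stop("family ", f$family_id[1L], ": expected exactly one proband, found ",
           nrow(child))
    fa <- child$father_id; mo <- child$mother_id
    for (p in c("father", "mother")) {
      id <- if (p == "father") fa else mo
      if (!is.na(id) && !(id %in% ped$sample_id)) {
        warning("family ", f$family_id[1L], ": ", p, " id '", id,
                "' not present as a sample; treating as missing")
        if (p == "father") fa <- NA_character_ else mo <- NA_character_
      }
    }
    n_par <- sum(!is.na(c(fa, mo)))
    data.frame(family_id = f$family_id[1L], proband_id = child$sample_id,
               father_id = fa, mother_id = mo, proband_sex = child$sex,
               affected = child$phenotype == 2L,
               type = c("singleton", "duo", "trio")[n_par + 1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  roles <- character(0)
  for (i in seq_len(nrow(out))) {
    roles[out$proband_id[i]] <- "proband"
    if (!is.na(out$father_id[i])) roles[out$father_id[i]] <- "father"
    if (!is.na(out$mother_id[i])) roles[out$mother_id[i]] <- "mother"
  }
  extra <- setdiff(ped$sample_id, names(roles))
  roles[extra] <- "other"
  attr(out, "samples") <- roles
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Count families of each configuration
#' @param pedigree a [read_pedigree()] result.
#' @return named integer vector over trio/duo/singleton.
#' @export
family_counts <- function(pedigree) {
  c(trio = sum(pedigree$type == "trio"),
    duo = sum(pedigree$type == "duo"),
    singleton = sum(pedigree$type == "singleton"))
}

#' Union of capture regions
#'
#' Reads one or more BED3 files (0-based half-open) and returns their union
#' as sorted, non-overlapping intervals — the unified capture used when
#' cohorts were captured with different reagents. The operation is
#' commutative, associative and idempotent over its inputs.
#'
#' @param beds character vector of BED file paths (>= 1).
#' @return `GRanges` of merged intervals with attribute `total_bases`.
#' @export
union_capture <- function(beds) {
  stopifnot(length(beds) >= 1L)
  grs <- lapply(beds, function(path) {
    df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("BED file ", path, " has fewer than 3 columns")
    names(df)[1:3] <- c("chrom", "start", "end")
    bad <- which(df$end <= df$start)
    if (length(bad))
      stop("malformed interval (end <= start) in ", path, " at line ", bad[1L])
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(start = df$start + 1L, end = df$end))
  })
  merged <- GenomicRanges::reduce(sort(do.call(c, grs)))
  attr(merged, "total_bases") <- sum(GenomicRanges::width(merged))
  merged
}

#' Write capture regions as BED3
#' @param capture a `GRanges`.
#' @param path output path.
#' @export
write_capture <- function(capture, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(capture)),
                   start = GenomicRanges::start(capture) - 1L,
                   end = GenomicRanges::end(capture))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# left-align is a no-op for plain substitutions; for indels, trim the common
# suffix then the common prefix, adjusting pos (1-based) for prefix trimming
normalize_allele <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

.num_or_na <- function(x) suppressWarnings(as.numeric(x))

# pull FORMAT fields for one sample into a prefix-named data.frame
.sample_fields <- function(gt_elem, prefix, n) {
  if (is.null(gt_elem)) {
    return(stats::setNames(
      data.frame(gt = NA_character_, dp = NA_real_, ad_alt = NA_real_,
                 gq = NA_real_, stringsAsFactors = FALSE)[rep(1L, n), ],
      paste0(prefix, c("_gt", "_dp", "_ad_alt", "_gq"))))
  }
  gt_elem
}

#' Read trio variant calls from a VCF
#'
#' Parses a VCF 4.2 with GT, AD, DP and GQ FORMAT fields and returns one
#' record per (variant, family). Multi-allelic sites are decomposed into
#' biallelic records (per-allele AD resolved by allele index); indel alleles
#' are normalized by trimming before matching; missing FORMAT values
#' propagate as NA, never as zero. Annotations (gene, functional class,
#' MetaSVM, MPC, population frequencies) are read from configurable INFO
#' keys, optionally overridden by a side-car table keyed by
#' (chrom, pos, ref, alt).
#'
#' @param path VCF file path.
#' @param pedigree a [read_pedigree()] result; every sample referenced by the
#'   pedigree must be present in the VCF.
#' @param info_keys named list mapping the fields `gene`, `class`, `metasvm`,
#'   `mpc` and any number of `maf_*` frequency fields to INFO keys.
#' @param annotations optional side-car data.frame with columns chrom, pos,
#'   ref, alt plus annotation columns; values override INFO-derived ones.
#' @return data.frame with one row per (variant, family): site fields
#'   (`chrom`, `pos`, `ref`, `alt`, `vqsr_pass`), annotations, and per-member
#'   genotype/support columns `pro_*`, `fa_*`, `mo_*` (gt, dp, ad_alt, gq).
#' @export
read_variants <- function(path, pedigree,
                          info_keys = list(gene = "GENE", class = "CLASS",
                                           metasvm = "METASVM", mpc = "MPC",
                                           maf_gnomad = "AF_GNOMAD",
                                           maf_bravo = "AF_BRAVO"),
                          annotations = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  samples <- colnames(gt)[-1L]

  need <- unique(stats::na.omit(c(pedigree$proband_id, pedigree$father_id,
                                  pedigree$mother_id)))
  missing <- setdiff(need, samples)
  if (length(missing))
    stop("pedigree sample(s) absent from VCF: ", paste(missing, collapse = ", "))

  gt_m <- vcfR::extract.gt(vcf, element = "GT")
  dp_m <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  gq_m <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
  ad_m <- vcfR::extract.gt(vcf, element = "AD")

  info_field <- function(key) {
    if (is.null(key)) return(rep(NA_character_, nrow(fix)))
    vcfR::extract.info(vcf, element = key)
  }
  anno <- list()
  for (nm in names(info_keys)) anno[[nm]] <- info_field(info_keys[[nm]])

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  site_i <- rep(seq_len(nrow(fix)), n_alt)
  allele_i <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

  pos <- as.integer(fix$POS)[site_i]
  ref <- fix$REF[site_i]
  alt <- unlist(alts, use.names = FALSE)
  norm <- Map(normalize_allele, pos, ref, alt)
  pos <- vapply(norm, `[[`, integer(1L), "pos")
  ref <- vapply(norm, `[[`, character(1L), "ref")
  alt <- vapply(norm, `[[`, character(1L), "alt")

  rec <- data.frame(chrom = fix$CHROM[site_i], pos = pos, ref = ref, alt = alt,
                    vqsr_pass = fix$FILTER[site_i] %in% c("PASS", "."),
                    stringsAsFactors = FALSE)
  for (nm in names(anno)) {
    v <- anno[[nm]][site_i]
    # per-allele annotations may be comma-separated in allele order
    multi <- grepl(",", v, fixed = TRUE)
    if (any(multi & n_alt[site_i] > 1L)) {
      parts <- strsplit(v, ",", fixed = TRUE)
      v <- mapply(function(p, i) if (length(p) >= i) p[i] else p[1L],
                  parts, allele_i)
    }
    rec[[nm]] <- if (nm %in% c("mpc") || startsWith(nm, "maf")) .num_or_na(v) else v
  }
  if (!is.null(annotations)) {
    key <- paste(rec$chrom, rec$pos, rec$ref, rec$alt, sep = ":")
    akey <- paste(annotations$chrom, annotations$pos, annotations$ref,
                  annotations$alt, sep = ":")
    hit <- match(key, akey)
    for (nm in setdiff(names(annotations), c("chrom", "pos", "ref", "alt"))) {
      v <- annotations[[nm]][hit]
      rec[[nm]] <- ifelse(is.na(hit), rec[[nm]], v)
    }
  }
  fq <- grep("^maf", names(rec), value = TRUE)
  for (nm in fq) {
    bad <- !is.na(rec[[nm]]) & (rec[[nm]] < 0 | rec[[nm]] > 1)
    if (any(bad)) stop("frequency column ", nm, " outside [0, 1]")
  }

  member <- function(ids) {
    idx <- match(ids, samples)
    pick <- function(m) {
      v <- matrix(NA, nrow = length(site_i), ncol = 1L)
      ok <- !is.na(idx)
      v[ok] <- m[cbind(site_i[ok], idx[ok])]
      v[, 1L]
    }
    gt_v <- pick(gt_m)
    dp_v <- as.numeric(pick(dp_m))
    gq_v <- as.numeric(pick(gq_m))
    ad_raw <- pick(ad_m)
    ad_alt <- rep(NA_real_, length(site_i))
    has_ad <- !is.na(ad_raw)
    if (any(has_ad)) {
      parts <- strsplit(ad_raw[has_ad], ",", fixed = TRUE)
      ai <- allele_i[has_ad]
      ad_alt[has_ad] <- mapply(function(p, i)
        if (length(p) > i) .num_or_na(p[i + 1L]) else NA_real_, parts, ai)
    }
    # genotype relative to this alt allele: count matching allele index
    gt_bi <- rep(NA_character_, length(site_i))
    has_gt <- !is.na(gt_v) & gt_v != "."
    if (any(has_gt)) {
      al <- strsplit(gsub("|", "/", gt_v[has_gt], fixed = TRUE), "/", fixed = TRUE)
      tgt <- as.character(allele_i[has_gt])
      gt_bi[has_gt] <- vapply(seq_along(al), function(j) {
        a <- al[[j]]
        if (any(a == ".")) return(NA_character_)
        paste(sort(as.integer(a == tgt[j])), collapse = "/")
      }, character(1L))
    }
    # DP missing but AD present: DP := sum(AD)
    fix_dp <- is.na(dp_v) & has_ad
    if (any(fix_dp)) {
      dp_v[fix_dp] <- vapply(strsplit(ad_raw[fix_dp], ",", fixed = TRUE),
                             function(p) sum(.num_or_na(p)), numeric(1L))
    }
    bad <- !is.na(ad_alt) & !is.na(dp_v) & ad_alt > dp_v
    if (any(bad)) stop("AD_alt exceeds DP for some records")
    data.frame(gt = gt_bi, dp = dp_v, ad_alt = ad_alt, gq = gq_v,
               stringsAsFactors = FALSE)
  }

  out <- vector("list", nrow(pedigree))
  for (i in seq_len(nrow(pedigree))) {
    pro <- member(rep(pedigree$proband_id[i], 1L))
    fa <- member(rep(pedigree$father_id[i], 1L))
    mo <- member(rep(pedigree$mother_id[i], 1L))
    names(pro) <- paste0("pro_", names(pro))
    names(fa) <- paste0("fa_", names(fa))
    names(mo) <- paste0("mo_", names(mo))
    block <- cbind(rec,
                   data.frame(family_id = pedigree$family_id[i],
                              family_type = pedigree$type[i],
                              stringsAsFactors = FALSE),
                   pro, fa, mo)
    # keep records where the family carries the allele or has any alt evidence
    carries <- !is.na(block$pro_gt) & block$pro_gt != "0/0" |
      !is.na(block$fa_gt) & block$fa_gt != "0/0" |
      !is.na(block$mo_gt) & block$mo_gt != "0/0"
    out[[i]] <- block[carries, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a cohort variant summary TSV
#' @param calls data.frame from [read_variants()].
#' @param path output path.
#' @export
write_cohort_summary <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
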