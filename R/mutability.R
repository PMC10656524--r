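#' Per-site, per-alternative mutation probabilities
#'
#' For every interior base of a sequence (flanking bases provide context),
#' look up the context-specific rate of mutating to each of the three
#' alternative bases. Sites whose trinucleotide context contains a non-ACGT
#' character are skipped (returned as NA rows) and counted.
#'
#' @param seq a single DNA string, length >= 3.
#' @param rates a [context_rate_table()].
#' @return numeric matrix of shape `(nchar(seq) - 2, 3)`; row i corresponds
#'   to sequence position i + 1. Attribute `alt` holds the matching matrix of
#'   alternative bases (alphabetical per row), attribute `skipped` the number
#'   of skipped sites.
#' @export
per_base_probabilities <- function(seq, rates) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3L) stop("sequence must have length >= 3")
  lk <- rate_lookup(rates)
  pos <- 2:(n - 1L)
  ctx <- substring(seq, pos - 1L, pos + 1L)
  ref <- substring(seq, pos, pos)
  bases <- c("A", "C", "G", "T")
  ok <- grepl("^[ACGT]{3}$", ctx)
  alt <- t(vapply(ref, function(r) if (r %in% bases) setdiff(bases, r) else rep(NA_character_, 3L),
                  character(3L)))
  out <- matrix(NA_real_, nrow = length(pos), ncol = 3L,
                dimnames = list(pos, c("alt1", "alt2", "alt3")))
  if (any(ok)) {
    key <- paste0(rep(ctx[ok], each = 3L), ">", as.vector(t(alt[ok, , drop = FALSE])))
    out[ok, ] <- matrix(lk[key], ncol = 3L, byrow = TRUE)
  }
  structure(out, alt = alt, skipped = sum(!ok))
}

.stop_codons <- c("TAA", "TAG", "TGA")

#' Functional classification of a coding substitution
#'
#' Deterministic consequence of substituting one base of a coding sequence,
#' from the standard genetic code: any change in the initiator codon is a
#' start-loss (ATG has no synonym), a change of the terminator codon to a
#' non-stop codon is a stop-loss, a change creating an in-frame stop is a
#' stop-gain, and remaining changes are synonymous or missense by amino-acid
#' identity. Canonical splice-site positions are handled by
#' [gene_mutability()], not here.
#'
#' @param cds coding sequence (single string, length a multiple of 3,
#'   start codon first, stop codon last).
#' @param pos 1-based position(s) within `cds`.
#' @param alt replacement base(s) on the coding strand; must differ from the
#'   reference base.
#' @return character vector of classes among `synonymous`, `missense`,
#'   `stopgain`, `stoploss`, `startloss`.
#' @export
classify_substitution <- function(cds, pos, alt) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("coding sequence length must be a multiple of 3")
  pos <- as.integer(pos)
  alt <- toupper(as.character(alt))
  if (length(alt) == 1L) alt <- rep(alt, length(pos))
  stopifnot(length(alt) == length(pos))
  if (any(pos < 1L | pos > n)) stop("position outside the modeled transcript")
  ref <- substring(cds, pos, pos)
  if (any(ref == alt)) stop("alt must differ from the reference base")
  codon_i <- (pos - 1L) %/% 3L             # 0-based codon index
  cstart <- codon_i * 3L + 1L
  old <- substring(cds, cstart, cstart + 2L)
  off <- (pos - 1L) %% 3L
  new <- old
  substr(new, off + 1L, off + 1L) <- alt
  gc <- Biostrings::GENETIC_CODE
  aa_old <- unname(gc[old])
  aa_new <- unname(gc[new])
  last_i <- n %/% 3L - 1L
  cls <- ifelse(codon_i == 0L, "startloss",
         ifelse(codon_i == last_i,
                ifelse(new %in% .stop_codons, "synonymous", "stoploss"),
         ifelse(aa_new == "*", "stopgain",
         ifelse(aa_new == aa_old, "synonymous", "missense"))))
  cls
}

.mutability_classes <- c("synonymous", "missense", "splice_canonical",
                         "stopgain", "stoploss", "startloss", "frameshift")

#' Gene-level mutation probabilities by functional class
#'
#' Sums per-site, per-alternative context rates over the captured coding
#' bases of a gene, classified by coding consequence, plus the canonical
#' splice positions (the two intronic bases flanking each internal exon
#' boundary). The frameshift probability is not modeled from sequence: it is
#' set to 1.25 times the stop-gain probability after summation. In-frame
#' indels are not modeled.
#'
#' @param contig_seq sequence of the contig carrying the gene (single string).
#' @param exons data.frame/matrix with columns `start`, `end`: 0-based
#'   half-open exon intervals on `contig_seq`, ascending and non-overlapping.
#' @param strand `"+"` or `"-"`.
#' @param rates a [context_rate_table()].
#' @param capture optional `GRanges` of captured intervals; when supplied,
#'   only overlapping bases contribute. `contig` names the contig to match
#'   against `capture` seqnames.
#' @param contig contig name (required when `capture` is given).
#' @param depth_mult per-gene sequencing-depth multiplier in \[0, 1\];
#'   defaults to 1 when no coverage summary is available.
#' @return named numeric vector of per-generation haploid probabilities for
#'   classes synonymous, missense, splice_canonical, stopgain, stoploss,
#'   startloss, frameshift. Attribute `skipped` counts non-ACGT sites.
#' @export
gene_mutability <- function(contig_seq, exons, strand = "+", rates,
                            capture = NULL, contig = NULL, depth_mult = 1) {
  stopifnot(is.character(contig_seq), length(contig_seq) == 1L)
  contig_seq <- toupper(contig_seq)
  exons <- as.data.frame(exons)
  stopifnot(all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$end <= exons$start)) stop("malformed exon interval (end <= start)")
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("exons must be non-overlapping")
  stopifnot(strand %in% c("+", "-"))
  if (!is.finite(depth_mult) || depth_mult < 0 || depth_mult > 1)
    stop("depth_mult must be in [0, 1]")

  n <- nchar(contig_seq)
  cds_len <- sum(exons$end - exons$start)
  if (cds_len == 0L) stop("missing transcript sequence (no exon bases)")
  if (cds_len %% 3L != 0L) stop("coding length must be a multiple of 3")

  pos0 <- unlist(Map(function(s, e) seq.int(s, e - 1L), exons$start, exons$end),
                 use.names = FALSE)                       # 0-based genomic
  exseq <- substring(contig_seq, exons$start + 1L, exons$end)
  cds <- paste(exseq, collapse = "")
  if (strand == "-") cds <- revcomp(cds)
  cds_idx <- if (strand == "+") seq_along(pos0) else rev(seq_along(pos0))

  in_capture <- function(p0) {
    if (is.null(capture)) return(rep(TRUE, length(p0)))
    if (is.null(contig)) stop("contig name required when capture is supplied")
    gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start = p0 + 1L, width = 1L))
    GenomicRanges::countOverlaps(gr, capture) > 0L
  }

  p <- stats::setNames(numeric(length(.mutability_classes)), .mutability_classes)
  skipped <- 0L
  bases <- c("A", "C", "G", "T")
  lk <- rate_lookup(rates)

  keep <- in_capture(pos0)
  if (!any(keep) && nrow(exons) > 0L)
    warning("gene does not intersect the capture region; probabilities are 0")
  if (any(keep)) {
    gpos <- pos0[keep]
    cpos <- cds_idx[keep]
    valid_ctx <- gpos >= 1L & gpos <= n - 2L
    ctx <- rep(NA_character_, length(gpos))
    ctx[valid_ctx] <- substring(contig_seq, gpos[valid_ctx], gpos[valid_ctx] + 2L)
    ref <- substring(contig_seq, gpos + 1L, gpos + 1L)
    ok <- !is.na(ctx) & grepl("^[ACGT]{3}$", ctx) & ref %in% bases
    skipped <- skipped + sum(!ok)
    if (any(ok)) {
      gpos <- gpos[ok]; cpos <- cpos[ok]; ctx <- ctx[ok]; ref <- ref[ok]
      alt <- lapply(ref, function(r) setdiff(bases, r))
      alt_flat <- unlist(alt, use.names = FALSE)
      ctx_flat <- rep(ctx, each = 3L)
      cpos_flat <- rep(cpos, each = 3L)
      rate_flat <- unname(lk[paste0(ctx_flat, ">", alt_flat)])
      cds_alt <- if (strand == "+") alt_flat else chartr("ACGT", "TGCA", alt_flat)
      cls <- classify_substitution(cds, cpos_flat, cds_alt)
      agg <- tapply(rate_flat, cls, sum)
      p[names(agg)] <- p[names(agg)] + agg
    }
  }

  # canonical splice sites: +-2 intronic bases at each internal exon boundary
  if (nrow(exons) > 1L) {
    m <- nrow(exons)
    sp0 <- c(outer(exons$end[-m], 0:1, `+`),          # donor side
             outer(exons$start[-1L], -(2:1), `+`))    # acceptor side
    sp0 <- sort(unique(sp0))
    sp0 <- sp0[!(sp0 %in% pos0)]                      # intronic only
    sp0 <- sp0[in_capture(sp0)]
    valid <- sp0 >= 1L & sp0 <= n - 2L
    skipped <- skipped + sum(!valid)
    sp0 <- sp0[valid]
    if (length(sp0)) {
      ctx <- substring(contig_seq, sp0, sp0 + 2L)
      ref <- substring(contig_seq, sp0 + 1L, sp0 + 1L)
      ok <- grepl("^[ACGT]{3}$", ctx) & ref %in% bases
      skipped <- skipped + sum(!ok)
      if (any(ok)) {
        ctx <- ctx[ok]; ref <- ref[ok]
        alt_flat <- unlist(lapply(ref, function(r) setdiff(bases, r)), use.names = FALSE)
        key <- paste0(rep(ctx, each = 3L), ">", alt_flat)
        p["splice_canonical"] <- p["splice_canonical"] + sum(lk[key])
      }
    }
  }

  p["frameshift"] <- 1.25 * p[["stopgain"]]
  structure(p * depth_mult, skipped = skipped)
}

#' Damaging mutability of a gene
#'
#' The mutability mass feeding damaging-variant expectations: all LoF classes
#' (stop-gain, stop-loss, start-loss, canonical splice, frameshift) plus the
#' fraction of the missense mass annotated damaging. The context model cannot
#' label which individual missense changes are MetaSVM-deleterious or
#' MPC >= 2, so a per-gene `dmis_fraction` partitions the missense
#' probability.
#'
#' @param p_class named vector from [gene_mutability()].
#' @param dmis_fraction fraction of missense probability mass that is
#'   damaging, in \[0, 1\].
#' @param lof_only if TRUE, exclude the missense contribution entirely.
#' @return single damaging per-generation haploid probability.
#' @export
damaging_mutability <- function(p_class, dmis_fraction = 0.3, lof_only = FALSE) {
  stopifnot(dmis_fraction >= 0, dmis_fraction <= 1)
  lof <- sum(p_class[c("stopgain", "stoploss", "startloss",
                       "splice_canonical", "frameshift")])
  if (lof_only) lof else lof + dmis_fraction * p_class[["missense"]]
}

#' Expected de novo count for a cohort
#'
#' A per-generation haploid probability `p` yields `2 * n_trios * p` expected
#' events over the diploid genomes of `n_trios` probands.
#'
#' @param p haploid per-generation probability (scalar or vector).
#' @param n_trios number of complete trios.
#' @return expected count(s).
#' @export
expected_dnv_count <- function(p, n_trios) {
  if (any(p < 0) || n_trios < 0) stop("negative inputs")
  2 * n_trios * p
}

#' Per-gene depth adjustment multipliers
#'
#' The expectation model is attenuated in genes with incomplete sequencing
#' coverage. The input is a per-gene coverage summary: the fraction of the
#' gene's captured coding bases attaining at least `k` independent reads in
#' at least a fraction `f` of samples (the cohort-level coverage QC
#' statistic). The multiplier is that fraction; genes absent from the summary
#' default to 1.
#'
#' @param coverage data.frame with columns `gene_id` and `frac_covered`, or
#'   NULL for no adjustment.
#' @param gene_ids character vector of genes needing multipliers.
#' @return named numeric vector of multipliers in \[0, 1\].
#' @export
depth_adjustment <- function(coverage = NULL, gene_ids) {
  mult <- stats::setNames(rep(1, length(gene_ids)), gene_ids)
  if (!is.null(coverage)) {
    stopifnot(all(c("gene_id", "frac_covered") %in% names(coverage)))
    if (any(coverage$frac_covered < 0 | coverage$frac_covered > 1))
      stop("frac_covered must be in [0, 1]")
    hit <- intersect(coverage$gene_id, gene_ids)
    mult[hit] <- coverage$frac_covered[match(hit, coverage$gene_id)]
  }
  mult
}
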