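# Cached fixture suite: generated once per test process
.fixture_env <- new.env(parent = emptyenv())

fixture_suite <- function() {
  if (is.null(.fixture_env$fx)) {
    dir <- file.path(tempdir(), "trioburden-fixture")
    .fixture_env$fx <- emit_fixture_suite(dir)
    .fixture_env$ped <- read_pedigree(.fixture_env$fx$paths[["ped"]])
    .fixture_env$calls <- read_variants(.fixture_env$fx$paths[["vcf"]],
                                        .fixture_env$ped)
    .fixture_env$caf <- cohort_af(.fixture_env$calls, .fixture_env$ped)
  }
  .fixture_env
}

# ---- independent brute-force oracles ---------------------------------------

# Poisson upper tail by direct forward term summation from k = observed
oracle_poisson_upper <- function(obs, lambda) {
  if (obs == 0) return(1)
  term <- exp(obs * log(lambda) - lambda - lgamma(obs + 1))
  total <- term
  k <- obs
  repeat {
    k <- k + 1
    term <- term * lambda / k
    total <- total + term
    if (term < total * 1e-18 && k > obs + 10) break
    if (k > obs + 10000) break
  }
  total
}

# Binomial upper tail P(X >= k) by direct pmf summation via lchoose
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  ks <- k:n
  sum(exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)))
}

# One-sided Fisher p by enumeration over all tables with the same margins
oracle_fisher_upper <- function(a, b, c_, d) {
  m <- a + c_; n2 <- b + d; size <- a + b; N <- m + n2
  ks <- max(0, size - n2):min(m, size)
  pk <- exp(lchoose(m, ks) + lchoose(n2, size - ks) - lchoose(N, size))
  sum(pk[ks >= a])
}

# Substitution consequence by whole-protein comparison through
# Biostrings::translate (an independent route to the genetic code).
# no.init.codon: translate literally (the annotation convention treats any
# change of the ATG initiator as start-loss, incl. to CTG/TTG).
oracle_classify_many <- function(cds, pos, alt) {
  muts <- vapply(seq_along(pos), function(i) {
    m <- cds
    substr(m, pos[i], pos[i]) <- alt[i]
    m
  }, character(1))
  tr <- function(set) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(set),
                                             no.init.codon = TRUE,
                                             if.fuzzy.codon = "solve"))
    do.call(rbind, strsplit(aa, ""))
  }
  aa0 <- tr(cds)[1, ]
  aa1 <- tr(muts)
  n <- length(aa0)
  vapply(seq_along(pos), function(i) {
    a1 <- aa1[i, ]
    if (a1[1] != "M") return("startloss")
    if (aa0[n] == "*" && a1[n] != "*") return("stoploss")
    if (any(a1[-c(1, n)] == "*" & aa0[-c(1, n)] != "*")) return("stopgain")
    if (identical(aa0, a1)) return("synonymous")
    "missense"
  }, character(1))
}

oracle_classify <- function(cds, pos, alt) oracle_classify_many(cds, pos, alt)

# Gene mutability by exhaustive enumeration with oracle classification
oracle_gene_mutability <- function(contig_seq, exons, strand, rates,
                                   captured_pos0 = NULL) {
  exons <- exons[order(exons$start), , drop = FALSE]
  pos0 <- unlist(Map(function(s, e) seq.int(s, e - 1L), exons$start,
                     exons$end))
  cds <- paste(substring(contig_seq, exons$start + 1L, exons$end),
               collapse = "")
  if (strand == "-") cds <- revcomp(cds)
  cds_idx <- if (strand == "+") seq_along(pos0) else rev(seq_along(pos0))
  lk <- stats::setNames(rates$rate, paste0(rates$context, ">", rates$alt))
  p <- stats::setNames(numeric(7),
                       c("synonymous", "missense", "splice_canonical",
                         "stopgain", "stoploss", "startloss", "frameshift"))
  sub_pos <- integer(0); sub_alt <- character(0); sub_rate <- numeric(0)
  for (i in seq_along(pos0)) {
    g0 <- pos0[i]
    if (!is.null(captured_pos0) && !(g0 %in% captured_pos0)) next
    ctx <- substr(contig_seq, g0, g0 + 2L)
    ref <- substr(contig_seq, g0 + 1L, g0 + 1L)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      cds_alt <- if (strand == "+") alt else chartr("ACGT", "TGCA", alt)
      sub_pos <- c(sub_pos, cds_idx[i])
      sub_alt <- c(sub_alt, cds_alt)
      sub_rate <- c(sub_rate, lk[[paste0(ctx, ">", alt)]])
    }
  }
  if (length(sub_pos)) {
    cls <- oracle_classify_many(cds, sub_pos, sub_alt)
    agg <- tapply(sub_rate, cls, sum)
    p[names(agg)] <- p[names(agg)] + agg
  }
  if (nrow(exons) > 1L) {
    m <- nrow(exons)
    sp0 <- sort(unique(c(outer(exons$end[-m], 0:1, `+`),
                         outer(exons$start[-1L], -(2:1), `+`))))
    sp0 <- setdiff(sp0, pos0)
    for (g0 in sp0) {
      if (!is.null(captured_pos0) && !(g0 %in% captured_pos0)) next
      ctx <- substr(contig_seq, g0, g0 + 2L)
      ref <- substr(contig_seq, g0 + 1L, g0 + 1L)
      for (alt in setdiff(c("A", "C", "G", "T"), ref))
        p["splice_canonical"] <- p["splice_canonical"] +
          lk[[paste0(ctx, ">", alt)]]
    }
  }
  p["frameshift"] <- 1.25 * p[["stopgain"]]
  p
}

# small single-exon gene on a padded contig
toy_gene <- function(cds, flank = "TTTTTTTTTT") {
  list(contig = paste0(flank, cds, flank),
       exons = data.frame(start = nchar(flank),
                          end = nchar(flank) + nchar(cds)))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
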