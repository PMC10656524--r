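test_that("per-base probabilities follow the context table", {
  flat <- flat_context_rates(1e-8)
  pb <- per_base_probabilities("AAA", flat)
  expect_equal(dim(pb), c(1L, 3L))
  expect_equal(unname(pb[1, ]), rep(1e-8, 3))
  expect_equal(dim(per_base_probabilities("ACGT", flat)), c(2L, 3L))

  # inflate one context and check only matching sites move (brute-force
  # per-site lookup)
  df <- as.data.frame(flat)
  df$rate[df$context == "ACG" & df$alt == "T"] <- 5e-7
  inflated <- context_rate_table(df)
  seq <- "TACGACGTT"
  pb2 <- per_base_probabilities(seq, inflated)
  alt <- attr(pb2, "alt")
  for (i in seq_len(nrow(pb2))) {
    ctx <- substr(seq, i, i + 2)
    for (j in 1:3) {
      want <- if (ctx == "ACG" && alt[i, j] == "T") 5e-7 else 1e-8
      expect_equal(pb2[i, j], want)
    }
  }
  # non-ACGT context is skipped and counted
  pbn <- per_base_probabilities("ANAA", flat)
  expect_equal(attr(pbn, "skipped"), 2L)
})

test_that("substitution classification matches the genetic code", {
  cds <- "ATGGCTAAGTGA"
  # third-codon wobble with the same amino acid
  expect_equal(classify_substitution(cds, 6, "A"), "synonymous")  # GCT->GCA
  # creating TAA in frame
  expect_equal(classify_substitution(cds, 7, "T"), "stopgain")    # AAG->TAG
  expect_error(classify_substitution(cds, 13, "A"), "outside")
  expect_error(classify_substitution(cds, 5, "C"), "differ")
})

test_that("all nine substitutions of each codon agree with a translation oracle", {
  set.seed(11)
  for (rep in 1:4) {
    interior <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                               c("TAA", "TAG", "TGA")), 6)
    cds <- paste0("ATG", paste(interior, collapse = ""), "TAA")
    for (pos in seq_len(nchar(cds))) {
      ref <- substr(cds, pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        expect_equal(classify_substitution(cds, pos, alt),
                     oracle_classify(cds, pos, alt),
                     info = paste(cds, pos, alt))
      }
    }
  }
})

test_that("gene mutability equals exhaustive enumeration", {
  set.seed(21)
  df <- as.data.frame(flat_context_rates(1e-8))
  df$rate <- exp(log(1e-8) + rnorm(nrow(df), 0, 0.5))
  key <- paste0(df$context, ">", df$alt)
  comp <- paste0(revcomp(df$context), ">", revcomp(df$alt))
  df$rate <- df$rate[match(pmin(key, comp), key)]
  rates <- context_rate_table(df)

  # 30-bp toy ORF, fully captured, single exon
  g <- toy_gene("ATGGCTAAGTTTCCCGGGACGCATGAGTGA")
  p <- gene_mutability(g$contig, g$exons, "+", rates)
  o <- oracle_gene_mutability(g$contig, g$exons, "+", rates)
  expect_equal(unclass(p)[names(o)], o, tolerance = 1e-12,
               ignore_attr = TRUE)

  # multi-exon gene with splice sites
  cds <- "ATGGCTAAGTTTCCCGGGACGCATGAGTGA"
  contig <- paste0("TTTTTTTTTT", substr(cds, 1, 15), "GTAAGCATTTTTCAG",
                   substr(cds, 16, 30), "TTTTTTTTTT")
  exons <- data.frame(start = c(10L, 40L), end = c(25L, 55L))
  p2 <- gene_mutability(contig, exons, "+", rates)
  o2 <- oracle_gene_mutability(contig, exons, "+", rates)
  expect_equal(unclass(p2)[names(o2)], o2, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_gt(p2[["splice_canonical"]], 0)
})

test_that("the frameshift probability is 1.25 times stop-gain for every gene", {
  fx <- fixture_suite()
  g <- fx$fx$universe$genes
  nz <- g$p_stopgain > 0
  expect_true(all(abs(g$p_frameshift[nz] / g$p_stopgain[nz] - 1.25) < 1e-12))
  expect_true(all(g$p_frameshift[!nz] == 0))
})

test_that("capture restriction removes excluded bases and is monotone", {
  rates <- flat_context_rates(1e-8)
  g <- toy_gene("ATGGCTAAGTTTCCCGGGACGCATGAGTGA")
  full <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, nchar(g$contig)))
  half <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 25))  # first 15 cds bases
  p_full <- gene_mutability(g$contig, g$exons, "+", rates,
                            capture = full, contig = "c1")
  p_half <- gene_mutability(g$contig, g$exons, "+", rates,
                            capture = half, contig = "c1")
  o_half <- oracle_gene_mutability(g$contig, g$exons, "+",
                                   as.data.frame(rates),
                                   captured_pos0 = 0:24)
  expect_equal(unclass(p_half)[names(o_half)], o_half, tolerance = 1e-12,
               ignore_attr = TRUE)
  # enlarging the capture never decreases any class probability
  expect_true(all(p_full >= p_half - 1e-15))
  # disjoint capture: zero with a warning
  off <- GenomicRanges::GRanges("c1", IRanges::IRanges(200, 300))
  expect_warning(p0 <- gene_mutability(g$contig, g$exons, "+", rates,
                                       capture = off, contig = "c1"),
                 "capture")
  expect_true(all(p0 == 0))
})

test_that("class probabilities conserve the per-base total", {
  set.seed(31)
  df <- as.data.frame(flat_context_rates(1e-8))
  df$rate <- exp(log(1e-8) + rnorm(nrow(df), 0, 0.4))
  rates <- context_rate_table(df)
  g <- toy_gene("ATGGCTAAGTTTCCCGGGACGCATGAGTGA")
  p <- gene_mutability(g$contig, g$exons, "+", rates)
  # before frameshift augmentation: class sums = sum of all per-base rates
  # over the coding positions
  s <- g$exons$start
  e <- g$exons$end
  lk <- stats::setNames(rates$rate, paste0(rates$context, ">", rates$alt))
  total <- 0
  for (g0 in s:(e - 1L)) {
    ctx <- substr(g$contig, g0, g0 + 2L)
    ref <- substr(g$contig, g0 + 1L, g0 + 1L)
    for (alt in setdiff(c("A", "C", "G", "T"), ref))
      total <- total + lk[[paste0(ctx, ">", alt)]]
  }
  expect_equal(sum(p) - p[["frameshift"]], total, tolerance = 1e-12)
})

test_that("mutability is strand-invariant under table complementation", {
  set.seed(41)
  df <- as.data.frame(flat_context_rates(1e-8))
  df$rate <- exp(log(1e-8) + rnorm(nrow(df), 0, 0.5))  # deliberately asymmetric
  rates <- context_rate_table(df)
  cds <- "ATGGCTAAGTTTCCCGGGACGCATGAGTGA"
  contig <- paste0("AACCGGTTAA", substr(cds, 1, 15), "GTAAGCATTTTTCAG",
                   substr(cds, 16, 30), "AATTCCGGAA")
  exons <- data.frame(start = c(10L, 40L), end = c(25L, 55L))
  p_fwd <- gene_mutability(contig, exons, "+", rates)
  len <- nchar(contig)
  contig_rc <- revcomp(contig)
  exons_rc <- data.frame(start = len - exons$end[2:1],
                         end = len - exons$start[2:1])
  p_rev <- gene_mutability(contig_rc, exons_rc, "-",
                           complement_context_rates(rates))
  expect_equal(unclass(p_fwd), unclass(p_rev), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("expected DNV counts scale as 2 N p and match simulation", {
  expect_equal(expected_dnv_count(1e-5, 90), 1.8e-3)
  expect_equal(expected_dnv_count(0, 90), 0)
  expect_error(expected_dnv_count(-1e-5, 90), "negative")
  set.seed(51)
  p <- c(2e-4, 5e-4, 1e-3)
  lam <- expected_dnv_count(p, 90)
  sims <- simulate_dnv_counts(lam, 20000)
  mc_se <- sqrt(lam / 20000)
  expect_true(all(abs(colMeans(sims) - lam) < 4 * mc_se))
})

test_that("depth adjustment defaults to one and applies coverage fractions", {
  m <- depth_adjustment(NULL, c("a", "b"))
  expect_equal(unname(m), c(1, 1))
  m2 <- depth_adjustment(data.frame(gene_id = "a", frac_covered = 0.8),
                         c("a", "b"))
  expect_equal(unname(m2), c(0.8, 1))
  expect_error(depth_adjustment(data.frame(gene_id = "a",
                                           frac_covered = 1.2), "a"),
               "frac_covered")
  rates <- flat_context_rates(1e-8)
  g <- toy_gene("ATGGCTAAGTGA")
  p1 <- gene_mutability(g$contig, g$exons, "+", rates, depth_mult = 1)
  p2 <- gene_mutability(g$contig, g$exons, "+", rates, depth_mult = 0.5)
  expect_equal(unclass(p2), unclass(p1) * 0.5, ignore_attr = TRUE)
})
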