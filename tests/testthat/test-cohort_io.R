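test_that("pedigree roles resolve trios, duos and singletons", {
  ped <- read_pedigree(write_lines_tmp(c(
    "F1 F1-c F1-f F1-m 1 2",
    "F1 F1-f 0 0 1 1",
    "F1 F1-m 0 0 2 1",
    "F2 F2-c F2-f 0 2 2",
    "F2 F2-f 0 0 1 1",
    "F3 F3-c 0 0 1 2")))
  expect_equal(unname(family_counts(ped)), c(1L, 1L, 1L))
  expect_equal(ped$type[ped$family_id == "F2"], "duo")
  expect_equal(ped$father_id[ped$family_id == "F1"], "F1-f")
  expect_true(is.na(ped$mother_id[ped$family_id == "F2"]))
})

test_that("pedigree invariant violations are caught", {
  expect_error(read_pedigree(write_lines_tmp(c(
    "F1 kid F1-f F1-m 1 2",
    "F1 F1-f 0 0 1 1",
    "F1 F1-m 0 0 2 1",
    "F2 kid 0 0 1 2"))), "duplicated sample")
  # parent id referencing a missing sample demotes with a warning
  expect_warning(ped <- read_pedigree(write_lines_tmp(c(
    "F1 F1-c F1-f F1-m 1 2",
    "F1 F1-m 0 0 2 1"))), "not present")
  expect_equal(ped$type, "duo")
})

test_that("capture union merges, counts bases, and is idempotent", {
  b1 <- write_lines_tmp(c("chr1\t0\t10", "chr1\t5\t20"), ".bed")
  b2 <- write_lines_tmp(c("chr1\t0\t5", "chr2\t10\t15"), ".bed")
  u1 <- union_capture(b1)
  expect_equal(attr(u1, "total_bases"), 20L)
  expect_equal(length(u1), 1L)
  u2 <- union_capture(b2)
  expect_equal(attr(u2, "total_bases"), 10L)
  expect_equal(length(u2), 2L)
  # commutative and idempotent over files
  ab <- union_capture(c(b1, b2))
  ba <- union_capture(c(b2, b1))
  aa <- union_capture(c(b1, b1))
  expect_identical(as.data.frame(ab), as.data.frame(ba))
  expect_identical(as.data.frame(aa), as.data.frame(u1))
  expect_error(union_capture(write_lines_tmp("chr1\t10\t10", ".bed")),
               "malformed")
})

make_mini_vcf <- function(rows, samples = c("P1", "F1", "M1")) {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"c\">",
    "##INFO=<ID=AF_GNOMAD,Number=1,Type=Float,Description=\"f\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), ".vcf")
}

mini_ped <- function() {
  read_pedigree(write_lines_tmp(c("T1 P1 F1 M1 1 2",
                                  "T1 F1 0 0 1 1",
                                  "T1 M1 0 0 2 1")))
}

test_that("VCF FORMAT fields map onto trio members", {
  vcf <- make_mini_vcf(paste("chr1", 100, ".", "A", "G", 50, "PASS",
                             "GENE=G1;CLASS=missense;AF_GNOMAD=0",
                             "GT:AD:DP:GQ",
                             "0/1:12,5:17:99", "0/0:20,0:20:99",
                             "0/0:18,0:18:99", sep = "\t"))
  calls <- read_variants(vcf, mini_ped())
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pro_ad_alt, 5)
  expect_equal(calls$pro_dp, 17)
  expect_equal(calls$fa_ad_alt, 0)
  expect_equal(calls$gene, "G1")
})

test_that("multi-allelic sites decompose and conserve the alt set", {
  vcf <- make_mini_vcf(paste("chr1", 100, ".", "A", "G,T", 50, "PASS",
                             "GENE=G1;CLASS=missense;AF_GNOMAD=0",
                             "GT:AD:DP:GQ",
                             "1/2:2,9,8:19:99", "0/1:10,9,0:19:99",
                             "0/2:12,0,7:19:99", sep = "\t"))
  calls <- read_variants(vcf, mini_ped())
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$alt, c("G", "T"))
  g <- calls[calls$alt == "G", ]
  expect_equal(g$pro_ad_alt, 9)
  expect_equal(g$pro_gt, "0/1")   # one allele matches index 1
  t_ <- calls[calls$alt == "T", ]
  expect_equal(t_$pro_ad_alt, 8)
  expect_equal(t_$mo_gt, "0/1")
})

test_that("missing FORMAT values stay missing and records are kept", {
  vcf <- make_mini_vcf(paste("chr1", 100, ".", "A", "G", 50, "PASS",
                             "GENE=G1;CLASS=missense;AF_GNOMAD=0",
                             "GT:AD:DP:GQ",
                             "0/1:12,5:17:.", "0/0:.:.:99",
                             "0/0:18,0:18:99", sep = "\t"))
  calls <- read_variants(vcf, mini_ped())
  expect_equal(nrow(calls), 1L)
  expect_true(is.na(calls$pro_gq))
  expect_true(is.na(calls$fa_ad_alt))
})

test_that("pedigree samples absent from the VCF are an error", {
  vcf <- make_mini_vcf(paste("chr1", 100, ".", "A", "G", 50, "PASS",
                             "GENE=G1;CLASS=missense;AF_GNOMAD=0",
                             "GT:AD:DP:GQ",
                             "0/1:12,5:17:99", "0/0:20,0:20:99",
                             "0/0:18,0:18:99", sep = "\t"),
                       samples = c("P1", "F1", "MX"))
  expect_error(read_variants(vcf, mini_ped()), "M1")
})

test_that("indel alleles are normalized by trimming", {
  n <- normalize_allele(100L, "TTCTG", "T")
  expect_equal(n, list(pos = 100L, ref = "TTCTG", alt = "T"))
  n2 <- normalize_allele(100L, "CAG", "CTG")   # shared prefix+suffix
  expect_equal(n2$pos, 101L)
  expect_equal(c(n2$ref, n2$alt), c("A", "T"))
})

test_that("written cohorts read back field-by-field", {
  fx <- fixture_suite()
  calls <- fx$calls
  co <- fx$fx$cohort
  key_calls <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  key_sites <- paste(co$variants$chrom, co$variants$pos, co$variants$ref,
                     co$variants$alt, sep = ":")
  ped <- fx$ped
  for (d in co$truth$dnv[seq_len(min(10, length(co$truth$dnv)))]) {
    i <- which(key_calls == key_sites[d$row] & calls$family_id == d$family)
    expect_length(i, 1L)
    pro <- ped$proband_id[ped$family_id == d$family]
    expect_equal(calls$pro_gt[i], "0/1")
    expect_equal(calls$pro_dp[i], unname(co$dp[d$row, pro]))
    expect_equal(calls$pro_ad_alt[i], unname(co$ad_alt[d$row, pro]))
    expect_equal(calls$pro_gq[i], unname(co$gq[d$row, pro]))
    expect_equal(calls$class[i], co$variants$class[d$row])
  }
})
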