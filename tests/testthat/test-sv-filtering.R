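# Helper: one-variant set with chosen MSHQ and carrier DHFFC values.
one_site <- function(svtype, mshq, dhffc_carriers, span = 1000L) {
  n <- length(dhffc_carriers) + 2L
  samples <- sprintf("S%d", seq_len(n))
  v <- data.frame(id = "s-1", chrom = "1", pos = 1000L,
                  end = 1000L + span, svtype = svtype,
                  svlen = if (svtype == "DEL") -span else span,
                  mshq = mshq, stringsAsFactors = FALSE)
  geno <- matrix(c(rep(1L, length(dhffc_carriers)), 0L, 0L), nrow = 1,
                 dimnames = list(NULL, samples))
  dh <- matrix(c(dhffc_carriers, 1, 1), nrow = 1,
               dimnames = list(NULL, samples))
  sv_set(v, geno, dh, caller = "sm")
}

test_that("smoove DHFFC thresholds are strict, aggregated as carrier median", {
  # DEL kept only when median carrier DHFFC < 0.7
  expect_true(filter_smoove_site(one_site("DEL", 3.5, c(0.69, 0.69)))$keep)
  expect_false(filter_smoove_site(one_site("DEL", 3.5, c(0.70, 0.70)))$keep)
  # DUP kept only when median carrier DHFFC > 1.25
  expect_false(filter_smoove_site(one_site("DUP", 3.5, c(1.25, 1.25)))$keep)
  expect_true(filter_smoove_site(one_site("DUP", 3.5, c(1.26, 1.26)))$keep)
  # median over carriers only: with the two non-carrier samples (DHFFC 1.0)
  # included the median would be 0.825 and the site would drop
  d <- filter_smoove_site(one_site("DEL", 3.5, c(0.65, 0.65)))
  expect_true(d$keep)
})

test_that("MSHQ rule requires strictly greater than 3", {
  expect_false(filter_smoove_site(one_site("DEL", 3.0, 0.5))$keep)
  expect_equal(filter_smoove_site(one_site("DEL", 3.0, 0.5))$rule, "MSHQ")
  expect_true(filter_smoove_site(one_site("DEL", 3.0001, 0.5))$keep)
  # absent MSHQ (no het sample): logged pass-through
  d <- filter_smoove_site(one_site("INS", NA_real_, numeric(0)))
  expect_true(d$keep)
  expect_true(d$passthrough)
})

test_that("universal filters: size strictly > 0.5 Mb, contig whitelist, 1-bp deletions", {
  mk <- function(chrom, span, svtype = "DEL") {
    data.frame(id = paste0("u", seq_along(chrom)), chrom = chrom,
               pos = 1000L, end = 1000L + span, svtype = svtype,
               svlen = -span, stringsAsFactors = FALSE)
  }
  v <- mk(c("1", "1", "scaffold_12", "1"), c(500000L, 500001L, 5000L, 1L))
  x <- sv_set(v, matrix(0L, 4, 2, dimnames = list(NULL, c("A", "B"))))
  res <- filter_universal(x, chromosome_whitelist = c("1", "2", "X", "Y", "MT"))
  expect_equal(res$decisions$keep, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$decisions$rule, c(NA, "size", "contig", "del_1bp"))
  # report conserves totals
  expect_equal(res$report$input_count,
               res$report$output_count + sum(res$report$removed_by_rule))
  expect_error(filter_universal(x, chromosome_whitelist = character(0)),
               "whitelist")
})

test_that("filters are idempotent and output a subset of input", {
  truth <- small_cohort()
  b <- emulate_caller(truth, default_profiles()$beta)
  wl <- c(as.character(1:5), "X", "Y")
  f1 <- filter_caller_set(b, wl, smoove_rules = TRUE)
  f2 <- filter_caller_set(f1$svs, wl, smoove_rules = TRUE)
  expect_true(all(f1$svs$variants$id %in% b$variants$id))
  expect_equal(f2$svs$variants$id, f1$svs$variants$id)
  expect_equal(f2$report$output_count, f1$report$output_count)
})

test_that("GATK hard filter drops on any failing rule, exact thresholds pass", {
  snp_pass <- data.frame(QD = 2, FS = 60, MQ = 40, MQRankSum = -12.5,
                         ReadPosRankSum = -8)
  expect_true(gatk_hard_filter(snp_pass, "SNP")$keep)
  snp_qd <- data.frame(QD = 1.9, FS = 10, MQ = 60, MQRankSum = 0,
                       ReadPosRankSum = 0)
  res <- gatk_hard_filter(snp_qd, "SNP")
  expect_false(res$keep)
  expect_equal(res$failed_rules, "QD")
  expect_false(gatk_hard_filter(data.frame(QD = 5, FS = 201), "INDEL")$keep)
  expect_true(gatk_hard_filter(data.frame(QD = 5, FS = 199), "INDEL")$keep)
  # absent and NA annotations never trigger
  expect_true(gatk_hard_filter(data.frame(QD = 5), "SNP")$keep)
  expect_true(gatk_hard_filter(data.frame(QD = 5, MQ = NA), "SNP")$keep)
  expect_error(gatk_hard_filter(snp_pass, "MNP"))
})

test_that("affected-base accounting reproduces percent-of-genome arithmetic", {
  genome <- 2671711444
  s <- affected_bases(c(SV = 125565382), genome)
  expect_equal(s$display[s$type == "ALL"], "4.70%")
  expect_equal(affected_bases(c(x = 162110901), genome)$display[2], "6.07%")
  expect_equal(affected_bases(c(x = 34900560), genome)$display[2], "1.31%")
  # per-type sum equals ALL exactly; empty set gives a zero ALL row
  truth <- small_cohort()
  ab <- affected_bases(truth$svs, genome)
  expect_equal(ab$bases[ab$type == "ALL"],
               sum(ab$bases[ab$type != "ALL"]))
  empty <- sv_subset(truth$svs, integer(0))
  ab0 <- affected_bases(empty, genome)
  expect_equal(ab0$bases, 0)
  expect_equal(ab0$display, "0.00%")
  expect_error(affected_bases(c(x = 1), 0), "positive")
})

test_that("small-variant accounting counts SNPs as 1 bp and indels as length difference", {
  loci <- data.frame(id = c("a", "b", "c"), chrom = "1",
                     pos = c(1L, 2L, 3L), ref = c("A", "AGGG", "T"),
                     alt = c("C", "A", "TAA"), stringsAsFactors = FALSE)
  gm <- genotype_matrix(loci, matrix(0L, 3, 2, dimnames = list(NULL, c("x", "y"))))
  ab <- affected_bases(gm, 1000)
  expect_equal(ab$bases[ab$type == "SNP"], 1)
  expect_equal(ab$bases[ab$type == "INDEL"], 3 + 2)
  expect_equal(ab$bases[ab$type == "ALL"], 6)
})
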