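write_test_vcf <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

sv_vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##contig=<ID=1,length=10000000>",
  "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
  "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type\">",
  "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2"), collapse = "\t"))

test_that("read_sv_vcf maps fields, assigns caller-prefixed ids in file order", {
  path <- write_test_vcf(c(sv_vcf_header,
    "1\t1000\tx\tN\t<DEL>\t.\tPASS\tEND=2000;SVTYPE=DEL;SVLEN=-1000\tGT\t0/1\t0/0",
    "1\t5000\ty\tN\t<DUP>\t.\tPASS\tEND=6000;SVTYPE=DUP;SVLEN=1000\tGT\t1/1\t./.",
    "1\t7000\tz\tA\tATT\t.\tPASS\tSVTYPE=INS;SVLEN=2\tGT\t0|1\t0/1"))
  svs <- read_sv_vcf(path, "manta")
  expect_equal(svs$variants$id, c("manta-1", "manta-2", "manta-3"))
  expect_equal(svs$variants$pos[1], 1000L)
  expect_equal(svs$variants$end[1], 2000L)
  expect_equal(svs$variants$svtype, c("DEL", "DUP", "INS"))
  # GT "./." -> missing; phased separators accepted
  expect_equal(unname(svs$geno[, "S1"]), c(1L, 2L, 1L))
  expect_equal(unname(svs$geno[, "S2"]), c(0L, NA_integer_, 1L))
})

test_that("multi-allelic and non-DEL/DUP/INS records are skipped", {
  path <- write_test_vcf(c(sv_vcf_header,
    "1\t100\ta\tA\tT,G\t.\tPASS\tSVTYPE=DEL;END=101\tGT\t0/1\t0/2",
    "1\t1000\tb\tN\t<DEL>\t.\tPASS\tEND=2000;SVTYPE=DEL;SVLEN=-1000\tGT\t0/1\t0/0",
    "1\t3000\tc\tN\t<INV>\t.\tPASS\tEND=4000;SVTYPE=INV\tGT\t0/1\t0/0"))
  svs <- suppressMessages(read_sv_vcf(path, "c"))
  expect_equal(n_variants(svs), 1L)
  expect_equal(svs$variants$id, "c-1")
})

test_that("symbolic ALT without INFO END is a parse error", {
  path <- write_test_vcf(c(sv_vcf_header,
    "1\t1000\ta\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL\tGT\t0/1\t0/0"))
  expect_error(read_sv_vcf(path, "c"), "END")
})

test_that("affected intervals follow the anchor-base convention", {
  v <- data.frame(id = c("d", "i", "u"), chrom = "1",
                  pos = c(1000L, 500L, 10L), end = c(2000L, 500L, 20L),
                  svtype = c("DEL", "INS", "DUP"),
                  svlen = c(-1000L, 735L, 10L), stringsAsFactors = FALSE)
  ai <- affected_interval(v)
  # DEL pos=1000 end=2000 affects 1001..2000, 1000 bp
  expect_equal(ai$start[1], 1001L)
  expect_equal(ai$stop[1], 2000L)
  expect_equal(ai$span[1], 1000L)
  expect_equal(ai$affected_bp[1], 1000L)
  # INS: zero-length breakpoint; |ref - alt| = 735 bases counted
  expect_equal(ai$span[2], 0L)
  expect_equal(ai$affected_bp[2], 735L)
  expect_equal(ai$affected_bp[3], 10L)
  bad <- v; bad$end[1] <- 900L
  expect_error(affected_interval(bad), "end < pos")
})

test_that("sv_set round-trips through VCF bit-exactly", {
  truth <- small_cohort()
  a <- emulate_caller(truth, default_profiles()$alpha)
  path <- tempfile(fileext = ".vcf")
  write_sv_vcf(a, path)
  back <- read_sv_vcf(path, "alpha")
  ord <- order(a$variants$chrom, a$variants$pos)
  expect_equal(back$variants$pos, a$variants$pos[ord])
  expect_equal(back$variants$end, a$variants$end[ord])
  expect_equal(back$variants$svlen, a$variants$svlen[ord])
  expect_equal(back$variants$svtype, a$variants$svtype[ord])
  expect_equal(unname(back$geno), unname(a$geno[ord, ]))
  expect_equal(unname(back$dhffc), unname(a$dhffc[ord, ]), tolerance = 1e-3)
  expect_equal(back$variants$mshq, a$variants$mshq[ord], tolerance = 1e-3)
})

test_that("read_genotype_matrix encodes dosage and applies the missing-rate filter", {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1,length=10000>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sprintf("S%d", 1:10)), collapse = "\t"))
  gts_ok <- paste(c("0/1", "1/1", "0|0", rep("0/0", 7)), collapse = "\t")
  gts_miss <- paste(c("./.", "./.", rep("0/1", 8)), collapse = "\t")  # 20% missing
  path <- write_test_vcf(c(hdr,
    paste("1\t100\ts1\tA\tC\t.\tPASS\t.\tGT", gts_ok, sep = "\t"),
    paste("1\t200\ts2\tA\tC,G\t.\tPASS\t.\tGT", gts_ok, sep = "\t"),
    paste("1\t300\ts3\tA\tC\t.\tPASS\t.\tGT", gts_miss, sep = "\t")))
  gm <- read_genotype_matrix(path, max_missing_rate = 0.1)
  # multi-allelic s2 excluded; s3 over the missing threshold (0.2 > 0.1)
  expect_equal(gm$loci$id, "s1")
  expect_equal(unname(gm$dosage[1, 1:3]), c(1L, 2L, 0L))
  gm_all <- read_genotype_matrix(path)
  expect_equal(gm_all$loci$id, c("s1", "s3"))
  expect_error(read_genotype_matrix(path, max_missing_rate = -1),
               "no sites retained")
})

test_that("malformed genotypes are treated as missing with a warning", {
  expect_warning(d <- gt_to_dosage(c("0/1", "7/0", "1|1")), "malformed")
  expect_equal(d, c(1L, NA_integer_, 2L))
})
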