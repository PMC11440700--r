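test_that("cohort configuration validates its invariants", {
  expect_error(cohort_config(n_samples = 1), "positive")
  expect_error(cohort_config(n_samples = 60, sv_counts = c(DEL = -1)),
               "positive")
  bad_ped <- data.frame(child = "S002", sire = "S999", dam = "S001",
                        stringsAsFactors = FALSE)
  expect_error(cohort_config(n_samples = 60, pedigree_spec = bad_ped),
               "unknown samples")
  # parent must precede child in cohort order
  late <- data.frame(child = "S010", sire = "S050", dam = "S001",
                     stringsAsFactors = FALSE)
  expect_error(cohort_config(n_samples = 60, pedigree_spec = late),
               "precede")
  expect_error(caller_profile("x", genotype_error_rate = c(DEL = 1.5)),
               "probabilities")
  expect_error(caller_profile("x", boundary_jitter_bp = -1), "jitter")
  # capacity: chromosome too small for requested loci
  expect_error(
    simulate_cohort(cohort_config(
      n_samples = 10, chrom_lengths = c("1" = 2000, X = 8e6, Y = 2e6),
      n_autosomes = 1, snp_density = 0.9, pseudogene_events = list())),
    "too small")
})

test_that("simulation is deterministic: same config and seed, identical files", {
  run <- function(dir) {
    cfg <- cohort_config(n_samples = 40, seed = 5)
    truth <- simulate_cohort(cfg, out_dir = dir)
    for (p in cfg$caller_profiles)
      emulate_caller(truth, p, path = file.path(dir, paste0(p$name, ".vcf")))
  }
  d1 <- tempfile(); d2 <- tempfile()
  run(d1); run(d2)
  files <- list.files(d1)
  expect_gt(length(files), 5)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # and a different seed changes the data
  d3 <- tempfile()
  truth3 <- simulate_cohort(cohort_config(n_samples = 40, seed = 6), d3)
  expect_false(identical(readLines(file.path(d1, "truth_snps.vcf")),
                         readLines(file.path(d3, "truth_snps.vcf"))))
})

test_that("truth genotypes are Mendelian-consistent on the autosomes", {
  truth <- default_cohort()
  ped <- truth$pedigree
  auto <- truth$svs$variants$chrom != "X"
  g_sv <- truth$svs$geno[auto, ]
  g_snp <- truth$snps$dosage[truth$snps$loci$chrom != "X", ]
  violations <- function(g) {
    bad <- 0
    for (k in seq_len(nrow(ped))) {
      c_ <- g[, ped$child[k]]; s_ <- g[, ped$sire[k]]; d_ <- g[, ped$dam[k]]
      bad <- bad + sum(
        (s_ == 0 & d_ == 0 & c_ != 0) | (s_ == 2 & d_ == 2 & c_ != 2) |
          (s_ == 0 & d_ == 2 & c_ != 1) | (s_ == 2 & d_ == 0 & c_ != 1) |
          (s_ == 0 & c_ == 2) | (d_ == 0 & c_ == 2) |
          (s_ == 2 & c_ == 0) | (d_ == 2 & c_ == 0), na.rm = TRUE)
    }
    bad
  }
  expect_equal(violations(g_sv), 0)
  expect_equal(violations(g_snp), 0)
})

test_that("parent-offspring truth kinship is 0.25 within Monte Carlo tolerance", {
  truth <- default_cohort()
  ped <- truth$pedigree
  auto <- truth$snps$loci$chrom != "X"
  expect_gte(sum(auto), 3000)   # enough loci for the pedigree expectation
  km <- king_matrix(truth$snps$dosage[auto, ])
  po <- mapply(function(ch, pa) km[ch, pa],
               c(ped$child, ped$child), c(ped$sire, ped$dam))
  expect_equal(mean(po), 0.25, tolerance = 0.02 / 0.25)
})

test_that("SNPs in LD blocks reproduce the configured r2 target within 0.1", {
  truth <- default_cohort()
  cfg <- truth$config
  svv <- truth$svs$variants
  snpl <- truth$snps$loci
  r2 <- c()
  for (ch in unique(snpl$chrom)) {
    sv_i <- which(svv$chrom == ch & !startsWith(svv$id, "pseudo"))
    snp_i <- which(snpl$chrom == ch)
    if (length(sv_i) == 0) next
    for (j in snp_i) {
      d <- abs(svv$pos[sv_i] - snpl$pos[j])
      near <- which.min(d)
      if (d[near] <= cfg$ld_block_size) {
        r2 <- c(r2, r2_dosage(truth$svs$geno[sv_i[near], ],
                              truth$snps$dosage[j, ]))
      }
    }
  }
  expect_gt(length(r2), 100)
  expect_equal(mean(r2, na.rm = TRUE), cfg$ld_r2_target, tolerance = 0.1 / 0.9)
})

test_that("sex-dependent depth ratios follow the generator contract", {
  truth <- small_cohort()
  r <- depth_ratios(truth$depth)
  xy <- r$sample[truth$sex_labels[r$sample] == "XY"]
  expect_true(all(r$y_ratio[r$sample %in% xy] > 0.25 &
                    r$y_ratio[r$sample %in% xy] < 0.75))
  expect_true(all(r$x_ratio[r$sample %in% xy] > 0.25 &
                    r$x_ratio[r$sample %in% xy] < 0.75))
  xx <- setdiff(r$sample, xy)
  expect_true(all(r$x_ratio[r$sample %in% xx] > 0.8))
  expect_true(all(r$y_ratio[r$sample %in% xx] < 0.1))
})

test_that("identity profile reproduces the truth exactly", {
  truth <- small_cohort()
  calls <- emulate_caller(truth, caller_profile("ident"))
  expect_equal(unname(calls$geno), unname(truth$svs$geno))
  expect_equal(calls$variants$pos, truth$svs$variants$pos)
  expect_equal(calls$variants$end, truth$svs$variants$end)
  # DHFFC consistent with true copy-number state
  del1 <- which(calls$variants$svtype == "DEL")[1]
  carriers <- truth$svs$geno[del1, ] == 1
  expect_true(all(abs(calls$dhffc[del1, carriers] - 0.5) < 0.3))
  expect_true(all(abs(calls$dhffc[del1, !carriers & truth$svs$geno[del1, ] == 0] - 1) < 0.3))
})

test_that("profile switches control insertions, detection and missingness", {
  truth <- small_cohort()
  no_ins <- emulate_caller(truth, caller_profile("ni",
                                                 emits_insertions = FALSE))
  expect_false(any(no_ins$variants$svtype == "INS"))
  half <- emulate_caller(truth, caller_profile("hf", detection_rate = 0.5))
  expect_lt(n_variants(half), n_variants(truth$svs))
  miss <- emulate_caller(truth, caller_profile("ms", missing_rate = 0.2))
  expect_gt(mean(is.na(miss$geno)), 0.1)
})

test_that("pseudogene injection emits one het deletion per intron per carrier", {
  truth_clean <- cached("small_clean", function()
    simulate_cohort(cohort_config(n_samples = 40, seed = 8,
                                  pseudogene_events = list())))
  introns <- truth_clean$genes$introns
  gene <- introns$gene_id[which(table(introns$gene_id)[introns$gene_id] >= 4)[1]]
  n_int <- sum(introns$gene_id == gene &
                 introns$transcript_id == introns$transcript_id[
                   introns$gene_id == gene][1])
  res <- inject_pseudogene_artifact(truth_clean, gene, carriers = "S005")
  expect_length(res$new_ids, n_int)
  idx <- match(res$new_ids, res$truth$svs$variants$id)
  expect_true(all(res$truth$svs$geno[idx, "S005"] == 1L))
  expect_true(all(res$truth$svs$geno[idx, setdiff(colnames(res$truth$svs$geno),
                                                  "S005")] == 0L))
  # spans match the introns exactly
  ai <- affected_interval(res$truth$svs)[idx, ]
  gi <- introns[introns$gene_id == gene, ]
  expect_setequal(paste(ai$start, ai$stop), paste(gi$start, gi$end))
  # zero carriers emit nothing
  res0 <- inject_pseudogene_artifact(truth_clean, gene, character(0))
  expect_length(res0$new_ids, 0)
  expect_equal(n_variants(res0$truth$svs), n_variants(truth_clean$svs))
  # a gene with < 2 introns is unsupported
  one_exon <- gene_models(data.frame(
    gene_id = "M1", transcript_id = "M1.t1", chrom = "1",
    start = c(100L, 700L), end = c(200L, 800L), stringsAsFactors = FALSE))
  t2 <- truth_clean
  t2$genes <- one_exon
  expect_error(inject_pseudogene_artifact(t2, "M1", "S005"),
               "fewer than 2 introns")
})
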