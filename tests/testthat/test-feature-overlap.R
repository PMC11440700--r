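simple_gene <- function(exon_starts, exon_len = 100L, gene_id = "GX",
                        chrom = "1") {
  df <- data.frame(gene_id = gene_id,
                   transcript_id = paste0(gene_id, ".t1"),
                   chrom = chrom, start = exon_starts,
                   end = exon_starts + exon_len - 1L,
                   stringsAsFactors = FALSE)
  gene_models(df, cds = df)
}

del_set <- function(pos, end, carriers_dosage, ids = NULL) {
  ids <- ids %||% paste0("d", seq_along(pos))
  v <- data.frame(id = ids, chrom = "1", pos = pos, end = end,
                  svtype = "DEL", svlen = -(end - pos),
                  stringsAsFactors = FALSE)
  sv_set(v, carriers_dosage, caller = "t")
}

test_that("the 10 bp overlap floor is enforced at the boundary", {
  genes <- simple_gene(c(5000L, 6000L))
  g <- matrix(1L, 2, 2, dimnames = list(NULL, c("A", "B")))
  # exon 5000..5099: deletion covering its last 9 vs 10 bases
  svs <- del_set(pos = c(5090L, 5089L), end = c(5200L, 5200L), g)
  ov <- gene_overlaps(svs, genes)
  expect_false("d1" %in% ov$sv_id)   # 5091..5099 = 9 bp
  expect_true("d2" %in% ov$sv_id)    # 5090..5099 = 10 bp
  expect_equal(ov$overlap_bp[ov$sv_id == "d2" & ov$feature == "exon"], 10L)
})

test_that("an SV spanning a whole gene reports full exon and CDS lengths", {
  genes <- simple_gene(c(5000L, 6000L, 7000L))
  g <- matrix(1L, 2, 2, dimnames = list(NULL, c("A", "B")))
  svs <- del_set(pos = c(4000L, 40000L), end = c(8000L, 41000L), g)
  ov <- gene_overlaps(svs, genes)
  expect_equal(ov$overlap_bp[ov$sv_id == "d1" & ov$feature == "exon"], 300L)
  expect_equal(ov$overlap_bp[ov$sv_id == "d1" & ov$feature == "CDS"], 300L)
  expect_false("d2" %in% ov$sv_id)   # intergenic
})

test_that("gene_overlaps agrees with the per-base brute-force oracle", {
  for (seed in 1:3) {
    genes <- random_gene_models(n_genes = 5, seed = seed)
    set.seed(seed + 100)
    n <- 30
    pos <- sample(1000:90000, n)
    span <- sample(20:4000, n, replace = TRUE)
    v <- data.frame(id = paste0("r", seq_len(n)),
                    chrom = sample(c("1", "2"), n, replace = TRUE),
                    pos = pos, end = pos + span,
                    svtype = sample(c("DEL", "DUP"), n, replace = TRUE),
                    svlen = span, stringsAsFactors = FALSE)
    svs <- sv_set(v, matrix(1L, n, 2, dimnames = list(NULL, c("A", "B"))),
                  caller = "r")
    got <- gene_overlaps(svs, genes)
    want <- oracle_gene_overlaps(svs, genes)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("GTF round trip preserves exons and derived introns", {
  genes <- random_gene_models(n_genes = 4, seed = 2)
  path <- tempfile(fileext = ".gtf")
  write_gtf(genes, path)
  back <- read_gene_models(path)
  ord <- function(df) {
    df <- df[order(df$gene_id, df$start), ]
    rownames(df) <- NULL
    df[, c("gene_id", "transcript_id", "chrom", "start", "end")]
  }
  expect_equal(ord(back$exons), ord(genes$exons))
  expect_equal(ord(back$introns[, names(genes$introns) != "intron_index"]),
               ord(genes$introns[, names(genes$introns) != "intron_index"]))
})

test_that("intron-matching deletion series in one carrier is flagged", {
  # gene with 5 introns between 6 exons of 100 bp, introns of 400 bp
  starts <- seq(10000L, by = 500L, length.out = 6L)
  genes <- simple_gene(starts)
  introns <- genes$introns
  expect_equal(nrow(introns), 5)
  samples <- c("CAR", "N1", "N2")
  g <- matrix(0L, 5, 3, dimnames = list(NULL, samples))
  g[, "CAR"] <- 1L
  dels <- del_set(pos = introns$start - 1L, end = introns$end, g)
  flags <- flag_pseudogene_artifacts(dels, genes)
  expect_equal(nrow(flags), 1)
  expect_equal(flags$gene_id, "GX")
  expect_equal(flags$carriers, "CAR")
  expect_setequal(strsplit(flags$supporting_deletions, ",")[[1]], dels$variants$id)
  ev <- strsplit(flags$evidence, ",")[[1]]
  expect_true(all(c("intron_match", "multi_intron_series", "het_only")
                  %in% ev))
  # coverage evidence only when a coverage track is provided
  expect_false("exon_coverage_elevated" %in% ev)
  cov <- data.frame(gene_id = "GX", sample = samples,
                    exon_depth = c(30, 20, 20), stringsAsFactors = FALSE)
  ev2 <- strsplit(flag_pseudogene_artifacts(dels, genes,
                                            coverage = cov)$evidence,
                  ",")[[1]]
  expect_true("exon_coverage_elevated" %in% ev2)
})

test_that("single intron matches and far-off boundaries do not flag", {
  starts <- seq(10000L, by = 500L, length.out = 6L)
  genes <- simple_gene(starts)
  introns <- genes$introns
  g1 <- matrix(c(1L, 0L, 0L), 1, 3,
               dimnames = list(NULL, c("CAR", "N1", "N2")))
  one <- del_set(introns$start[1] - 1L, introns$end[1], g1)
  expect_equal(nrow(flag_pseudogene_artifacts(one, genes)), 0)
  # boundaries 200 bp away from any intron boundary contribute nothing
  g5 <- matrix(rep(c(1L, 0L, 0L), each = 5)[c(1, 6, 11)], 5, 3,
               dimnames = list(NULL, c("CAR", "N1", "N2")))
  g5[] <- 0L; g5[, 1] <- 1L
  far <- del_set(introns$start - 201L, introns$end - 200L, g5)
  expect_equal(nrow(flag_pseudogene_artifacts(far, genes)), 0)
  # carriers must share the series: two carriers each with one intron
  g2 <- matrix(0L, 2, 3, dimnames = list(NULL, c("C1", "C2", "N1")))
  g2[1, "C1"] <- 1L; g2[2, "C2"] <- 1L
  split_c <- del_set(introns$start[1:2] - 1L, introns$end[1:2], g2)
  expect_equal(nrow(flag_pseudogene_artifacts(split_c, genes)), 0)
})

test_that("injected artifacts survive an identity caller and are all flagged", {
  truth <- small_cohort()
  calls <- emulate_caller(truth, caller_profile("ident"))
  flags <- flag_pseudogene_artifacts(calls, truth$genes,
                                     coverage = truth$exon_coverage)
  expect_equal(flags$gene_id, "G01")
  expect_equal(flags$carriers, "S001")
  # every injected record is recovered as supporting evidence
  support <- strsplit(flags$supporting_deletions, ",")[[1]]
  injected <- calls$variants$id[attr(calls, "truth_id") %in%
                                  truth$pseudogene_ids]
  expect_setequal(support, injected)
  ev <- strsplit(flags$evidence, ",")[[1]]
  expect_true("exon_coverage_elevated" %in% ev)
  # no clean genic deletion produces a second flag
  expect_equal(nrow(flags), 1)
})
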