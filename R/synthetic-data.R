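# Synthetic pedigree cohort generator.
#
# The generator produces the full set of inputs the downstream stages
# consume: truth SV genotypes, a SNP genotype matrix in LD with the SVs,
# two pseudo-caller call sets with boundary jitter and type-specific
# genotype error, chip manifests, gene models, per-chromosome depth
# summaries, and processed-pseudogene deletion artifacts.
#
# Determinism: every random draw runs under a seed derived from the master
# seed and a stage/locus key (see derive_seed()), so a fixed seed gives
# byte-identical outputs and adding loci or stages never perturbs draws
# belonging to earlier ones.

#' Pseudo-caller error profile
#'
#' @param name caller label (used as the id prefix of emitted records).
#' @param boundary_jitter_bp maximum uniform shift applied independently to
#'   POS and END.
#' @param genotype_error_rate named per-type probabilities (`DEL`, `DUP`,
#'   `INS`) that a sample's genotype is replaced by a different one.
#' @param missing_rate per-genotype missing probability.
#' @param detection_rate probability that a truth locus is reported at all.
#' @param emits_insertions whether the caller reports insertions.
#' @return list of class `caller_profile`.
#' @export
caller_profile <- function(name, boundary_jitter_bp = 0,
                           genotype_error_rate = c(DEL = 0, DUP = 0, INS = 0),
                           missing_rate = 0, detection_rate = 1,
                           emits_insertions = TRUE) {
  probs <- c(genotype_error_rate, missing_rate, detection_rate)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must be in [0, 1]")
  if (boundary_jitter_bp < 0) stopf("boundary_jitter_bp must be >= 0")
  structure(list(name = name, boundary_jitter_bp = boundary_jitter_bp,
                 genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate,
                 detection_rate = detection_rate,
                 emits_insertions = emits_insertions),
            class = "caller_profile")
}

#' Default pseudo-caller profiles
#'
#' Two profiles emulating the qualitative differences between a
#' breakpoint-precise caller that reports insertions ("alpha") and a
#' read-pair/split-read caller that does not ("beta"): beta has larger
#' boundary jitter, higher genotype error and a small missing rate, and
#' duplications are noisier than deletions for both.
#'
#' @return named list of two [caller_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    alpha = caller_profile("alpha", boundary_jitter_bp = 10,
                           genotype_error_rate = c(DEL = 0.01, DUP = 0.03,
                                                   INS = 0.02),
                           missing_rate = 0, detection_rate = 0.75,
                           emits_insertions = TRUE),
    beta = caller_profile("beta", boundary_jitter_bp = 60,
                          genotype_error_rate = c(DEL = 0.03, DUP = 0.07,
                                                  INS = 0.08),
                          missing_rate = 0.003, detection_rate = 0.90,
                          emits_insertions = FALSE))
}

#' Synthetic cohort configuration
#'
#' Defaults describe a mostly-male pedigreed cohort: 310 samples
#' (290 XY, 20 XX), 250 founders and 60 offspring of founder pairs,
#' roughly 3,500 SNPs and 300 SVs on five 10-Mb autosomes plus an 8-Mb X,
#' 20x mean depth, and founder allele frequencies drawn from a symmetric
#' Beta giving a U-shaped frequency spectrum.
#'
#' @param n_samples cohort size.
#' @param pedigree_spec data.frame `child`, `sire`, `dam` (sample ids);
#'   parents must appear in the cohort before their children. `NULL` gives
#'   the default 60-offspring pedigree.
#' @param n_autosomes number of autosomes.
#' @param chrom_lengths named bp lengths for all chromosomes incl. `X`, `Y`.
#' @param sv_counts named counts per SV type (`DEL`, `DUP`, `INS`).
#' @param snp_density SNP loci per bp (autosomes and X).
#' @param ld_block_size bp window around an SV inside which SNPs are
#'   generated in LD with it.
#' @param ld_r2_target dosage r-squared targeted for SNPs in LD blocks.
#' @param founder_af_beta shape parameter of the symmetric Beta allele
#'   frequency distribution (frequencies clamped to `[0.02, 0.98]` to keep
#'   loci polymorphic).
#' @param recomb_rate uniform per-bp recombination rate per meiosis.
#' @param mean_depth mean autosome fold coverage.
#' @param depth_cv coefficient of variation of per-chromosome depth noise.
#' @param n_genes number of synthetic gene models.
#' @param caller_profiles named list of two [caller_profile()] objects.
#' @param sex_assignments named character vector sample -> `"XX"`/`"XY"`.
#' @param pseudogene_events list of `list(gene =, carriers =)` entries.
#' @param seed master integer seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 310, pedigree_spec = NULL,
                          n_autosomes = 5, chrom_lengths = NULL,
                          sv_counts = c(DEL = 150, DUP = 100, INS = 50),
                          snp_density = 6e-5, ld_block_size = 10000,
                          ld_r2_target = 0.9, founder_af_beta = 0.5,
                          recomb_rate = 1e-8, mean_depth = 20,
                          depth_cv = 0.05, n_genes = 30,
                          caller_profiles = default_profiles(),
                          sex_assignments = NULL,
                          pseudogene_events = NULL, seed = 1L) {
  if (n_samples < 2 || n_autosomes < 1 || any(sv_counts < 0) ||
      snp_density <= 0 || mean_depth <= 0)
    stopf("counts and rates must be positive")
  samples <- sprintf("S%03d", seq_len(n_samples))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- c(setNames(rep(10e6, n_autosomes),
                                as.character(seq_len(n_autosomes))),
                       X = 8e6, Y = 2e6)
  }
  if (!all(c("X", "Y") %in% names(chrom_lengths)))
    stopf("chrom_lengths must include X and Y")
  if (is.null(pedigree_spec)) pedigree_spec <- default_pedigree(samples)
  validate_pedigree(pedigree_spec, samples)
  if (is.null(sex_assignments)) {
    sex_assignments <- setNames(rep("XY", n_samples), samples)
    dams <- unique(pedigree_spec$dam)
    # the default mostly-male cohort: dams are the female samples
    n_xx <- min(20, length(dams))
    if (n_xx > 0) sex_assignments[dams[seq_len(n_xx)]] <- "XX"
  }
  if (!all(names(sex_assignments) %in% samples) ||
      !all(sex_assignments %in% c("XX", "XY")))
    stopf("sex_assignments must map cohort samples to XX/XY")
  if (is.null(pseudogene_events) && n_genes >= 1)
    pseudogene_events <- list(list(gene = "G01", carriers = samples[1]))
  structure(list(n_samples = n_samples, samples = samples,
                 pedigree_spec = pedigree_spec, n_autosomes = n_autosomes,
                 chrom_lengths = chrom_lengths, sv_counts = sv_counts,
                 snp_density = snp_density, ld_block_size = ld_block_size,
                 ld_r2_target = ld_r2_target,
                 founder_af_beta = founder_af_beta,
                 recomb_rate = recomb_rate, mean_depth = mean_depth,
                 depth_cv = depth_cv, n_genes = n_genes,
                 caller_profiles = caller_profiles,
                 sex_assignments = sex_assignments,
                 pseudogene_events = pseudogene_events %||% list(),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Default pedigree: a small-effective-size breeding population. A handful
# of founders and a pool of "popular sires" (the earliest samples) father
# most of the cohort, with the second parent drawn from all earlier
# samples. This gives the pervasive, graded relatedness typical of an
# intensively selected dairy population, which the kinship-correlation
# evaluation relies on. Deterministic regardless of the master seed: the
# pedigree is part of the stated world, not a random draw per run.
default_pedigree <- function(samples, n_founders = 30L, sire_pool = 8L) {
  n <- length(samples)
  n_founders <- min(n_founders, max(2L, n %/% 3))
  if (n <= n_founders + 1L)
    return(data.frame(child = character(), sire = character(),
                      dam = character(), stringsAsFactors = FALSE))
  with_seed(key_hash("default-pedigree"), {
    child <- samples[(n_founders + 1L):n]
    sire <- dam <- character(length(child))
    for (k in seq_along(child)) {
      i <- n_founders + k
      sire[k] <- sample(samples[seq_len(min(sire_pool, i - 1L))], 1)
      repeat {
        dam[k] <- sample(samples[seq_len(i - 1L)], 1)
        if (dam[k] != sire[k]) break
      }
    }
    data.frame(child = child, sire = sire, dam = dam,
               stringsAsFactors = FALSE)
  })
}

validate_pedigree <- function(ped, samples) {
  if (nrow(ped) == 0) return(invisible(TRUE))
  if (!all(c(ped$child, ped$sire, ped$dam) %in% samples))
    stopf("pedigree references unknown samples")
  if (anyDuplicated(ped$child)) stopf("duplicate children in pedigree")
  for (k in seq_len(nrow(ped))) {
    ci <- match(ped$child[k], samples)
    if (match(ped$sire[k], samples) >= ci ||
        match(ped$dam[k], samples) >= ci)
      stopf("pedigree parent %s/%s does not precede child %s",
            ped$sire[k], ped$dam[k], ped$child[k])
    if (ped$sire[k] == ped$child[k] || ped$dam[k] == ped$child[k])
      stopf("pedigree child %s is its own parent", ped$child[k])
  }
  invisible(TRUE)
}

# One gamete from a parent's two haplotype columns: recombination with a
# Poisson number of crossovers at uniform positions, no interference.
gamete <- function(h1, h2, positions, chrom_len, rate, seed) {
  with_seed(seed, {
    k <- rpois(1, rate * chrom_len)
    start <- sample(0:1, 1)
    if (k == 0) {
      if (start == 0) h1 else h2
    } else {
      breaks <- sort(runif(k, 1, chrom_len))
      seg <- findInterval(positions, breaks)
      ifelse((start + seg) %% 2 == 0, h1, h2)
    }
  })
}

#' Simulate a synthetic cohort
#'
#' Generates founder haplotypes locus by locus (allele frequencies from the
#' configured symmetric Beta; SNPs inside an SV's LD block co-segregate with
#' the SV at the configured r-squared target), transmits haplotypes through
#' the pedigree with recombination, and derives gene models, chip
#' manifests, sex-dependent depth summaries and exon-coverage tracks.
#' X loci in XY samples are hemizygous and diploid-coded (dosage 0 or 2).
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory; when given, writes `truth_snps.vcf`,
#'   `truth_svs.vcf`, `genes.gtf`, `chip_dense.tsv`, `chip_sparse.tsv`,
#'   `depth_summary.tsv`, `exon_coverage.tsv` and `sex_labels.tsv`.
#' @return object of class `truth_set`: list with `svs` (an [sv_set()] of
#'   truth genotypes), `snps` (a [genotype_matrix()]), `sex_labels`,
#'   `genes` (a `gene_models`), `chip` (dense/sparse manifests), `depth`,
#'   `exon_coverage`, `pedigree`, `haplotypes` and `config`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  seed <- cfg$seed
  samples <- cfg$samples
  n <- length(samples)
  sex <- cfg$sex_assignments[samples]
  auto <- as.character(seq_len(cfg$n_autosomes))
  variant_chroms <- c(auto, "X")
  lens <- cfg$chrom_lengths

  # --- place SV loci ---------------------------------------------------
  sv_types <- rep(names(cfg$sv_counts), cfg$sv_counts)
  n_sv <- length(sv_types)
  sv_chrom <- with_seed(derive_seed(seed, "svchrom"),
                        sample(variant_chroms, n_sv, replace = TRUE,
                               prob = lens[variant_chroms]))
  sv_span <- with_seed(derive_seed(seed, "svsize"), {
    span <- round(exp(rnorm(n_sv, log(2000), 1)))
    span[sv_types == "DUP"] <- round(exp(rnorm(sum(sv_types == "DUP"),
                                               log(5000), 1)))
    pmin(pmax(span, 100L), 200000L)
  })
  ins_len <- with_seed(derive_seed(seed, "inssize"),
                       pmin(pmax(round(exp(rnorm(n_sv, log(300), 0.8))),
                                 50L), 5000L))
  sv_pos <- with_seed(derive_seed(seed, "svpos"), {
    vapply(seq_len(n_sv), function(i) {
      L <- lens[[sv_chrom[i]]]
      hi <- if (sv_types[i] == "INS") L - 1 else L - sv_span[i] - 1
      if (hi < 2) stopf("chromosome %s too small for requested SV sizes",
                        sv_chrom[i])
      as.integer(floor(runif(1, 2, hi)))
    }, integer(1))
  })
  sv <- data.frame(chrom = sv_chrom, pos = sv_pos,
                   end = ifelse(sv_types == "INS", sv_pos,
                                sv_pos + sv_span),
                   svtype = sv_types,
                   svlen = ifelse(sv_types == "INS", ins_len,
                                  ifelse(sv_types == "DEL", -sv_span,
                                         sv_span)),
                   stringsAsFactors = FALSE)
  sv <- sv[order(match(sv$chrom, variant_chroms), sv$pos), ]
  rownames(sv) <- NULL
  sv$id <- paste0("truth-", seq_len(nrow(sv)))

  # --- place SNP loci and build haplotypes -----------------------------
  theta <- sqrt(cfg$ld_r2_target)
  hap <- list()        # chrom -> loci x 2n haplotype matrix
  loci_tab <- list()   # chrom -> data.frame(pos, kind, sv_row)
  for (ch in variant_chroms) {
    L <- lens[[ch]]
    n_snp <- round(cfg$snp_density * L)
    sv_rows <- which(sv$chrom == ch)
    if (n_snp + length(sv_rows) > 0.5 * L)
      stopf("chromosome %s (%d bp) too small for %d requested loci",
            ch, L, n_snp + length(sv_rows))
    snp_pos <- with_seed(derive_seed(seed, "snppos", ch),
                         sort(sample.int(L - 1, n_snp)) + 1L)
    snp_pos <- setdiff(snp_pos, sv$pos[sv_rows])
    tab <- rbind(
      data.frame(pos = sv$pos[sv_rows], kind = "SV", sv_row = sv_rows,
                 stringsAsFactors = FALSE),
      data.frame(pos = snp_pos, kind = "SNP",
                 sv_row = NA_integer_, stringsAsFactors = FALSE))
    tab <- tab[order(tab$pos), ]
    rownames(tab) <- NULL

    n_hap <- 2L * n
    H <- matrix(0L, nrow = nrow(tab), ncol = n_hap)
    founders <- setdiff(samples, cfg$pedigree_spec$child)
    f_idx <- match(founders, samples)
    f_cols <- as.vector(rbind(2L * f_idx - 1L, 2L * f_idx))

    # per-locus allele frequencies, keyed so extra loci never shift draws
    af <- vapply(seq_len(nrow(tab)), function(r)
      with_seed(derive_seed(seed, "af", ch, tab$pos[r]),
                min(max(stats::rbeta(1, cfg$founder_af_beta,
                                     cfg$founder_af_beta), 0.02), 0.98)),
      numeric(1))
    # SNPs inside an SV's LD block co-segregate with it; nearest SV wins
    sv_in_ch <- which(tab$kind == "SV")
    link <- rep(NA_integer_, nrow(tab))
    if (length(sv_in_ch)) {
      for (r in which(tab$kind == "SNP")) {
        d <- abs(tab$pos[sv_in_ch] - tab$pos[r])
        jmin <- which.min(d)
        if (d[jmin] <= cfg$ld_block_size) {
          link[r] <- sv_in_ch[jmin]
          af[r] <- af[sv_in_ch[jmin]]  # equal frequency => corr == theta
        }
      }
    }
    # founder haplotypes: SV loci first, then SNPs (LD copies need them)
    for (r in sv_in_ch) {
      u <- with_seed(derive_seed(seed, "hap", ch, tab$pos[r]),
                     runif(length(f_cols)))
      H[r, f_cols] <- as.integer(u < af[r])
    }
    for (r in which(tab$kind == "SNP")) {
      draws <- with_seed(derive_seed(seed, "hap", ch, tab$pos[r]),
                         list(u = runif(length(f_cols)),
                              v = runif(length(f_cols))))
      allele <- as.integer(draws$u < af[r])
      if (!is.na(link[r])) {
        copy <- draws$v < theta
        allele[copy] <- H[link[r], f_cols][copy]
      }
      H[r, f_cols] <- allele
    }
    # hemizygous X in XY founders: second haplotype mirrors the first
    if (ch == "X") {
      for (i in f_idx[sex[f_idx] == "XY"]) H[, 2L * i] <- H[, 2L * i - 1L]
    }
    hap[[ch]] <- H
    loci_tab[[ch]] <- tab
  }

  # --- transmit through the pedigree -----------------------------------
  ped <- cfg$pedigree_spec
  for (k in seq_len(nrow(ped))) {
    ci <- match(ped$child[k], samples)
    si <- match(ped$sire[k], samples)
    di <- match(ped$dam[k], samples)
    for (ch in variant_chroms) {
      H <- hap[[ch]]
      P <- loci_tab[[ch]]$pos
      L <- lens[[ch]]
      if (ch != "X") {
        H[, 2L * ci - 1L] <- gamete(H[, 2L * si - 1L], H[, 2L * si], P, L,
                                    cfg$recomb_rate,
                                    derive_seed(seed, "meiosis", ped$child[k],
                                                "sire", ch))
        H[, 2L * ci] <- gamete(H[, 2L * di - 1L], H[, 2L * di], P, L,
                               cfg$recomb_rate,
                               derive_seed(seed, "meiosis", ped$child[k],
                                           "dam", ch))
      } else {
        dam_x <- gamete(H[, 2L * di - 1L], H[, 2L * di], P, L,
                        cfg$recomb_rate,
                        derive_seed(seed, "meiosis", ped$child[k], "dam", ch))
        if (sex[ci] == "XY") {
          H[, 2L * ci - 1L] <- dam_x
          H[, 2L * ci] <- dam_x       # hemizygous, diploid-coded
        } else {
          H[, 2L * ci - 1L] <- H[, 2L * si - 1L]  # sire X passed unrecombined
          H[, 2L * ci] <- dam_x
        }
      }
      hap[[ch]] <- H
    }
  }

  # --- dosage matrices --------------------------------------------------
  odd <- 2L * seq_len(n) - 1L
  sv_geno <- matrix(NA_integer_, nrow = nrow(sv), ncol = n,
                    dimnames = list(sv$id, samples))
  snp_rows <- list()
  snp_dosage <- list()
  for (ch in variant_chroms) {
    tab <- loci_tab[[ch]]
    D <- hap[[ch]][, odd, drop = FALSE] + hap[[ch]][, odd + 1L, drop = FALSE]
    is_sv <- tab$kind == "SV"
    if (any(is_sv)) sv_geno[tab$sv_row[is_sv], ] <- D[is_sv, , drop = FALSE]
    if (any(!is_sv)) {
      snp_rows[[ch]] <- data.frame(chrom = ch, pos = tab$pos[!is_sv],
                                   stringsAsFactors = FALSE)
      snp_dosage[[ch]] <- D[!is_sv, , drop = FALSE]
    }
  }
  snp_loci <- do.call(rbind, snp_rows)
  snp_loci <- data.frame(id = paste0("snp-", seq_len(nrow(snp_loci))),
                         snp_loci, ref = "A", alt = "C",
                         stringsAsFactors = FALSE)
  snps <- genotype_matrix(snp_loci, do.call(rbind, snp_dosage))
  colnames(snps$dosage) <- samples
  truth_svs <- sv_set(sv[, c("id", "chrom", "pos", "end", "svtype", "svlen")],
                      sv_geno, caller = "truth")

  # --- gene models ------------------------------------------------------
  genes <- with_seed(derive_seed(seed, "genes"), {
    rows <- lapply(seq_len(cfg$n_genes), function(g) {
      ch <- sample(auto, 1)
      n_ex <- sample(4:8, 1)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      in_len <- sample(500:3000, n_ex - 1, replace = TRUE)
      total <- sum(ex_len) + sum(in_len)
      start <- sample.int(max(1L, lens[[ch]] - total - 1000L), 1)
      starts <- start + cumsum(c(0L, head(ex_len, -1) + in_len))
      gid <- sprintf("G%02d", g)
      data.frame(gene_id = gid, transcript_id = paste0(gid, ".t1"),
                 chrom = ch, start = starts, end = starts + ex_len - 1L,
                 stringsAsFactors = FALSE)
    })
    exons <- do.call(rbind, rows)
    gene_models(exons, cds = exons)
  })

  # --- chip manifests ---------------------------------------------------
  manifest_of <- function(frac, label, key) {
    idx <- with_seed(derive_seed(seed, key),
                     sort(sample.int(nrow(snp_loci),
                                     round(frac * nrow(snp_loci)))))
    m <- data.frame(marker_name = paste0(label, "_", snp_loci$id[idx]),
                    chrom = snp_loci$chrom[idx], pos = snp_loci$pos[idx],
                    stringsAsFactors = FALSE)
    attr(m, "panel_label") <- label
    m
  }
  chip <- list(dense = manifest_of(0.40, "dense", "chip_dense"),
               sparse = manifest_of(0.07, "sparse", "chip_sparse"))

  # --- depth summaries and exon coverage --------------------------------
  all_chroms <- names(lens)
  depth <- with_seed(derive_seed(seed, "depth"), {
    base <- cfg$mean_depth * (1 + rnorm(n, 0, 0.03))
    rows <- lapply(seq_len(n), function(i) {
      fac <- setNames(rep(1, length(all_chroms)), all_chroms)
      fac["X"] <- if (sex[i] == "XX") 1 else 0.5
      fac["Y"] <- if (sex[i] == "XX") 0.005 else 0.5
      data.frame(sample = samples[i], chrom = all_chroms,
                 mean_depth = pmax(0, base[i] * fac *
                                     (1 + rnorm(length(all_chroms), 0,
                                                cfg$depth_cv))),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rownames(depth) <- NULL
  exon_cov <- with_seed(derive_seed(seed, "exoncov"), {
    gids <- unique(genes$exons$gene_id)
    data.frame(gene_id = rep(gids, each = n),
               sample = rep(samples, length(gids)),
               exon_depth = cfg$mean_depth *
                 (1 + rnorm(n * length(gids), 0, cfg$depth_cv)),
               stringsAsFactors = FALSE)
  })

  truth <- structure(
    list(svs = truth_svs, snps = snps, sex_labels = sex, genes = genes,
         chip = chip, depth = depth, exon_coverage = exon_cov,
         pedigree = ped, haplotypes = hap, loci = loci_tab,
         pseudogene_ids = character(0), config = cfg),
    class = "truth_set")

  for (ev in cfg$pseudogene_events) {
    truth <- inject_pseudogene_artifact(truth, ev$gene, ev$carriers)$truth
  }

  if (!is.null(out_dir)) write_cohort(truth, out_dir)
  truth
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d samples, %d SVs, %d SNPs, %d genes\n",
              length(x$sex_labels), nrow(x$svs$variants),
              nrow(x$snps$loci), length(unique(x$genes$exons$gene_id))))
  invisible(x)
}

#' Inject processed-pseudogene deletion artifacts
#'
#' For every intron of `gene`, emits a heterozygous deletion spanning
#' exactly that intron in each carrier (0/0 elsewhere) and elevates the
#' carriers' exon coverage for the gene, mimicking reads from an intron-less
#' retro-copy aligning back to the parent gene.
#'
#' @param truth a `truth_set` from [simulate_cohort()].
#' @param gene gene id present in `truth$genes` with at least 2 introns.
#' @param carriers character vector of carrier sample ids (possibly empty,
#'   in which case nothing is emitted).
#' @return list with `truth` (modified) and `new_ids` (ids of the injected
#'   deletion records, also accumulated in `truth$pseudogene_ids`).
#' @export
inject_pseudogene_artifact <- function(truth, gene, carriers) {
  introns <- truth$genes$introns
  tx <- introns$transcript_id[introns$gene_id == gene]
  if (length(tx) == 0)
    stopf("gene %s not found or has no introns", gene)
  introns <- introns[introns$transcript_id == tx[1], , drop = FALSE]
  if (nrow(introns) < 2)
    stopf("gene %s has fewer than 2 introns; pseudogene artifacts need a series",
          gene)
  if (length(carriers) == 0) return(list(truth = truth, new_ids = character(0)))
  samples <- colnames(truth$svs$geno)
  if (!all(carriers %in% samples)) stopf("unknown carrier sample")

  new_v <- data.frame(
    id = sprintf("pseudo-%s-%d", gene, introns$intron_index),
    chrom = introns$chrom, pos = introns$start - 1L, end = introns$end,
    svtype = "DEL", svlen = -(introns$end - introns$start + 1L),
    stringsAsFactors = FALSE)
  new_g <- matrix(0L, nrow = nrow(new_v), ncol = length(samples),
                  dimnames = list(new_v$id, samples))
  new_g[, carriers] <- 1L

  comb_v <- rbind(truth$svs$variants[, names(new_v)], new_v)
  comb_g <- rbind(truth$svs$geno, new_g)
  ord <- order(match(comb_v$chrom, unique(c(comb_v$chrom))), comb_v$pos)
  truth$svs <- sv_set(comb_v[ord, ], comb_g[ord, , drop = FALSE],
                      caller = "truth")
  hit <- truth$exon_coverage$gene_id == gene &
    truth$exon_coverage$sample %in% carriers
  truth$exon_coverage$exon_depth[hit] <- truth$exon_coverage$exon_depth[hit] * 1.6
  truth$pseudogene_ids <- c(truth$pseudogene_ids, new_v$id)
  list(truth = truth, new_ids = new_v$id)
}

#' Emulate a structural-variant caller on the truth set
#'
#' Each truth SV is reported with the profile's detection rate; reported
#' POS/END are shifted independently by up to `boundary_jitter_bp`;
#' genotypes are corrupted per SV type and set missing at the profile
#' rates. Site quality (MSHQ-like, the mean heterozygous-sample quality)
#' and per-sample DHFFC (depth fold change inside the SV relative to its
#' flanks) are drawn consistently with the true copy-number state plus
#' Gaussian noise: deletion carriers centre on 0.5 (het) / 0.05 (hom),
#' duplication carriers on 1.5 / 2.0, non-carriers on 1.0.
#'
#' @param truth a `truth_set`.
#' @param profile a [caller_profile()].
#' @param path optional VCF output path.
#' @return an [sv_set()] with ids `<profile$name>-N`; attribute
#'   `truth_id` maps each record to its source truth locus.
#' @export
emulate_caller <- function(truth, profile, path = NULL) {
  stopifnot(inherits(profile, "caller_profile"))
  seed <- truth$config$seed
  v <- truth$svs$variants
  n <- ncol(truth$svs$geno)
  samples <- colnames(truth$svs$geno)

  keep <- vapply(v$id, function(id)
    with_seed(derive_seed(seed, "detect", profile$name, id),
              runif(1) < profile$detection_rate), logical(1))
  if (!profile$emits_insertions) keep <- keep & v$svtype != "INS"
  v <- v[keep, , drop = FALSE]
  true_g <- truth$svs$geno[keep, , drop = FALSE]
  m <- nrow(v)

  geno <- true_g
  dhffc <- matrix(NA_real_, nrow = m, ncol = n,
                  dimnames = list(NULL, samples))
  mshq <- rep(NA_real_, m)
  pos <- v$pos; end <- v$end
  for (i in seq_len(m)) {
    s <- derive_seed(seed, "emit", profile$name, v$id[i])
    with_seed(s, {
      if (profile$boundary_jitter_bp > 0 && v$svtype[i] != "INS") {
        j <- profile$boundary_jitter_bp
        pos[i] <- max(1L, v$pos[i] + as.integer(round(runif(1, -j, j))))
        end[i] <- v$end[i] + as.integer(round(runif(1, -j, j)))
        if (end[i] <= pos[i]) end[i] <- pos[i] + 1L
      }
      e <- profile$genotype_error_rate[[v$svtype[i]]] %||% 0
      u_err <- runif(n); u_pick <- runif(n); u_miss <- runif(n)
      g <- true_g[i, ]
      flip <- u_err < e & !is.na(g)
      # adjacent-dosage miscalls (one allele wrong): 0->1, 2->1, 1->0 or 2;
      # a single error never turns one homozygote into the opposing one
      g[flip] <- ifelse(g[flip] == 1L,
                        ifelse(u_pick[flip] > 0.5, 2L, 0L), 1L)
      g[u_miss < profile$missing_rate] <- NA_integer_
      geno[i, ] <- g
      if (v$svtype[i] %in% c("DEL", "DUP")) {
        centre <- if (v$svtype[i] == "DEL") c(1, 0.5, 0.05) else c(1, 1.5, 2)
        tg <- true_g[i, ]
        mu <- centre[ifelse(is.na(tg), 1L, tg) + 1L]
        dhffc[i, ] <- pmax(0, mu + rnorm(n, 0, 0.05))
      }
      n_het <- sum(g == 1L, na.rm = TRUE)
      if (n_het > 0) mshq[i] <- min(4, max(1, rnorm(1, 3.6, 0.4)))
    })
  }
  out_v <- data.frame(id = paste0(profile$name, "-", seq_len(m)),
                      chrom = v$chrom, pos = pos,
                      end = ifelse(v$svtype == "INS", pos, end),
                      svtype = v$svtype,
                      svlen = ifelse(v$svtype == "DEL", -(end - pos),
                                     ifelse(v$svtype == "DUP", end - pos,
                                            v$svlen)),
                      mshq = mshq, stringsAsFactors = FALSE)
  set <- sv_set(out_v, geno, dhffc, caller = profile$name)
  attr(set, "truth_id") <- v$id
  if (!is.null(path))
    write_sv_vcf(set, path,
                 contig_lengths = truth$config$chrom_lengths)
  set
}

# Write all cohort files to a directory.
write_cohort <- function(truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lens <- truth$config$chrom_lengths
  write_snp_vcf(truth$snps, file.path(out_dir, "truth_snps.vcf"),
                contig_lengths = lens)
  write_sv_vcf(truth$svs, file.path(out_dir, "truth_svs.vcf"),
               contig_lengths = lens)
  write_gtf(truth$genes, file.path(out_dir, "genes.gtf"))
  tsv <- function(df, name) write.table(df, file.path(out_dir, name),
                                        sep = "\t", quote = FALSE,
                                        row.names = FALSE)
  tsv(truth$chip$dense, "chip_dense.tsv")
  tsv(truth$chip$sparse, "chip_sparse.tsv")
  tsv(truth$depth, "depth_summary.tsv")
  tsv(truth$exon_coverage, "exon_coverage.tsv")
  tsv(data.frame(sample = names(truth$sex_labels),
                 sex = unname(truth$sex_labels)), "sex_labels.tsv")
  invisible(out_dir)
}
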