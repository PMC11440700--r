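# KING-robust kinship from genotype dosages, and the SV-vs-SNP kinship
# correlation experiment used to score SV genotype quality.
#
# For a sample pair (i, j) the within-pair KING-robust estimator is
#
#   phi = (N_AaAa - 2 * N_AAaa) / (N_Aa(i) + N_Aa(j))
#
# where N_AaAa counts sites heterozygous in both samples, N_AAaa counts
# opposing homozygotes, and N_Aa(i) counts sites heterozygous in sample i
# among sites non-missing in both. This matches the estimator reported by
# vcftools --relatedness2. phi is 0.5 for identical genomes and ~0.25 for
# parent-offspring pairs.

#' KING-robust kinship coefficient for one sample pair
#'
#' Sites with a missing dosage in either sample are excluded from all
#' counts. When neither sample is heterozygous at any comparable site the
#' estimator is undefined and `NA` is returned with a warning.
#'
#' @param dos_i,dos_j sample-aligned dosage vectors (0/1/2/`NA`).
#' @return kinship coefficient phi, or `NA`.
#' @export
king_phi <- function(dos_i, dos_j) {
  stopifnot(length(dos_i) == length(dos_j))
  ok <- !is.na(dos_i) & !is.na(dos_j)
  di <- dos_i[ok]; dj <- dos_j[ok]
  n_het_i <- sum(di == 1)
  n_het_j <- sum(dj == 1)
  if (n_het_i + n_het_j == 0) {
    warnf("KING phi undefined: no heterozygous sites in either sample")
    return(NA_real_)
  }
  n_het_both <- sum(di == 1 & dj == 1)
  n_opp_hom <- sum((di == 0 & dj == 2) | (di == 2 & dj == 0))
  (n_het_both - 2 * n_opp_hom) / (n_het_i + n_het_j)
}

#' KING kinship for all sample pairs of a dosage matrix
#'
#' Vectorised over pairs via cross-products of indicator matrices; missing
#' dosages are handled pairwise-complete, exactly as in [king_phi()].
#'
#' @param dosage loci x samples dosage matrix (0/1/2/`NA`), or a
#'   [genotype_matrix()].
#' @return symmetric matrix of phi values (`NA` where undefined); diagonal
#'   is each sample against itself (0.5 when it has any het site).
#' @export
king_matrix <- function(dosage) {
  if (inherits(dosage, "genotype_matrix")) dosage <- dosage$dosage
  valid <- !is.na(dosage)
  H <- valid & dosage == 1L; H[is.na(H)] <- FALSE; storage.mode(H) <- "double"
  A0 <- valid & dosage == 0L; A0[is.na(A0)] <- FALSE; storage.mode(A0) <- "double"
  A2 <- valid & dosage == 2L; A2[is.na(A2)] <- FALSE; storage.mode(A2) <- "double"
  V <- valid; storage.mode(V) <- "double"
  n_het_both <- crossprod(H)            # t(H) %*% H
  n_opp <- crossprod(A0, A2)            # i hom-ref, j hom-alt
  n_opp <- n_opp + t(n_opp)
  n_het_i <- crossprod(H, V)            # [i,j]: i het & j non-missing
  denom <- n_het_i + t(n_het_i)
  phi <- (n_het_both - 2 * n_opp) / denom
  phi[denom == 0] <- NA_real_
  dimnames(phi) <- list(colnames(dosage), colnames(dosage))
  phi
}

# Lower-triangle pair vector of a symmetric matrix, with pair labels.
pair_vector <- function(m) {
  idx <- which(lower.tri(m), arr.ind = TRUE)
  data.frame(i = rownames(m)[idx[, 2]], j = rownames(m)[idx[, 1]],
             phi = m[idx], stringsAsFactors = FALSE)
}

#' Randomly subsample loci from a genotype matrix
#'
#' Eligible loci are biallelic sites whose per-site missing rate does not
#' exceed `max_missing_rate`. Exactly `n` loci are drawn uniformly,
#' deterministically for a given `seed`.
#'
#' @param x a [genotype_matrix()] (or an [sv_set()], whose genotypes are
#'   used directly).
#' @param n number of loci to draw.
#' @param with_replacement draw with replacement (default `FALSE`).
#' @param max_missing_rate per-site missing-rate ceiling (default 0.1).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return a [genotype_matrix()] of the drawn loci (duplicates possible when
#'   drawing with replacement).
#' @export
subsample_loci <- function(x, n, with_replacement = FALSE,
                           max_missing_rate = 0.1, seed = 1L) {
  if (inherits(x, "sv_set")) {
    loci <- data.frame(id = x$variants$id, chrom = x$variants$chrom,
                       pos = x$variants$pos, ref = "N",
                       alt = paste0("<", x$variants$svtype, ">"),
                       stringsAsFactors = FALSE)
    x <- genotype_matrix(loci, x$geno)
  }
  miss <- rowMeans(is.na(x$dosage))
  eligible <- which(miss <= max_missing_rate)
  if (!with_replacement && n > length(eligible))
    stopf("requested %d loci without replacement but only %d eligible",
          n, length(eligible))
  drawn <- with_seed(seed,
                     sample(eligible, n, replace = with_replacement))
  gm <- genotype_matrix(x$loci[drawn, , drop = FALSE],
                        x$dosage[drawn, , drop = FALSE])
  rownames(gm$dosage) <- NULL
  gm
}

#' SV-vs-SNP kinship correlation experiment
#'
#' The SNP baseline is drawn once (`snp_baseline_size` biallelic loci with
#' missing rate <= `max_missing_rate`, without replacement) and its KING
#' kinship computed for every sample pair. Then, per replicate,
#' `loci_per_replicate` SV loci are drawn with replacement, pairwise phi is
#' recomputed, and the Pearson correlation between the SV and SNP phi
#' vectors is taken over all pairs where both are defined.
#'
#' @param sv a [genotype_matrix()] or [sv_set()] of SV genotypes.
#' @param snp a [genotype_matrix()] of SNP genotypes over the same samples.
#' @param n_replicates number of SV resampling replicates (default 100).
#' @param loci_per_replicate SV loci per replicate (default 2000).
#' @param with_replacement draw SV replicate loci with replacement
#'   (default `TRUE`, per the resampling protocol).
#' @param snp_baseline_size size of the single SNP baseline draw
#'   (default 20000).
#' @param max_missing_rate eligibility ceiling on per-site missing rate.
#' @param seed integer seed driving both the baseline draw and the
#'   replicate draws.
#' @return object of class `kinship_experiment`: list with `r`
#'   (per-replicate Pearson correlations), `mean_r`, `median_r`,
#'   `n_pairs_used`, `n_dropped_pairs` and the configuration.
#' @export
kinship_correlation <- function(sv, snp, n_replicates = 100,
                                loci_per_replicate = 2000,
                                with_replacement = TRUE,
                                snp_baseline_size = 20000,
                                max_missing_rate = 0.1, seed = 1L) {
  if (inherits(sv, "sv_set")) {
    sv <- genotype_matrix(
      data.frame(id = sv$variants$id, chrom = sv$variants$chrom,
                 pos = sv$variants$pos, ref = "N",
                 alt = paste0("<", sv$variants$svtype, ">"),
                 stringsAsFactors = FALSE),
      sv$geno)
  }
  common <- intersect(colnames(sv$dosage), colnames(snp$dosage))
  if (length(common) < 2) stopf("need at least 2 shared samples")
  sv_d <- sv$dosage[, common, drop = FALSE]
  snp_sub <- subsample_loci(genotype_matrix(snp$loci,
                                            snp$dosage[, common, drop = FALSE]),
                            n = snp_baseline_size, with_replacement = FALSE,
                            max_missing_rate = max_missing_rate,
                            seed = derive_seed(seed, "snp_baseline"))
  phi_snp <- king_matrix(snp_sub$dosage)
  snp_pairs <- pair_vector(phi_snp)

  sv_gm <- genotype_matrix(sv$loci, sv_d)
  r <- numeric(n_replicates)
  dropped <- integer(n_replicates)
  for (k in seq_len(n_replicates)) {
    rep_gm <- subsample_loci(sv_gm, n = loci_per_replicate,
                             with_replacement = with_replacement,
                             max_missing_rate = max_missing_rate,
                             seed = derive_seed(seed, "replicate", k))
    phi_sv <- suppressWarnings(king_matrix(rep_gm$dosage))
    sv_pairs <- pair_vector(phi_sv)
    ok <- !is.na(sv_pairs$phi) & !is.na(snp_pairs$phi)
    dropped[k] <- sum(!ok)
    r[k] <- cor(sv_pairs$phi[ok], snp_pairs$phi[ok])
  }
  structure(list(r = r, mean_r = mean(r), median_r = median(r),
                 n_pairs_used = nrow(snp_pairs) - dropped,
                 n_dropped_pairs = dropped,
                 config = list(n_replicates = n_replicates,
                               loci_per_replicate = loci_per_replicate,
                               with_replacement = with_replacement,
                               snp_baseline_size = snp_baseline_size,
                               max_missing_rate = max_missing_rate,
                               seed = seed)),
            class = "kinship_experiment")
}

#' @export
print.kinship_experiment <- function(x, ...) {
  cat(sprintf("<kinship_experiment> %d replicates x %d loci: mean r = %.4f, median r = %.4f\n",
              x$config$n_replicates, x$config$loci_per_replicate,
              x$mean_r, x$median_r))
  invisible(x)
}
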