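# Per-SV report cards: allele frequency, genotype counts, exact
# Hardy-Weinberg test, shared status, chip overlap / tag SNPs, gene
# overlaps and optional sex-stratified genotype counts.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test: given the observed allele counts, all
#' heterozygote counts `h` of the same parity as the minor-allele count are
#' enumerated with probability
#' `P(h) = 2^h * n! / (n_AA(h)! * h! * n_aa(h)!) / C`,
#' and the p-value is the total probability of configurations no more likely
#' than the observed one (plain minimum-likelihood tail, no mid-p
#' correction).
#'
#' @param hom_ref,het,hom_alt non-negative genotype counts.
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact <- function(hom_ref, het, hom_alt) {
  if (length(hom_ref) > 1L)
    return(mapply(hwe_exact, hom_ref, het, hom_alt))
  counts <- c(hom_ref, het, hom_alt)
  if (any(is.na(counts)) || any(counts < 0))
    stopf("genotype counts must be non-negative")
  n <- sum(counts)
  if (n < 1) stopf("at least one genotyped sample required")
  minor <- min(2 * hom_alt + het, 2 * hom_ref + het)
  hs <- seq(minor %% 2, minor, by = 2)
  logp <- vapply(hs, function(h) {
    n_minor_hom <- (minor - h) / 2
    n_major_hom <- n - h - n_minor_hom
    h * log(2) + lfactorial(n) - lfactorial(n_minor_hom) -
      lfactorial(h) - lfactorial(n_major_hom)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[hs == het]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

#' Genotype counts and alternate-allele frequency of a dosage vector
#'
#' @param dosage vector of 0/1/2/`NA`.
#' @return list with `hom_ref`, `het`, `hom_alt`, `missing`, `af`
#'   (`(het + 2*hom_alt) / (2 * non-missing)`).
#' @export
genotype_summary <- function(dosage) {
  hom_ref <- sum(dosage == 0L, na.rm = TRUE)
  het <- sum(dosage == 1L, na.rm = TRUE)
  hom_alt <- sum(dosage == 2L, na.rm = TRUE)
  n <- hom_ref + het + hom_alt
  list(hom_ref = hom_ref, het = het, hom_alt = hom_alt,
       missing = sum(is.na(dosage)),
       af = if (n > 0) (het + 2 * hom_alt) / (2 * n) else NA_real_)
}

#' Assemble per-SV report cards
#'
#' One card per SV in the set, combining genotype statistics with the
#' results of the upstream analyses. Hemizygous samples at X loci are
#' counted as their diploid-coded genotypes; the sex-stratified blocks are
#' the interpretive aid for such loci.
#'
#' @param svs an [sv_set()].
#' @param shared optional `pairs` data.frame from [find_shared()] (matched
#'   on `id_a` or `id_b`).
#' @param tags optional data.frame from [tag_scan_all()] (or a named list of
#'   them, one per panel).
#' @param chip optional data.frame from [chip_overlap()] (or a named list of
#'   them, one per panel).
#' @param overlaps optional data.frame from [gene_overlaps()].
#' @param sex_calls optional data.frame `sample`, `label` from
#'   [infer_sex()]; adds per-label genotype count blocks.
#' @return list of `sv_card` objects (class `sv_card_list`).
#' @export
sv_cards <- function(svs, shared = NULL, tags = NULL, chip = NULL,
                     overlaps = NULL, sex_calls = NULL) {
  v <- svs$variants
  if (!is.null(shared) && nrow(shared) > 0) {
    if (any(is.na(shared$id_a) | is.na(shared$id_b) |
              !nzchar(shared$id_a) | !nzchar(shared$id_b)))
      stopf("shared pairs contain dangling partner ids")
    # pairs not touching this call set are ignored
    shared <- shared[shared$id_a %in% v$id | shared$id_b %in% v$id, ,
                     drop = FALSE]
  }
  tags <- normalise_panel(tags, "tags")
  chip <- normalise_panel(chip, "chip")
  cards <- lapply(seq_len(nrow(v)), function(i) {
    gs <- genotype_summary(svs$geno[i, ])
    partner <- NA_character_
    if (!is.null(shared)) {
      hit_a <- shared$id_a == v$id[i]
      hit_b <- shared$id_b == v$id[i]
      if (any(hit_a)) partner <- shared$id_b[which(hit_a)[1]]
      if (any(hit_b)) partner <- shared$id_a[which(hit_b)[1]]
    }
    card <- list(
      sv_id = v$id[i], chrom = v$chrom[i], pos = v$pos[i], end = v$end[i],
      svtype = v$svtype[i], svlen = v$svlen[i],
      alt_allele_frequency = gs$af,
      genotype_counts = c(hom_ref = gs$hom_ref, het = gs$het,
                          hom_alt = gs$hom_alt, missing = gs$missing),
      hwe_p = if (gs$hom_ref + gs$het + gs$hom_alt > 0)
        hwe_exact(gs$hom_ref, gs$het, gs$hom_alt) else NA_real_,
      shared = !is.na(partner), shared_partner = partner)
    card$overlapping_snps <- lapply(chip, function(d) {
      m <- d$markers[d$sv_id == v$id[i]]
      if (length(m) && nzchar(m)) strsplit(m, ",")[[1]] else character(0)
    })
    card$tag_snps <- lapply(tags, function(d) {
      m <- d$tags[d$sv_id == v$id[i]]
      if (length(m) && nzchar(m)) strsplit(m, ",")[[1]] else character(0)
    })
    if (!is.null(overlaps)) {
      o <- overlaps[overlaps$sv_id == v$id[i], c("gene_id", "feature",
                                                 "overlap_bp")]
      rownames(o) <- NULL
      card$gene_overlaps <- o
    }
    if (!is.null(sex_calls)) {
      card$sex_stratified_counts <- lapply(
        split(sex_calls$sample, sex_calls$label), function(s) {
          gs2 <- genotype_summary(svs$geno[i, intersect(s, colnames(svs$geno))])
          c(hom_ref = gs2$hom_ref, het = gs2$het, hom_alt = gs2$hom_alt,
            missing = gs2$missing)
        })
    }
    structure(card, class = "sv_card")
  })
  structure(cards, class = "sv_card_list", names = v$id)
}

normalise_panel <- function(x, what) {
  if (is.null(x)) return(list())
  if (is.data.frame(x)) return(setNames(list(x), what))
  x
}

#' @export
print.sv_card <- function(x, ...) {
  cat(sprintf("<sv_card> %s %s:%d-%d %s (svlen %d)\n", x$sv_id, x$chrom,
              x$pos, x$end, x$svtype, x$svlen))
  cat(sprintf("  AF = %.4f; genotypes 0/0:%d 0/1:%d 1/1:%d ./.:%d; HWE p = %.3g\n",
              x$alt_allele_frequency, x$genotype_counts[["hom_ref"]],
              x$genotype_counts[["het"]], x$genotype_counts[["hom_alt"]],
              x$genotype_counts[["missing"]], x$hwe_p))
  if (x$shared) cat(sprintf("  shared with %s\n", x$shared_partner))
  invisible(x)
}

#' Write SV cards as JSON lines
#'
#' @param cards an `sv_card_list` from [sv_cards()].
#' @param path output path (one JSON object per line).
#' @export
write_sv_cards <- function(cards, path) {
  lines <- vapply(cards, function(card) {
    card$gene_overlaps <- if (!is.null(card$gene_overlaps))
      card$gene_overlaps else NULL
    jsonlite::toJSON(unclass(card), auto_unbox = TRUE, digits = NA,
                     na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Variant count summary table (per type and caller)
#'
#' @param sets named list of [sv_set()] objects (and/or
#'   [genotype_matrix()] objects of small variants, classified SNP/INDEL).
#' @param shared optional `pairs` data.frame from [find_shared()]; adds a
#'   `Shared` column counting pairs by the type of the first set's record.
#' @return data.frame of counts, one row per variant type plus `ALL`.
#' @export
summary_table_counts <- function(sets, shared = NULL) {
  type_counts <- lapply(sets, function(s) {
    if (inherits(s, "sv_set")) table(s$variants$svtype)
    else {
      is_snp <- nchar(s$loci$ref) == 1 & nchar(s$loci$alt) == 1
      table(ifelse(is_snp, "SNP", "INDEL"))
    }
  })
  shared_counts <- NULL
  if (!is.null(shared) && nrow(shared) > 0) {
    first <- sets[[1]]
    t_of <- first$variants$svtype[match(shared$id_a, first$variants$id)]
    shared_counts <- table(t_of)
  }
  types <- unique(c(unlist(lapply(type_counts, names)),
                    names(shared_counts)))
  types <- intersect(c("DEL", "DUP", "INS", "INDEL", "SNP"), types)
  out <- data.frame(type = c(types, "ALL"), stringsAsFactors = FALSE)
  for (nm in names(sets)) {
    cnt <- setNames(rep(0L, length(types)), types)
    tc <- type_counts[[nm]]
    cnt[names(tc)] <- as.integer(tc)
    out[[nm]] <- c(cnt, sum(cnt))
  }
  if (!is.null(shared)) {
    cnt <- setNames(rep(0L, length(types)), types)
    if (!is.null(shared_counts)) cnt[names(shared_counts)] <- as.integer(shared_counts)
    out[["Shared"]] <- c(cnt, sum(cnt))
  }
  out
}

#' Write the full set of summary tables
#'
#' Emits count, affected-base and overlap/tag summary TSVs.
#'
#' @param path_prefix file prefix; `<prefix>_counts.tsv` etc. are written.
#' @param counts table from [summary_table_counts()].
#' @param affected named list of [affected_bases()] summaries.
#' @param overlap_tag named list of [tag_overlap_summary()] tables.
#' @return character vector of written paths, invisibly.
#' @export
write_summary_tables <- function(path_prefix, counts = NULL,
                                 affected = NULL, overlap_tag = NULL) {
  written <- character(0)
  wr <- function(df, suffix) {
    p <- paste0(path_prefix, "_", suffix, ".tsv")
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  if (!is.null(counts)) wr(counts, "counts")
  if (!is.null(affected)) {
    for (nm in names(affected)) {
      df <- as.data.frame(affected[[nm]])
      df$bases <- format(df$bases, scientific = FALSE, trim = TRUE)
      wr(df, paste0("affected_", nm))
    }
  }
  if (!is.null(overlap_tag)) {
    for (nm in names(overlap_tag)) wr(overlap_tag[[nm]], nm)
  }
  invisible(written)
}
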