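# Site-level filtering of caller output and affected-base accounting.
#
# Rules are applied in a fixed order (size, contig, 1-bp deletion, MSHQ,
# DHFFC) and each removed record is attributed to the first rule it fails,
# so filter reports are reproducible and their counts conserve totals.

#' Smoove-style site filter decision
#'
#' Implements the caller developer's recommended site filters: mean
#' heterozygous-sample quality (MSHQ) strictly greater than `mshq_min` for
#' all SVs, and a duphold-style depth fold change (DHFFC) strictly below
#' `dhffc_del_max` for deletions / strictly above `dhffc_dup_min` for
#' duplications. DHFFC is a per-sample quantity; it is aggregated per site
#' as the median over carrier samples (dosage >= 1). Sites with no MSHQ
#' (no heterozygous sample) or no carrier DHFFC pass the corresponding rule
#' and are counted as pass-throughs.
#'
#' @param x an [sv_set()] carrying `mshq` and a `dhffc` matrix.
#' @param mshq_min keep requires MSHQ strictly greater than this (default 3).
#' @param dhffc_del_max deletions kept only when median carrier DHFFC is
#'   strictly below this (default 0.7).
#' @param dhffc_dup_min duplications kept only when median carrier DHFFC is
#'   strictly above this (default 1.25).
#' @return data.frame with columns `id`, `keep`, `rule` (failing rule label
#'   or `NA`) and `passthrough` (rule skipped for lack of data).
#' @export
filter_smoove_site <- function(x, mshq_min = 3, dhffc_del_max = 0.7,
                               dhffc_dup_min = 1.25) {
  v <- x$variants
  keep <- rep(TRUE, nrow(v))
  rule <- rep(NA_character_, nrow(v))
  passthrough <- rep(FALSE, nrow(v))

  has_mshq <- !is.na(v$mshq)
  fail_mshq <- has_mshq & v$mshq <= mshq_min
  rule[fail_mshq] <- "MSHQ"
  keep[fail_mshq] <- FALSE
  passthrough[!has_mshq] <- TRUE

  carrier_med <- rep(NA_real_, nrow(v))
  if (!is.null(x$dhffc)) {
    for (i in seq_len(nrow(v))) {
      carriers <- !is.na(x$geno[i, ]) & x$geno[i, ] >= 1L
      vals <- x$dhffc[i, carriers]
      vals <- vals[!is.na(vals)]
      if (length(vals)) carrier_med[i] <- median(vals)
    }
  }
  need_dhffc <- v$svtype %in% c("DEL", "DUP")
  fail_dhffc <- keep & need_dhffc & !is.na(carrier_med) &
    ifelse(v$svtype == "DEL", carrier_med >= dhffc_del_max,
           carrier_med <= dhffc_dup_min)
  rule[fail_dhffc] <- "DHFFC"
  keep[fail_dhffc] <- FALSE
  passthrough[need_dhffc & is.na(carrier_med)] <- TRUE

  data.frame(id = v$id, keep = keep, rule = rule,
             passthrough = passthrough, stringsAsFactors = FALSE)
}

#' Universal SV site filters
#'
#' Removes records whose span (`end - pos`) strictly exceeds `max_len`
#' (default 0.5 Mb), records on contigs outside `chromosome_whitelist`, and
#' 1-bp deletions (spurious single-base deletion calls).
#'
#' @param x an [sv_set()].
#' @param max_len maximum allowed span in bp; strictly larger spans removed.
#' @param chromosome_whitelist character vector of allowed contig names.
#' @return list with elements `svs` (filtered [sv_set()]), `decisions`
#'   (per-record data.frame) and `report` (a `filter_report`).
#' @export
filter_universal <- function(x, max_len = 500000,
                             chromosome_whitelist = NULL) {
  if (is.null(chromosome_whitelist) || length(chromosome_whitelist) == 0)
    stopf("chromosome_whitelist must be a non-empty character vector")
  v <- x$variants
  span <- v$end - v$pos
  keep <- rep(TRUE, nrow(v))
  rule <- rep(NA_character_, nrow(v))

  fail <- span > max_len
  rule[fail] <- "size"; keep[fail] <- FALSE
  fail <- keep & !(v$chrom %in% chromosome_whitelist)
  rule[fail] <- "contig"; keep[fail] <- FALSE
  fail <- keep & v$svtype == "DEL" & span == 1L
  rule[fail] <- "del_1bp"; keep[fail] <- FALSE

  decisions <- data.frame(id = v$id, keep = keep, rule = rule,
                          stringsAsFactors = FALSE)
  list(svs = sv_subset(x, keep), decisions = decisions,
       report = filter_report(decisions))
}

#' Apply all site filters for one caller
#'
#' Universal rules first (size, contig, 1-bp deletion), then the
#' Smoove-specific MSHQ/DHFFC rules when `smoove_rules = TRUE`; attribution
#' is to the first failing rule in that order.
#'
#' @inheritParams filter_universal
#' @inheritParams filter_smoove_site
#' @param smoove_rules apply MSHQ/DHFFC rules (the second caller does not
#'   emit these fields, so the rules are skipped for it).
#' @return list with `svs`, `decisions` and `report` as in
#'   [filter_universal()].
#' @export
filter_caller_set <- function(x, chromosome_whitelist, max_len = 500000,
                              smoove_rules = FALSE, mshq_min = 3,
                              dhffc_del_max = 0.7, dhffc_dup_min = 1.25) {
  uni <- filter_universal(x, max_len = max_len,
                          chromosome_whitelist = chromosome_whitelist)
  decisions <- uni$decisions
  if (smoove_rules) {
    sm <- filter_smoove_site(uni$svs, mshq_min = mshq_min,
                             dhffc_del_max = dhffc_del_max,
                             dhffc_dup_min = dhffc_dup_min)
    i <- match(sm$id, decisions$id)
    decisions$keep[i] <- sm$keep
    decisions$rule[i[!sm$keep]] <- sm$rule[!sm$keep]
  }
  list(svs = sv_subset(x, decisions$keep), decisions = decisions,
       report = filter_report(decisions))
}

#' Summarise per-record filter decisions
#'
#' @param decisions data.frame with `keep` and `rule` columns.
#' @return object of class `filter_report` with `input_count`,
#'   `removed_by_rule` (named integer vector) and `output_count`;
#'   `input_count == output_count + sum(removed_by_rule)`.
#' @export
filter_report <- function(decisions) {
  removed <- table(decisions$rule[!decisions$keep])
  structure(list(input_count = nrow(decisions),
                 removed_by_rule = setNames(as.integer(removed),
                                            names(removed)),
                 output_count = sum(decisions$keep)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> in=%d out=%d\n", x$input_count, x$output_count))
  for (r in names(x$removed_by_rule))
    cat(sprintf("  removed by %s: %d\n", r, x$removed_by_rule[[r]]))
  invisible(x)
}

#' GATK-style hard filter for small variants
#'
#' A site is dropped when any single rule fires; annotations absent from the
#' metrics never trigger a rule. SNP rules: QD < 2, FS > 60, MQ < 40,
#' MQRankSum < -12.5, ReadPosRankSum < -8. Indel rules: QD < 2, FS > 200,
#' ReadPosRankSum < -20. All inequalities are strict, so a metric exactly at
#' its threshold passes.
#'
#' @param site_metrics data.frame (or single-row list) with any of the
#'   columns `QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`; `NA` or absent
#'   values pass.
#' @param variant_class `"SNP"` or `"INDEL"`.
#' @return data.frame with `keep` (logical) and `failed_rules` (comma-joined
#'   labels, `""` when kept).
#' @export
gatk_hard_filter <- function(site_metrics, variant_class) {
  variant_class <- match.arg(variant_class, c("SNP", "INDEL"))
  m <- as.data.frame(site_metrics)
  rules <- if (variant_class == "SNP") {
    list(QD = function(v) v < 2, FS = function(v) v > 60,
         MQ = function(v) v < 40, MQRankSum = function(v) v < -12.5,
         ReadPosRankSum = function(v) v < -8)
  } else {
    list(QD = function(v) v < 2, FS = function(v) v > 200,
         ReadPosRankSum = function(v) v < -20)
  }
  n <- nrow(m)
  failed <- matrix(FALSE, nrow = n, ncol = length(rules),
                   dimnames = list(NULL, names(rules)))
  for (r in names(rules)) {
    if (r %in% names(m)) {
      hit <- rules[[r]](m[[r]])
      failed[, r] <- !is.na(hit) & hit
    }
  }
  labels <- apply(failed, 1, function(row)
    paste(colnames(failed)[row], collapse = ","))
  data.frame(keep = rowSums(failed) == 0, failed_rules = labels,
             stringsAsFactors = FALSE)
}

#' Affected-base totals and percent of genome
#'
#' Base accounting follows the additive convention: SNP loci count one base,
#' indels and SV insertions the absolute REF/ALT length difference, and SV
#' deletions/duplications their reference span. Overlapping records within a
#' set are intentionally double-counted.
#'
#' @param x an [sv_set()], a [genotype_matrix()] of small variants (loci are
#'   classified SNP vs INDEL from REF/ALT lengths), or a named numeric
#'   vector of per-type base totals.
#' @param genome_length total reference length in bp.
#' @return data.frame of class `affected_bases_summary` with columns `type`,
#'   `bases`, `percent` (numeric), `display` (e.g. `"4.70%"`), including an
#'   `ALL` row equal to the per-type sum.
#' @export
affected_bases <- function(x, genome_length) {
  if (genome_length <= 0) stopf("genome_length must be positive")
  per_type <- if (inherits(x, "sv_set")) {
    ai <- affected_interval(x)
    tapply(as.numeric(ai$affected_bp), x$variants$svtype, sum)
  } else if (inherits(x, "genotype_matrix")) {
    is_snp <- nchar(x$loci$ref) == 1 & nchar(x$loci$alt) == 1
    bp <- ifelse(is_snp, 1, abs(nchar(x$loci$ref) - nchar(x$loci$alt)))
    tapply(as.numeric(bp), ifelse(is_snp, "SNP", "INDEL"), sum)
  } else {
    x
  }
  per_type <- per_type[!is.na(per_type)]
  types <- names(per_type)
  bases <- c(as.numeric(per_type), sum(per_type))
  out <- data.frame(type = c(types, "ALL"), bases = bases,
                    percent = 100 * bases / genome_length,
                    stringsAsFactors = FALSE)
  out$display <- sprintf("%.2f%%", out$percent)
  class(out) <- c("affected_bases_summary", "data.frame")
  attr(out, "genome_length") <- genome_length
  out
}
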