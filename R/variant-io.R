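# Reading, writing and normalising variant call files.
#
# Two containers are used throughout the package:
#   * `sv_set`          -- structural-variant sites with per-sample genotype
#                          dosages and optional per-sample DHFFC values;
#   * `genotype_matrix` -- biallelic small-variant loci x samples dosage
#                          matrix (0/1/2, NA = missing).
# All coordinates are 1-based inclusive, as in VCF and GTF.

#' Construct a structural-variant call set
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `end`,
#'   `svtype` (one of `"DEL"`, `"DUP"`, `"INS"`), `svlen` (signed bp) and
#'   optionally `mshq` (mean heterozygous-sample site quality, `NA` when the
#'   caller does not emit it or no sample is heterozygous).
#' @param geno integer matrix of allele dosages (0, 1, 2, `NA` = missing),
#'   one row per variant (rownames = `variants$id`), one column per sample.
#' @param dhffc optional numeric matrix, same shape as `geno`, of per-sample
#'   depth fold-change values (depth inside the SV relative to its flanks).
#' @param caller label identifying the producing caller.
#' @return object of class `sv_set`.
#' @export
sv_set <- function(variants, geno, dhffc = NULL, caller = "caller") {
  required <- c("id", "chrom", "pos", "end", "svtype", "svlen")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0)
    stopf("variants is missing columns: %s", paste(missing_cols, collapse = ", "))
  if (!"mshq" %in% names(variants)) variants$mshq <- NA_real_
  if (anyDuplicated(variants$id))
    stopf("duplicated SV ids in call set")
  if (any(variants$end < variants$pos))
    stopf("invalid SV span: end < pos")
  for (col in c("pos", "end", "svlen"))
    variants[[col]] <- as.integer(variants[[col]])
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(variants))
    stopf("geno has %d rows but variants has %d", nrow(geno), nrow(variants))
  rownames(geno) <- variants$id
  if (!is.null(dhffc)) {
    dhffc <- as.matrix(dhffc)
    storage.mode(dhffc) <- "double"
    stopifnot(all(dim(dhffc) == dim(geno)))
    rownames(dhffc) <- variants$id
    colnames(dhffc) <- colnames(geno)
  }
  structure(
    list(variants = as.data.frame(variants, stringsAsFactors = FALSE),
         geno = geno, dhffc = dhffc, caller = caller),
    class = "sv_set")
}

#' @export
print.sv_set <- function(x, ...) {
  cat(sprintf("<sv_set> %s: %d variants x %d samples\n",
              x$caller, nrow(x$variants), ncol(x$geno)))
  print(table(x$variants$svtype))
  invisible(x)
}

#' @rdname sv_set
#' @param x an `sv_set`.
#' @export
n_variants <- function(x) nrow(x$variants)

#' Subset a call set by variant index or id
#'
#' @param x an `sv_set`.
#' @param i integer or logical index, or character vector of ids.
#' @export
sv_subset <- function(x, i) {
  if (is.character(i)) i <- match(i, x$variants$id)
  sv_set(x$variants[i, , drop = FALSE],
         x$geno[i, , drop = FALSE],
         if (!is.null(x$dhffc)) x$dhffc[i, , drop = FALSE],
         caller = x$caller)
}

#' Construct a dosage genotype matrix
#'
#' @param loci data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param dosage integer matrix loci x samples with entries 0/1/2/`NA`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(loci, dosage) {
  required <- c("id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols) > 0)
    stopf("loci is missing columns: %s", paste(missing_cols, collapse = ", "))
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(loci))
    stopf("dosage has %d rows but loci has %d", nrow(dosage), nrow(loci))
  rownames(dosage) <- loci$id
  structure(list(loci = as.data.frame(loci, stringsAsFactors = FALSE),
                 dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d loci x %d samples\n",
              nrow(x$loci), ncol(x$dosage)))
  invisible(x)
}

# Convert VCF GT strings to dosages. Any genotype containing "." is missing;
# anything not matching a diploid GT pattern is treated as missing with a
# warning. Alleles > 1 must be excluded upstream (biallelic contract).
gt_to_dosage <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  d <- rep(NA_integer_, length(gt))
  ok <- grepl("^[01]/[01]$", gt)
  d[ok] <- (substr(gt[ok], 1, 1) == "1") + (substr(gt[ok], 3, 3) == "1")
  bad <- !ok & !grepl("\\.", gt) & !is.na(gt)
  if (any(bad))
    warnf("%d malformed genotypes treated as missing (e.g. '%s')",
          sum(bad), gt[bad][1])
  d
}

#' Read a structural-variant VCF into an `sv_set`
#'
#' Biallelic DEL/DUP/INS records are retained and renumbered
#' `<caller_label>-N` in file order starting at 1, mirroring the
#' caller-prefixed id scheme (`manta-1234`, `smoove-2345`) used when merging
#' call sets. Multi-allelic sites and SV types other than DEL/DUP/INS (BND,
#' INV, ...) are skipped with a message. Symbolic ALT records without an INFO
#' END are a parse error.
#'
#' @param path VCF 4.x file (plain or gzipped) with a GT FORMAT field.
#' @param caller_label prefix for the assigned record ids.
#' @return an [sv_set()].
#' @export
read_sv_vcf <- function(path, caller_label) {
  vcf <- VariantAnnotation::readVcf(path, genome = "cohort")
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(alt_list)
  multi <- n_alt > 1
  if (any(multi))
    message(sum(multi), " multi-allelic site(s) skipped")
  alt1 <- rep(NA_character_, length(vcf))
  alt1[!multi] <- vapply(alt_list[!multi], function(a)
    as.character(a)[1] %||% NA_character_, character(1))

  inf <- VariantAnnotation::info(vcf)
  svtype <- if ("SVTYPE" %in% names(inf)) as.character(inf$SVTYPE) else {
    # infer from symbolic ALT
    sub("^<(.*)>$", "\\1", alt1)
  }
  keep <- !multi & svtype %in% c("DEL", "DUP", "INS")
  n_skipped <- sum(!multi & !svtype %in% c("DEL", "DUP", "INS"))
  if (n_skipped > 0)
    message(n_skipped, " non-DEL/DUP/INS record(s) skipped")

  rr <- SummarizedExperiment::rowRanges(vcf)
  pos <- GenomicRanges::start(rr)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  ref <- as.character(VariantAnnotation::ref(vcf))
  end_info <- if ("END" %in% names(inf)) inf$END else rep(NA_integer_, length(vcf))
  svlen <- if ("SVLEN" %in% names(inf)) {
    sl <- inf$SVLEN
    if (is.list(sl) || methods::is(sl, "List"))
      vapply(sl, function(v) if (length(v)) as.integer(v[1]) else NA_integer_,
             integer(1))
    else as.integer(sl)
  } else rep(NA_integer_, length(vcf))
  mshq <- if ("MSHQ" %in% names(inf)) as.numeric(inf$MSHQ) else
    rep(NA_real_, length(vcf))

  symbolic <- grepl("^<.*>$", alt1)
  need_end <- keep & symbolic & is.na(end_info)
  if (any(need_end))
    stopf("symbolic ALT record(s) without INFO END at %s",
          paste(head(paste0(chrom[need_end], ":", pos[need_end]), 3),
                collapse = ", "))

  # sequence-resolved records: END from REF length; INS affect a breakpoint
  end <- end_info
  seqres <- keep & !symbolic
  end[seqres] <- pos[seqres] + nchar(ref[seqres]) - 1L
  # symbolic INS: breakpoint record, END = POS
  end[keep & symbolic & svtype == "INS" & is.na(end)] <-
    pos[keep & symbolic & svtype == "INS" & is.na(end)]

  # fill SVLEN where derivable
  der <- keep & is.na(svlen) & svtype %in% c("DEL", "DUP")
  svlen[der] <- (end[der] - pos[der]) * ifelse(svtype[der] == "DEL", -1L, 1L)
  ins_seq <- keep & is.na(svlen) & svtype == "INS" & !symbolic
  svlen[ins_seq] <- nchar(alt1[ins_seq]) - nchar(ref[ins_seq])

  idx <- which(keep)
  variants <- data.frame(
    id = paste0(caller_label, "-", seq_along(idx)),
    chrom = chrom[idx], pos = pos[idx], end = as.integer(end[idx]),
    svtype = svtype[idx], svlen = svlen[idx], mshq = mshq[idx],
    stringsAsFactors = FALSE)

  gt <- VariantAnnotation::geno(vcf)$GT
  geno <- matrix(gt_to_dosage(gt[idx, , drop = FALSE]),
                 nrow = length(idx), dimnames = list(NULL, colnames(gt)))
  dhffc <- NULL
  if ("DHFFC" %in% names(VariantAnnotation::geno(vcf))) {
    dh <- VariantAnnotation::geno(vcf)$DHFFC
    dhffc <- matrix(as.numeric(dh[idx, , drop = FALSE]),
                    nrow = length(idx), dimnames = list(NULL, colnames(dh)))
  }
  sv_set(variants, geno, dhffc, caller = caller_label)
}

# Format a numeric for VCF output ('.' for NA).
vcf_num <- function(x, digits = 4) ifelse(is.na(x), ".", formatC(x, digits = digits, format = "g"))

dosage_to_gt <- function(d) {
  gt <- rep("./.", length(d))
  gt[!is.na(d) & d == 0L] <- "0/0"
  gt[!is.na(d) & d == 1L] <- "0/1"
  gt[!is.na(d) & d == 2L] <- "1/1"
  gt
}

#' Write an `sv_set` to a VCF 4.2 file
#'
#' Records are written with symbolic ALT alleles (`<DEL>`, `<DUP>`, `<INS>`),
#' INFO END/SVTYPE/SVLEN/MSHQ and FORMAT GT (plus DHFFC when present), so
#' that [read_sv_vcf()] on the output reproduces the set.
#'
#' @param x an [sv_set()].
#' @param path output file path.
#' @param contig_lengths optional named vector of contig lengths for the
#'   header; defaults to the maximum end seen per contig.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(x, path, contig_lengths = NULL) {
  v <- x$variants
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(v$end, v$chrom, max)
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant described in this record\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Difference in length between REF and ALT alleles\">",
    "##INFO=<ID=MSHQ,Number=1,Type=Float,Description=\"Mean quality score across heterozygous samples\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  has_dhffc <- !is.null(x$dhffc)
  if (has_dhffc)
    hdr <- c(hdr, "##FORMAT=<ID=DHFFC,Number=1,Type=Float,Description=\"Fold change of variant depth relative to flanking regions\">")
  samples <- colnames(x$geno)
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", samples), collapse = "\t"))

  ord <- order(v$chrom, v$pos)
  info <- sprintf("END=%d;SVTYPE=%s;SVLEN=%d", v$end, v$svtype, v$svlen)
  info <- ifelse(is.na(v$mshq), info,
                 paste0(info, ";MSHQ=", vcf_num(v$mshq)))
  gt <- matrix(dosage_to_gt(x$geno), nrow = nrow(v))
  if (has_dhffc) {
    fmt <- "GT:DHFFC"
    cells <- matrix(paste0(gt, ":", vcf_num(x$dhffc)), nrow = nrow(v))
  } else {
    fmt <- "GT"
    cells <- gt
  }
  body <- paste(v$chrom, v$pos, v$id, "N", paste0("<", v$svtype, ">"),
                ".", "PASS", info, fmt,
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body[ord]), path)
  invisible(path)
}

#' Write a biallelic small-variant genotype matrix as VCF 4.2
#'
#' @param x a [genotype_matrix()].
#' @param path output path.
#' @param contig_lengths optional named contig-length vector for the header.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(x, path, contig_lengths = NULL) {
  l <- x$loci
  if (is.null(contig_lengths)) contig_lengths <- tapply(l$pos, l$chrom, max)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(x$dosage)), collapse = "\t"))
  ord <- order(l$chrom, l$pos)
  gt <- matrix(dosage_to_gt(x$dosage), nrow = nrow(l))
  body <- paste(l$chrom, l$pos, l$id, l$ref, l$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body[ord]), path)
  invisible(path)
}

#' Read a biallelic genotype dosage matrix from a VCF
#'
#' Dosage is the count of non-reference alleles (0, 1, 2); genotypes
#' containing `.` are missing. Multi-allelic sites are excluded, as are
#' sites whose per-site missing rate exceeds `max_missing_rate` when given.
#'
#' @param path VCF file with GT.
#' @param max_missing_rate optional per-site missing-rate ceiling; sites with
#'   a strictly larger missing fraction are dropped.
#' @return a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, max_missing_rate = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "cohort")
  alt_list <- VariantAnnotation::alt(vcf)
  biallelic <- lengths(alt_list) == 1
  gt <- VariantAnnotation::geno(vcf)$GT
  dosage <- matrix(gt_to_dosage(gt), nrow = nrow(gt),
                   dimnames = dimnames(gt))
  keep <- biallelic
  if (!is.null(max_missing_rate)) {
    miss <- rowMeans(is.na(dosage))
    keep <- keep & miss <= max_missing_rate
  }
  if (!any(keep))
    stopf("no sites retained (%d input, %d multi-allelic, %d over missing-rate threshold)",
          length(keep), sum(!biallelic),
          if (is.null(max_missing_rate)) 0L else sum(biallelic & !keep))
  rr <- SummarizedExperiment::rowRanges(vcf)
  loci <- data.frame(
    id = names(rr)[keep],
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    ref = as.character(VariantAnnotation::ref(vcf))[keep],
    alt = vapply(alt_list[keep], function(a) as.character(a)[1], character(1)),
    stringsAsFactors = FALSE)
  genotype_matrix(loci, dosage[keep, , drop = FALSE])
}

#' Affected reference interval of variant records
#'
#' Under the VCF convention for symbolic alleles POS is the base before the
#' event, so a DEL/DUP affects `pos+1 .. end` (span `end - pos` bp). An
#' insertion is a zero-length breakpoint at `pos`; the bases it contributes
#' to affected-base accounting are `|svlen|`, reported separately in
#' `affected_bp`.
#'
#' @param x an [sv_set()] or its `variants` data.frame.
#' @return data.frame with columns `id`, `chrom`, `start`, `stop`, `span`
#'   (interval length, 0 for INS) and `affected_bp` (bases counted toward
#'   genome coverage).
#' @export
affected_interval <- function(x) {
  v <- if (inherits(x, "sv_set")) x$variants else x
  if (any(v$end < v$pos)) stopf("invalid record: end < pos")
  is_ins <- v$svtype == "INS"
  start <- v$pos + 1L
  stop <- ifelse(is_ins, v$pos, v$end)
  span <- stop - start + 1L
  affected <- ifelse(is_ins, abs(v$svlen), span)
  data.frame(id = v$id, chrom = v$chrom, start = start,
             stop = stop, span = as.integer(span),
             affected_bp = as.integer(affected), stringsAsFactors = FALSE)
}

#' Export a genotype matrix as TSV
#'
#' @param x a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotype_tsv <- function(x, path) {
  df <- cbind(x$loci, as.data.frame(x$dosage))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
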