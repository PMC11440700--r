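# Chip-SNP overlap and tag-SNP discovery.
#
# A chip marker "overlaps" an SV when its position lies inside the affected
# interval (pos+1 .. end). A "tag SNP" lies OUTSIDE the interval, within
# `window` bp of the nearer SV edge, and has dosage r-squared >= `r2_min`
# with the SV. Candidates are visited nearest-first, merging both flanks
# (ties: left flank first); scanning stops once `max_tags` tags are found.

#' Read a SNP-chip manifest TSV
#'
#' @param path TSV with columns `marker_name`, `chrom`, `pos` (1-based).
#' @param panel_label label attached to the manifest.
#' @return data.frame sorted by chromosome and position, deduplicated on
#'   (chrom, pos), with attribute `panel_label`.
#' @export
read_chip_manifest <- function(path, panel_label = "chip") {
  m <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character"))
  stopifnot(all(c("marker_name", "chrom", "pos") %in% names(m)))
  m <- m[!duplicated(m[, c("chrom", "pos")]), ]
  m <- m[order(m$chrom, m$pos), ]
  rownames(m) <- NULL
  attr(m, "panel_label") <- panel_label
  m
}

#' Chip markers inside an SV's affected interval
#'
#' @param sv single-row `variants` data.frame (or single-variant
#'   [sv_set()]).
#' @param manifest chip manifest data.frame (`marker_name`, `chrom`, `pos`).
#' @return character vector of marker names; always empty for insertions
#'   (zero-length breakpoint).
#' @export
overlapping_snps <- function(sv, manifest) {
  v <- if (inherits(sv, "sv_set")) sv$variants else sv
  stopifnot(nrow(v) == 1)
  ai <- affected_interval(v)
  if (ai$span <= 0) return(character(0))
  hit <- manifest$chrom == ai$chrom & manifest$pos >= ai$start &
    manifest$pos <= ai$stop
  manifest$marker_name[hit]
}

#' Chip-marker overlap for every SV in a set
#'
#' @param svs an [sv_set()].
#' @param manifest chip manifest data.frame.
#' @return data.frame `sv_id`, `n_overlap`, `markers` (comma-joined names).
#' @export
chip_overlap <- function(svs, manifest) {
  ai <- affected_interval(svs)
  gr_sv <- GenomicRanges::GRanges(ai$chrom,
                                  IRanges::IRanges(ai$start,
                                                   pmax(ai$stop, ai$start - 1L)))
  nonempty <- ai$span > 0
  gr_m <- GenomicRanges::GRanges(manifest$chrom,
                                 IRanges::IRanges(manifest$pos, manifest$pos))
  hits <- GenomicRanges::findOverlaps(gr_sv[nonempty], gr_m)
  by_sv <- split(manifest$marker_name[S4Vectors::subjectHits(hits)],
                 factor(S4Vectors::queryHits(hits),
                        levels = seq_len(sum(nonempty))))
  markers <- vector("list", nrow(ai))
  markers[nonempty] <- by_sv
  data.frame(sv_id = ai$id,
             n_overlap = vapply(markers, length, integer(1)),
             markers = vapply(markers, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Squared dosage correlation between two loci
#'
#' Squared Pearson correlation of 0/1/2 dosages over pairwise-complete
#' samples (the quantity computed by vcftools `--geno-r2`). Undefined
#' (`NA`) when fewer than two complete pairs remain or either vector is
#' constant over them.
#'
#' @param x,y sample-aligned dosage vectors.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
r2_dosage <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (all(x == x[1]) || all(y == y[1])) return(NA_real_)
  cor(x, y)^2
}

#' Scan for tag SNPs around one SV
#'
#' @param sv single-row `variants` data.frame or single-variant [sv_set()];
#'   when an `sv_set` is given its genotypes are used as `sv_dosage`.
#' @param snp a [genotype_matrix()] of candidate SNPs (e.g. the loci of a
#'   chip panel), sample-aligned with `sv_dosage`.
#' @param sv_dosage dosage vector of the SV across samples (required when
#'   `sv` is a bare data.frame).
#' @param window maximum distance in bp from the nearer SV edge
#'   (default 10000).
#' @param r2_min minimum r-squared to record a tag (default 0.8, inclusive).
#' @param max_tags stop after this many tags (default 5).
#' @return list of class `tag_report`: `sv_id`, `tags` (data.frame
#'   `marker`, `r2`, `distance` -- signed, negative = left flank), `capped`.
#' @export
tag_scan <- function(sv, snp, sv_dosage = NULL, window = 10000,
                     r2_min = 0.8, max_tags = 5) {
  if (inherits(sv, "sv_set")) {
    stopifnot(nrow(sv$variants) == 1)
    sv_dosage <- sv$geno[1, ]
    v <- sv$variants
  } else {
    v <- sv
    stopifnot(nrow(v) == 1, !is.null(sv_dosage))
  }
  samples <- colnames(snp$dosage)
  if (!is.null(names(sv_dosage))) sv_dosage <- sv_dosage[samples]
  ai <- affected_interval(v)
  left_edge <- v$pos; right_edge <- v$end

  on_chrom <- snp$loci$chrom == v$chrom
  p <- snp$loci$pos
  inside <- on_chrom & p >= ai$start & p <= ai$stop
  left <- on_chrom & !inside & p <= left_edge & (left_edge - p) <= window
  right <- on_chrom & !inside & p > right_edge & (p - right_edge) <= window
  cand <- which(left | right)
  if (length(cand) == 0)
    return(structure(list(sv_id = v$id, tags = empty_tags(), capped = FALSE),
                     class = "tag_report"))
  dist <- ifelse(p[cand] <= left_edge, -(left_edge - p[cand]),
                 p[cand] - right_edge)
  # nearest first; ties left-flank first
  ord <- order(abs(dist), dist)
  cand <- cand[ord]; dist <- dist[ord]

  tags <- list()
  capped <- FALSE
  for (k in seq_along(cand)) {
    r2 <- r2_dosage(sv_dosage, snp$dosage[cand[k], ])
    if (!is.na(r2) && r2 >= r2_min) {
      tags[[length(tags) + 1L]] <-
        data.frame(marker = snp$loci$id[cand[k]], r2 = r2,
                   distance = dist[k], stringsAsFactors = FALSE)
      if (length(tags) == max_tags) {
        capped <- k < length(cand)
        break
      }
    }
  }
  tags <- if (length(tags)) do.call(rbind, tags) else empty_tags()
  structure(list(sv_id = v$id, tags = tags, capped = capped),
            class = "tag_report")
}

empty_tags <- function() {
  data.frame(marker = character(), r2 = numeric(), distance = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.tag_report <- function(x, ...) {
  cat(sprintf("<tag_report> %s: %d tag(s)%s\n", x$sv_id, nrow(x$tags),
              if (x$capped) " (capped)" else ""))
  if (nrow(x$tags)) print(x$tags)
  invisible(x)
}

#' Tag scan for every SV in a set
#'
#' @param svs an [sv_set()].
#' @inheritParams tag_scan
#' @return data.frame `sv_id`, `n_tags`, `capped`, `tags` (comma-joined
#'   `marker@r2`), one row per SV.
#' @export
tag_scan_all <- function(svs, snp, window = 10000, r2_min = 0.8,
                         max_tags = 5) {
  rows <- lapply(seq_len(nrow(svs$variants)), function(i) {
    rep <- tag_scan(svs$variants[i, , drop = FALSE], snp,
                    sv_dosage = svs$geno[i, ], window = window,
                    r2_min = r2_min, max_tags = max_tags)
    data.frame(sv_id = rep$sv_id, n_tags = nrow(rep$tags),
               capped = rep$capped,
               tags = paste(sprintf("%s@%.3f", rep$tags$marker, rep$tags$r2),
                            collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-type overlap / tag count summary table
#'
#' Counts SVs with at least one overlapping (or tag) SNP and renders the
#' `count (percent%)` cells used in the package's summary tables.
#'
#' @param counts named integer vector: SVs of each type with >= 1 hit.
#' @param totals named integer vector: total SVs per type (the
#'   denominators). Must cover the names of `counts`.
#' @return data.frame `type`, `count`, `total`, `percent` (numeric, `NA`
#'   when the total is zero), `display`; plus an `ALL` row.
#' @export
tag_overlap_summary <- function(counts, totals) {
  types <- names(totals)
  cnt <- setNames(rep(0L, length(types)), types)
  cnt[names(counts)] <- as.integer(counts)
  tot <- totals
  if (!"ALL" %in% types) {
    cnt <- c(cnt, ALL = sum(cnt))
    tot <- c(tot, ALL = sum(totals))
  }
  pct <- ifelse(tot == 0, NA_real_, 100 * cnt / tot)
  display <- ifelse(tot == 0, as.character(cnt),
                    paste0(cnt, " (", format_percent(cnt, tot), ")"))
  data.frame(type = names(cnt), count = as.integer(cnt),
             total = as.integer(tot), percent = pct, display = display,
             stringsAsFactors = FALSE, row.names = NULL)
}
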