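# Gene-feature overlap and processed-pseudogene artifact flagging.
#
# Exon/CDS overlaps below 10 bp are not recorded: tiny overlaps are a
# hallmark of processed-pseudogene deletion artifacts, whose split reads
# land a few bases into the flanking exons. A processed pseudogene is an
# intron-less, reverse-transcribed gene copy inserted elsewhere in the
# genome; its reads align back to the parent gene and mimic a series of
# heterozygous intron-spanning deletions with elevated exon coverage.

#' Read gene models from a GTF file
#'
#' @param path GTF (1-based inclusive) with `exon` and optionally `CDS`
#'   features carrying `gene_id` and `transcript_id` attributes.
#' @return object of class `gene_models`: list with `exons` and `cds`
#'   data.frames (`gene_id`, `transcript_id`, `chrom`, `start`, `end`) and
#'   `introns` derived per transcript as the gaps between consecutive exons.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(type = as.character(gr$type),
                   gene_id = gr$gene_id,
                   transcript_id = gr$transcript_id,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  gene_models(exons = df[df$type == "exon", -1],
              cds = df[df$type == "CDS", -1])
}

#' Construct gene models from exon / CDS tables
#'
#' @param exons data.frame with `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end` (1-based inclusive exon intervals).
#' @param cds optional data.frame with the same columns for coding parts.
#' @return a `gene_models` object (see [read_gene_models()]).
#' @export
gene_models <- function(exons, cds = NULL) {
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "start", "end")
                %in% names(exons)))
  if (is.null(cds)) cds <- exons[0, ]
  introns <- derive_introns(exons)
  structure(list(exons = exons, cds = cds, introns = introns),
            class = "gene_models")
}

# Introns of each transcript: gaps between consecutive exons.
derive_introns <- function(exons) {
  parts <- split(exons, exons$transcript_id)
  rows <- lapply(parts, function(e) {
    e <- e[order(e$start), ]
    if (nrow(e) < 2) return(NULL)
    data.frame(gene_id = e$gene_id[1], transcript_id = e$transcript_id[1],
               chrom = e$chrom[1],
               start = e$end[-nrow(e)] + 1L,
               end = e$start[-1] - 1L,
               intron_index = seq_len(nrow(e) - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), transcript_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), intron_index = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write gene models as GTF
#'
#' @param genes a `gene_models` object.
#' @param path output path.
#' @export
write_gtf <- function(genes, path) {
  fmt_rows <- function(df, type) {
    if (nrow(df) == 0) return(character(0))
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     df$gene_id, df$transcript_id)
    paste(df$chrom, "svherd", type, df$start, df$end, ".", "+", ".",
          attrs, sep = "\t")
  }
  lines <- c(fmt_rows(genes$exons, "exon"), fmt_rows(genes$cds, "CDS"))
  writeLines(lines, path)
  invisible(path)
}

#' Exon / CDS gene overlaps of SVs
#'
#' For each gene, exon (and separately CDS) intervals are unioned over
#' transcripts and intersected with each SV's affected interval; the
#' overlap is recorded only when it reaches `min_overlap` bases.
#'
#' @param svs an [sv_set()] or `variants` data.frame.
#' @param genes a `gene_models` object.
#' @param min_overlap minimum overlap in bp to record (default 10).
#' @return data.frame `sv_id`, `gene_id`, `feature` (`"exon"`/`"CDS"`),
#'   `overlap_bp`.
#' @export
gene_overlaps <- function(svs, genes, min_overlap = 10) {
  ai <- affected_interval(svs)
  ai <- ai[ai$span > 0, , drop = FALSE]
  empty <- data.frame(sv_id = character(), gene_id = character(),
                      feature = character(), overlap_bp = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(ai) == 0) return(empty)
  gr_sv <- GenomicRanges::GRanges(ai$chrom, IRanges::IRanges(ai$start, ai$stop))

  one_class <- function(feat_df, label) {
    if (nrow(feat_df) == 0) return(empty)
    gr_feat <- GenomicRanges::GRanges(feat_df$chrom,
                                      IRanges::IRanges(feat_df$start,
                                                       feat_df$end))
    # union intervals per gene so multi-transcript exons are not
    # double-counted
    by_gene <- GenomicRanges::reduce(
      GenomicRanges::split(gr_feat, feat_df$gene_id))
    flat <- unlist(by_gene)
    gene_of <- rep(names(by_gene), lengths(by_gene))
    hits <- GenomicRanges::findOverlaps(gr_sv, flat)
    if (length(hits) == 0) return(empty)
    ov <- GenomicRanges::pintersect(gr_sv[S4Vectors::queryHits(hits)],
                                    flat[S4Vectors::subjectHits(hits)])
    d <- data.frame(sv_id = ai$id[S4Vectors::queryHits(hits)],
                    gene_id = gene_of[S4Vectors::subjectHits(hits)],
                    bp = GenomicRanges::width(ov), stringsAsFactors = FALSE)
    agg <- stats::aggregate(bp ~ sv_id + gene_id, data = d, FUN = sum)
    agg <- agg[agg$bp >= min_overlap, , drop = FALSE]
    if (nrow(agg) == 0) return(empty)
    data.frame(sv_id = agg$sv_id, gene_id = agg$gene_id, feature = label,
               overlap_bp = as.integer(agg$bp), stringsAsFactors = FALSE)
  }
  out <- rbind(one_class(genes$exons, "exon"), one_class(genes$cds, "CDS"))
  out <- out[order(out$sv_id, out$feature, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag likely processed-pseudogene deletion artifacts
#'
#' A deletion "intron-matches" when both of its affected-interval boundaries
#' lie within `boundary_tol` bp of the boundaries of the same annotated
#' intron. A gene is flagged when some sample carries intron-matching
#' deletions over at least `min_introns` distinct introns of that gene.
#' Supporting evidence recorded: `intron_match` and `multi_intron_series`
#' (always, by construction), `het_only` when at least `het_fraction_min`
#' of the carrier genotypes across supporting deletions are heterozygous,
#' and `exon_coverage_elevated` when a carrier's exon coverage is at least
#' `exon_cov_ratio_min` times the cohort median (only assessed when
#' `coverage` is supplied; its absence never blocks a flag).
#'
#' All thresholds are heuristic operationalisations of qualitative signs
#' and are exposed as parameters.
#'
#' @param deletions an [sv_set()]; non-DEL records are ignored.
#' @param genes a `gene_models` object.
#' @param coverage optional data.frame `gene_id`, `sample`, `exon_depth`
#'   of per-sample mean exon coverage per gene.
#' @param boundary_tol boundary tolerance in bp (default 20).
#' @param min_introns minimum distinct intron matches sharing a carrier
#'   (default 2).
#' @param het_fraction_min heterozygous fraction for `het_only` evidence
#'   (default 0.8).
#' @param exon_cov_ratio_min coverage ratio for `exon_coverage_elevated`
#'   (default 1.3).
#' @return data.frame `gene_id`, `carriers`, `supporting_deletions`,
#'   `evidence` (comma-joined sets); zero rows when nothing is flagged.
#' @export
flag_pseudogene_artifacts <- function(deletions, genes, coverage = NULL,
                                      boundary_tol = 20, min_introns = 2,
                                      het_fraction_min = 0.8,
                                      exon_cov_ratio_min = 1.3) {
  empty <- data.frame(gene_id = character(), carriers = character(),
                      supporting_deletions = character(),
                      evidence = character(), stringsAsFactors = FALSE)
  v <- deletions$variants
  del_idx <- which(v$svtype == "DEL")
  introns <- genes$introns
  if (length(del_idx) == 0 || nrow(introns) == 0) return(empty)
  ai <- affected_interval(deletions)

  # match deletions to introns on boundary proximity
  matches <- list()
  for (i in del_idx) {
    cand <- introns$chrom == ai$chrom[i] &
      abs(introns$start - ai$start[i]) <= boundary_tol &
      abs(introns$end - ai$stop[i]) <= boundary_tol
    if (any(cand)) {
      hit <- introns[cand, , drop = FALSE]
      matches[[length(matches) + 1L]] <- data.frame(
        sv_idx = i, sv_id = v$id[i], gene_id = hit$gene_id,
        intron_key = paste0(hit$gene_id, ":", hit$start, "-", hit$end),
        stringsAsFactors = FALSE)
    }
  }
  if (length(matches) == 0) return(empty)
  m <- unique(do.call(rbind, matches))

  flags <- list()
  for (g in unique(m$gene_id)) {
    mg <- m[m$gene_id == g, , drop = FALSE]
    samples <- colnames(deletions$geno)
    # distinct introns matched by deletions carried by each sample
    introns_by_sample <- sapply(samples, function(s) {
      carried <- mg$sv_idx[deletions$geno[mg$sv_idx, s] >= 1 &
                             !is.na(deletions$geno[mg$sv_idx, s])]
      length(unique(mg$intron_key[mg$sv_idx %in% carried]))
    })
    carriers <- samples[introns_by_sample >= min_introns]
    if (length(carriers) == 0) next
    support <- unique(mg$sv_id[apply(
      deletions$geno[mg$sv_idx, carriers, drop = FALSE] >= 1, 1,
      any, na.rm = TRUE)])
    support_idx <- match(support, v$id)
    evidence <- c("intron_match", "multi_intron_series")
    gts <- deletions$geno[support_idx, , drop = FALSE]
    carried_gts <- gts[!is.na(gts) & gts >= 1]
    if (length(carried_gts) > 0 &&
        mean(carried_gts == 1) >= het_fraction_min)
      evidence <- c(evidence, "het_only")
    if (!is.null(coverage)) {
      cov_g <- coverage[coverage$gene_id == g, , drop = FALSE]
      if (nrow(cov_g) > 0) {
        med <- median(cov_g$exon_depth)
        carrier_cov <- cov_g$exon_depth[cov_g$sample %in% carriers]
        if (length(carrier_cov) > 0 && med > 0 &&
            max(carrier_cov) / med >= exon_cov_ratio_min)
          evidence <- c(evidence, "exon_coverage_elevated")
      }
    }
    flags[[length(flags) + 1L]] <- data.frame(
      gene_id = g, carriers = paste(sort(carriers), collapse = ","),
      supporting_deletions = paste(sort(support), collapse = ","),
      evidence = paste(evidence, collapse = ","), stringsAsFactors = FALSE)
  }
  if (length(flags) == 0) return(empty)
  out <- do.call(rbind, flags)
  out[order(out$gene_id), , drop = FALSE]
}
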