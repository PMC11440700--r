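# Two-caller shared-SV identification.
#
# A pair of records (one per caller) is "shared" when: same chromosome and
# SV type; the overlapping portion covers at least `min_overlap` of the
# length of EACH record; at least `min_gt_match` of the comparable genotypes
# agree; and no sample is homozygous-reference in one set and
# homozygous-alternate in the other. Matching is one-to-one: candidate
# pairs are ranked by min(frac_a, frac_b), ties broken by genotype match
# fraction then leftmost partner start, and accepted greedily.

#' Reciprocal overlap fractions of two affected intervals
#'
#' @param a,b single-row data.frames (or lists) with `chrom`, `start`,
#'   `stop` fields as produced by [affected_interval()].
#' @return numeric vector `c(frac_a, frac_b)`: intersection size over each
#'   interval's own length; `c(0, 0)` when disjoint.
#' @export
overlap_fractions <- function(a, b) {
  if (a$chrom != b$chrom) stopf("overlap_fractions requires the same chromosome")
  ov <- min(a$stop, b$stop) - max(a$start, b$start) + 1
  ov <- max(ov, 0)
  len_a <- a$stop - a$start + 1
  len_b <- b$stop - b$start + 1
  c(frac_a = if (len_a > 0) ov / len_a else 0,
    frac_b = if (len_b > 0) ov / len_b else 0)
}

#' Genotype concordance between two dosage vectors
#'
#' Samples missing in either vector are excluded from the denominator.
#' An opposing homozygote is a sample with dosage 0 in one vector and 2 in
#' the other.
#'
#' @param ga,gb sample-aligned dosage vectors (0/1/2/`NA`).
#' @return list with `match_fraction`, `opposing_hom_count`, `n_compared`.
#' @export
genotype_concordance <- function(ga, gb) {
  if (length(ga) != length(gb))
    stopf("dosage vectors have different lengths")
  ok <- !is.na(ga) & !is.na(gb)
  if (!any(ok)) stopf("no comparable genotypes (all missing)")
  ga <- ga[ok]; gb <- gb[ok]
  list(match_fraction = mean(ga == gb),
       opposing_hom_count = sum((ga == 0 & gb == 2) | (ga == 2 & gb == 0)),
       n_compared = sum(ok))
}

# Candidate-pair metrics for one pair of row indices; returns NULL when the
# pair fails any criterion.
shared_pair_metrics <- function(ia, ib, ai_a, ai_b, set_a, set_b,
                                min_overlap, min_gt_match, ins_window) {
  va <- set_a$variants[ia, ]; vb <- set_b$variants[ib, ]
  if (va$svtype == "INS") {
    # insertions are zero-length breakpoints: "overlap" is breakpoint
    # proximity within ins_window bp
    dist <- abs(va$pos - vb$pos)
    if (dist > ins_window) return(NULL)
    frac_a <- frac_b <- 1
  } else {
    fr <- overlap_fractions(ai_a[ia, ], ai_b[ib, ])
    frac_a <- fr[["frac_a"]]; frac_b <- fr[["frac_b"]]
    if (frac_a < min_overlap || frac_b < min_overlap) return(NULL)
  }
  gc <- tryCatch(genotype_concordance(set_a$geno[ia, ], set_b$geno[ib, ]),
                 error = function(e) NULL)
  if (is.null(gc)) return(NULL)
  if (gc$match_fraction < min_gt_match || gc$opposing_hom_count > 0)
    return(NULL)
  data.frame(id_a = va$id, id_b = vb$id, ia = ia, ib = ib,
             frac_a = frac_a, frac_b = frac_b,
             genotype_match_fraction = gc$match_fraction,
             opposing_homozygotes = gc$opposing_hom_count,
             partner_start = vb$pos, stringsAsFactors = FALSE)
}

#' Identify SVs shared between two call sets
#'
#' @param set_a,set_b [sv_set()] objects with identical sample sets (aligned
#'   by sample id). `set_a` plays the genotype-precedence role: merged
#'   records carry `set_a` genotypes.
#' @param min_overlap minimum reciprocal overlap fraction (default 0.9).
#' @param min_gt_match minimum genotype match fraction (default 0.9).
#' @param ins_window maximum breakpoint distance for insertion pairing in bp
#'   (insertions have no span to overlap; 100 bp by default).
#' @return list with `pairs` (data.frame of `SharedPair` rows: `id_a`,
#'   `id_b`, `frac_a`, `frac_b`, `genotype_match_fraction`,
#'   `opposing_homozygotes`, `genotype_source`) and `merged` (an [sv_set()]
#'   of the shared records with `set_a` coordinates and genotypes).
#' @export
find_shared <- function(set_a, set_b, min_overlap = 0.9, min_gt_match = 0.9,
                        ins_window = 100) {
  sa <- colnames(set_a$geno); sb <- colnames(set_b$geno)
  if (!identical(sort(sa), sort(sb)))
    stopf("call sets have different sample ids")
  if (!identical(sa, sb)) {
    # align columns by id, never by order
    set_b <- sv_set(set_b$variants, set_b$geno[, sa, drop = FALSE],
                    if (!is.null(set_b$dhffc)) set_b$dhffc[, sa, drop = FALSE],
                    caller = set_b$caller)
  }
  ai_a <- affected_interval(set_a)
  ai_b <- affected_interval(set_b)

  cand <- list()
  va <- set_a$variants; vb <- set_b$variants
  for (ia in seq_len(nrow(va))) {
    same <- which(vb$chrom == va$chrom[ia] & vb$svtype == va$svtype[ia])
    if (va$svtype[ia] == "INS") {
      near <- same[abs(vb$pos[same] - va$pos[ia]) <= ins_window]
    } else {
      # quick interval prefilter before exact fractions
      near <- same[ai_b$start[same] <= ai_a$stop[ia] &
                     ai_b$stop[same] >= ai_a$start[ia]]
    }
    for (ib in near) {
      m <- shared_pair_metrics(ia, ib, ai_a, ai_b, set_a, set_b,
                               min_overlap, min_gt_match, ins_window)
      if (!is.null(m)) cand[[length(cand) + 1L]] <- m
    }
  }
  if (length(cand) == 0) {
    pairs <- data.frame(id_a = character(), id_b = character(),
                        frac_a = numeric(), frac_b = numeric(),
                        genotype_match_fraction = numeric(),
                        opposing_homozygotes = integer(),
                        genotype_source = character(),
                        stringsAsFactors = FALSE)
    return(list(pairs = pairs, merged = sv_subset(set_a, integer(0))))
  }
  cand <- do.call(rbind, cand)
  score <- pmin(cand$frac_a, cand$frac_b)
  ord <- order(-score, -cand$genotype_match_fraction, cand$partner_start,
               cand$id_a, cand$id_b)
  cand <- cand[ord, ]
  used_a <- logical(nrow(va)); used_b <- logical(nrow(vb))
  take <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_a[cand$ia[k]] && !used_b[cand$ib[k]]) {
      take[k] <- TRUE
      used_a[cand$ia[k]] <- TRUE
      used_b[cand$ib[k]] <- TRUE
    }
  }
  sel <- cand[take, ]
  sel <- sel[order(sel$ia), ]
  pairs <- data.frame(sel[, c("id_a", "id_b", "frac_a", "frac_b",
                              "genotype_match_fraction",
                              "opposing_homozygotes")],
                      genotype_source = set_a$caller,
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(pairs = pairs, merged = sv_subset(set_a, sel$ia))
}
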