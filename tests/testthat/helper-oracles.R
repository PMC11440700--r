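# Shared fixtures and independent oracles for the test suite.
# Cohorts are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# 60-sample cohort for cheap unit tests
small_cohort <- function() cached("small", function()
  simulate_cohort(cohort_config(n_samples = 60, seed = 3)))

# the stated-world default cohort (310 samples, ~3.5k SNPs, ~300 SVs)
default_cohort <- function() cached("default", function()
  simulate_cohort(cohort_config(seed = 7)))

# --- HWE oracle: enumeration via the probability recurrence --------------
# P(h+2)/P(h) = 4 * nAA(h) * naa(h) / ((h+2) * (h+1)), independent of the
# log-factorial evaluation used by the implementation.
oracle_hwe <- function(hom_ref, het, hom_alt) {
  n <- hom_ref + het + hom_alt
  minor <- min(2 * hom_alt + het, 2 * hom_ref + het)
  hs <- seq(minor %% 2, minor, by = 2)
  p <- numeric(length(hs))
  p[1] <- 1
  for (k in seq_along(hs)[-1]) {
    h <- hs[k - 1]
    n_minor <- (minor - h) / 2
    n_major <- n - h - n_minor
    p[k] <- p[k - 1] * 4 * n_minor * n_major / ((h + 2) * (h + 1))
  }
  p <- p / sum(p)
  p_obs <- p[hs == het]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

# --- Pearson r^2 oracle from the definition sums -------------------------
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy^2 / (sxx * syy)
}

# --- KING phi oracle via explicit per-site loop --------------------------
oracle_king_phi <- function(di, dj) {
  n_both <- n_opp <- n_i <- n_j <- 0
  for (s in seq_along(di)) {
    if (is.na(di[s]) || is.na(dj[s])) next
    if (di[s] == 1 && dj[s] == 1) n_both <- n_both + 1
    if ((di[s] == 0 && dj[s] == 2) || (di[s] == 2 && dj[s] == 0))
      n_opp <- n_opp + 1
    if (di[s] == 1) n_i <- n_i + 1
    if (dj[s] == 1) n_j <- n_j + 1
  }
  if (n_i + n_j == 0) return(NA_real_)
  (n_both - 2 * n_opp) / (n_i + n_j)
}

norm_pairs <- function(df) {
  df <- df[order(df$id_a, df$id_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# --- brute-force all-pairs shared-SV oracle -------------------------------
# Independent quadratic implementation of the shared-SV criteria and the
# greedy one-to-one matching rule.
oracle_shared_pairs <- function(A, B, min_overlap = 0.9, min_gt_match = 0.9,
                                ins_window = 100) {
  va <- A$variants; vb <- B$variants
  rows <- list()
  for (i in seq_len(nrow(va))) {
    for (j in seq_len(nrow(vb))) {
      if (va$chrom[i] != vb$chrom[j] || va$svtype[i] != vb$svtype[j]) next
      if (va$svtype[i] == "INS") {
        if (abs(va$pos[i] - vb$pos[j]) > ins_window) next
        fa <- fb <- 1
      } else {
        sa <- va$pos[i] + 1; ea <- va$end[i]
        sb <- vb$pos[j] + 1; eb <- vb$end[j]
        ov <- max(0, min(ea, eb) - max(sa, sb) + 1)
        fa <- ov / (ea - sa + 1); fb <- ov / (eb - sb + 1)
        if (fa < min_overlap || fb < min_overlap) next
      }
      ga <- A$geno[i, ]; gb <- B$geno[j, colnames(A$geno)]
      ok <- !is.na(ga) & !is.na(gb)
      if (!any(ok)) next
      mf <- mean(ga[ok] == gb[ok])
      opp <- sum((ga[ok] == 0 & gb[ok] == 2) | (ga[ok] == 2 & gb[ok] == 0))
      if (mf < min_gt_match || opp > 0) next
      rows[[length(rows) + 1]] <-
        data.frame(i = i, j = j, score = min(fa, fb), mf = mf,
                   bstart = vb$pos[j], id_a = va$id[i], id_b = vb$id[j],
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(id_a = character(), id_b = character(),
                      stringsAsFactors = FALSE))
  cand <- do.call(rbind, rows)
  cand <- cand[order(-cand$score, -cand$mf, cand$bstart, cand$id_a,
                     cand$id_b), ]
  used_i <- used_j <- integer(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!(cand$i[k] %in% used_i) && !(cand$j[k] %in% used_j)) {
      keep[k] <- TRUE
      used_i <- c(used_i, cand$i[k]); used_j <- c(used_j, cand$j[k])
    }
  }
  out <- cand[keep, c("id_a", "id_b")]
  out[order(out$id_a), , drop = FALSE]
}

# --- per-base gene-overlap oracle ----------------------------------------
oracle_gene_overlaps <- function(svs, genes, min_overlap = 10) {
  ai <- affected_interval(svs)
  rows <- list()
  for (feat in c("exon", "CDS")) {
    tab <- if (feat == "exon") genes$exons else genes$cds
    for (i in seq_len(nrow(ai))) {
      if (ai$span[i] <= 0) next
      sv_bases <- ai$start[i]:ai$stop[i]
      for (g in unique(tab$gene_id)) {
        fg <- tab[tab$gene_id == g & tab$chrom == ai$chrom[i], , drop = FALSE]
        if (nrow(fg) == 0) next
        feat_bases <- unique(unlist(mapply(seq, fg$start, fg$end,
                                           SIMPLIFY = FALSE)))
        bp <- length(intersect(sv_bases, feat_bases))
        if (bp >= min_overlap)
          rows[[length(rows) + 1]] <-
            data.frame(sv_id = ai$id[i], gene_id = g, feature = feat,
                       overlap_bp = bp, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(sv_id = character(), gene_id = character(),
                      feature = character(), overlap_bp = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$sv_id, out$feature, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- random paired call sets for property tests ---------------------------
# Two noisy views of a common set of truth loci, plus caller-private loci.
random_paired_sets <- function(n_loci = 150, n_samples = 30, seed = 1,
                               jitter = 25, error = 0.05) {
  set.seed(seed)
  samples <- sprintf("P%02d", seq_len(n_samples))
  types <- sample(c("DEL", "DUP", "INS"), n_loci, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
  chrom <- sample(c("1", "2"), n_loci, replace = TRUE)
  span <- sample(200:5000, n_loci, replace = TRUE)
  pos <- sample(10000:900000, n_loci)
  truth_g <- matrix(rbinom(n_loci * n_samples, 2, 0.3), nrow = n_loci,
                    dimnames = list(NULL, samples))
  view <- function(label) {
    keep <- runif(n_loci) < 0.85
    p2 <- pmax(1L, pos + sample(-jitter:jitter, n_loci, replace = TRUE))
    e2 <- ifelse(types == "INS", p2, p2 + span +
                   sample(-jitter:jitter, n_loci, replace = TRUE))
    g <- truth_g
    flip <- matrix(runif(length(g)) < error, nrow = n_loci)
    g[flip] <- ifelse(g[flip] == 1, sample(c(0L, 2L), sum(flip), TRUE), 1L)
    g[matrix(runif(length(g)) < 0.01, nrow = n_loci)] <- NA_integer_
    idx <- which(keep)
    v <- data.frame(id = paste0(label, "-", seq_along(idx)),
                    chrom = chrom[idx], pos = p2[idx],
                    end = pmax(e2[idx], p2[idx]), svtype = types[idx],
                    svlen = ifelse(types[idx] == "DEL", -(e2[idx] - p2[idx]),
                                   ifelse(types[idx] == "DUP",
                                          e2[idx] - p2[idx], 300L)),
                    stringsAsFactors = FALSE)
    sv_set(v, g[idx, , drop = FALSE], caller = label)
  }
  list(a = view("la"), b = view("lb"))
}

# random small gene models for the overlap property test
random_gene_models <- function(n_genes = 6, seed = 1, chrom_len = 100000) {
  set.seed(seed)
  rows <- lapply(seq_len(n_genes), function(g) {
    n_ex <- sample(2:5, 1)
    ex_len <- sample(50:200, n_ex, replace = TRUE)
    in_len <- sample(100:500, n_ex - 1, replace = TRUE)
    start <- sample.int(chrom_len - sum(ex_len) - sum(in_len) - 10, 1)
    starts <- start + cumsum(c(0L, head(ex_len, -1) + in_len))
    gid <- sprintf("RG%02d", g)
    data.frame(gene_id = gid, transcript_id = paste0(gid, ".t1"),
               chrom = sample(c("1", "2"), 1), start = starts,
               end = starts + ex_len - 1L, stringsAsFactors = FALSE)
  })
  exons <- do.call(rbind, rows)
  gene_models(exons, cds = exons)
}
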