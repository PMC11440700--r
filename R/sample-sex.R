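# Sex inference from per-chromosome read-depth summaries.
#
# A diploid XX sample has X coverage near the autosome level and essentially
# no Y coverage; an XY sample has roughly half-autosome coverage on both X
# and Y. Samples with a Y:autosome ratio near 1 together with an X ratio
# near 0.5 are consistent with XYY (or XY/XYY mosaicism). Anything outside
# those regions is reported as ambiguous rather than forced into a class.

#' Default sex-classification thresholds
#'
#' The class regions were chosen to separate the XX / XY / XYY-like depth
#' clusters with wide margins; all bounds are configurable.
#'
#' @return named list of region bounds.
#' @export
sex_thresholds <- function() {
  list(xx_x_min = 0.8, xx_y_max = 0.1,
       xy_x_range = c(0.35, 0.65), xy_y_range = c(0.25, 0.75),
       xyy_y_min = 0.85)
}

#' X:autosome and Y:autosome depth ratios
#'
#' The autosome baseline is the unweighted mean of per-autosome mean depths.
#' A missing X or Y row yields a ratio of 0 with a warning.
#'
#' @param depth data.frame with columns `sample`, `chrom`, `mean_depth`.
#' @param autosomes character vector naming autosome rows; default is every
#'   chromosome other than `x_chrom`, `y_chrom` and `"MT"`.
#' @param x_chrom,y_chrom sex chromosome labels.
#' @return data.frame with `sample`, `x_ratio`, `y_ratio`.
#' @export
depth_ratios <- function(depth, autosomes = NULL, x_chrom = "X",
                         y_chrom = "Y") {
  stopifnot(all(c("sample", "chrom", "mean_depth") %in% names(depth)))
  if (is.null(autosomes))
    autosomes <- setdiff(unique(depth$chrom), c(x_chrom, y_chrom, "MT"))
  out <- lapply(split(depth, depth$sample), function(d) {
    auto <- d$mean_depth[d$chrom %in% autosomes]
    if (length(auto) == 0 || mean(auto) <= 0)
      stopf("sample %s has no positive autosome depth", d$sample[1])
    base <- mean(auto)
    xd <- d$mean_depth[d$chrom == x_chrom]
    yd <- d$mean_depth[d$chrom == y_chrom]
    if (length(xd) == 0) { warnf("sample %s: no %s depth row, x_ratio set to 0", d$sample[1], x_chrom); xd <- 0 }
    if (length(yd) == 0) { warnf("sample %s: no %s depth row, y_ratio set to 0", d$sample[1], y_chrom); yd <- 0 }
    data.frame(sample = d$sample[1], x_ratio = xd[1] / base,
               y_ratio = yd[1] / base, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sample), , drop = FALSE]
}

#' Classify sample sex from depth ratios
#'
#' Default regions: XX when `x_ratio >= 0.8` and `y_ratio <= 0.1`; XY when
#' `x_ratio` in `[0.35, 0.65]` and `y_ratio` in `[0.25, 0.75]`; XYY_like when
#' `x_ratio` in `[0.35, 0.65]` and `y_ratio >= 0.85`; otherwise ambiguous.
#'
#' @param x_ratio,y_ratio numeric vectors of depth ratios.
#' @param thresholds see [sex_thresholds()].
#' @return character vector of labels in
#'   `{"XX", "XY", "XYY_like", "ambiguous"}`.
#' @export
classify_sex <- function(x_ratio, y_ratio, thresholds = sex_thresholds()) {
  stopifnot(is.finite(x_ratio), is.finite(y_ratio))
  t <- thresholds
  label <- rep("ambiguous", length(x_ratio))
  label[x_ratio >= t$xx_x_min & y_ratio <= t$xx_y_max] <- "XX"
  in_x_band <- x_ratio >= t$xy_x_range[1] & x_ratio <= t$xy_x_range[2]
  label[in_x_band & y_ratio >= t$xy_y_range[1] &
          y_ratio <= t$xy_y_range[2]] <- "XY"
  label[in_x_band & y_ratio >= t$xyy_y_min] <- "XYY_like"
  label
}

#' Infer sex for every sample in a depth summary
#'
#' @inheritParams depth_ratios
#' @inheritParams classify_sex
#' @return data.frame with `sample`, `x_ratio`, `y_ratio`, `label`.
#' @export
infer_sex <- function(depth, autosomes = NULL, x_chrom = "X", y_chrom = "Y",
                      thresholds = sex_thresholds()) {
  r <- depth_ratios(depth, autosomes = autosomes, x_chrom = x_chrom,
                    y_chrom = y_chrom)
  r$label <- classify_sex(r$x_ratio, r$y_ratio, thresholds)
  r
}

#' Read a mosdepth-like depth summary TSV
#'
#' @param path TSV with columns `sample`, `chrom`, `mean_depth`.
#' @return data.frame.
#' @export
read_depth_summary <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(sample = "character", chrom = "character"))
  stopifnot(all(c("sample", "chrom", "mean_depth") %in% names(d)))
  if (any(d$mean_depth < 0)) stopf("negative depth values in %s", path)
  d
}
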