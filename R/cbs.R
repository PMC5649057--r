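#' Segment tumor/control depth ratios
#'
#' Circular binary segmentation on the log2 ratio of tumor to control mean
#' exon depth. At each recursion the maximal circular two-changepoint
#' statistic is tested against `alpha_seg` using a Bonferroni-corrected normal
#' bound on the max statistic; the noise scale is estimated robustly from
#' successive differences. Exons with zero control depth are dropped with a
#' warning.
#'
#' @param exons Data frame with `chrom, start, end, depth_tumor,
#'   depth_control`, sorted by genomic order.
#' @param alpha_seg Significance cutoff for declaring a changepoint.
#' @param min_width Minimum number of exons per segment.
#' @return Data frame of segments: `chrom, start, end, first_exon, last_exon,
#'   n_exons, mean_ratio` (ratio on the natural scale), covering the retained
#'   exons contiguously per chromosome.
#' @export
segment_depth_ratio <- function(exons, alpha_seg = 1e-5, min_width = 5L) {
  keep <- exons$depth_control > 0
  if (!all(keep)) {
    warning(sum(!keep), " exon(s) with zero control depth dropped")
    exons <- exons[keep, , drop = FALSE]
  }
  if (nrow(exons) == 0) stop("no exons with positive control depth")
  out <- list()
  for (chr in unique(exons$chrom)) {
    ex <- exons[exons$chrom == chr, , drop = FALSE]
    lr <- log2(pmax(ex$depth_tumor, 0.5) / ex$depth_control)
    m <- length(lr)
    if (m < 2L * min_width) {
      if (m < 10) warning("fewer than 10 exons on ", chr, "; single segment")
      bounds <- c(0L, m)
    } else {
      # robust scale from successive differences
      sigma <- stats::mad(diff(lr)) / sqrt(2)
      if (!is.finite(sigma) || sigma <= 0) sigma <- stats::sd(lr)
      if (!is.finite(sigma) || sigma <= 0) sigma <- 1e-6
      cps <- cbs_recurse(lr, 1L, m, sigma, alpha_seg, min_width)
      bounds <- sort(unique(c(0L, cps, m)))
    }
    for (b in seq_len(length(bounds) - 1L)) {
      i1 <- bounds[b] + 1L
      i2 <- bounds[b + 1L]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr,
        start = ex$start[i1],
        end = ex$end[i2],
        first_exon = i1, last_exon = i2,
        n_exons = i2 - i1 + 1L,
        mean_ratio = mean(ex$depth_tumor[i1:i2] / ex$depth_control[i1:i2]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

# recursive CBS on x[lo..hi]; returns changepoint indices (right-closed)
cbs_recurse <- function(x, lo, hi, sigma, alpha, min_width) {
  m <- hi - lo + 1L
  if (m < 2L * min_width) return(integer())
  seg <- x[lo:hi]
  sp <- cbs_best_split(seg, sigma, min_width)
  if (is.null(sp) || sp$p >= alpha) return(integer())
  cuts <- lo - 1L + sp$cuts # global right-closed boundaries
  inner <- integer()
  pieces <- cbind(c(lo, cuts + 1L), c(cuts, hi))
  for (r in seq_len(nrow(pieces))) {
    inner <- c(inner, cbs_recurse(x, pieces[r, 1], pieces[r, 2],
                                  sigma, alpha, min_width))
  }
  sort(unique(c(cuts, inner)))
}

# best circular (arc vs complement) split of one segment
cbs_best_split <- function(seg, sigma, min_width) {
  m <- length(seg)
  cs <- c(0, cumsum(seg))
  idx <- 0:m
  # arc (i, j]: pairs with width and complement both >= min_width
  ij <- which(outer(idx, idx, function(i, j) {
    w <- j - i
    w >= min_width & (m - w) >= min_width
  }), arr.ind = TRUE)
  if (nrow(ij) == 0) return(NULL)
  i <- idx[ij[, 1]]
  j <- idx[ij[, 2]]
  keep <- j > i
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(NULL)
  w <- j - i
  arc_mean <- (cs[j + 1] - cs[i + 1]) / w
  comp_mean <- (cs[m + 1] - (cs[j + 1] - cs[i + 1])) / (m - w)
  z <- abs(arc_mean - comp_mean) / (sigma * sqrt(1 / w + 1 / (m - w)))
  best <- which.max(z)
  n_tests <- length(z)
  p <- min(1, 2 * n_tests * stats::pnorm(-z[best]))
  cuts <- c(i[best], j[best])
  cuts <- cuts[cuts > 0 & cuts < m]
  list(p = p, cuts = cuts, z = z[best])
}
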