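# Matching segmented (piecewise-constant) copy-number profiles to
# expression probes and quantifying the in-cis copy-number contribution
# to expression variation.  A probe inside a segment takes the segment
# value; a probe spanning a boundary the base-weighted average; a probe
# in an inter-segment gap the value of the nearest segment (mean of the
# two at an exact tie).

#' Interpolate a piecewise-constant profile at probe positions
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`
#'   (1-based closed), `value` for one sample; per-chromosome segments
#'   must be non-overlapping.
#' @param probes `GRanges` of probes.
#' @return numeric vector, one value per probe; `NA` for probes on
#'   chromosomes absent from the profile.
#' @export
pcf_value_at_probe <- function(segments, probes) {
  out <- rep(NA_real_, length(probes))
  pchrom <- as.character(seqnames(probes))
  for (chr in unique(pchrom)) {
    seg <- segments[segments$chrom == chr, , drop = FALSE]
    if (!nrow(seg)) next
    seg <- seg[order(seg$start), , drop = FALSE]
    qi <- which(pchrom == chr)
    qs <- start(probes)[qi]; qe <- end(probes)[qi]
    for (j in seq_along(qi)) {
      cov_bases <- pmax(0, pmin(qe[j], seg$end) - pmax(qs[j], seg$start) + 1)
      if (any(cov_bases > 0)) {
        out[qi[j]] <- sum(cov_bases * seg$value) / sum(cov_bases)
      } else {
        gap <- pmax(seg$start - qe[j], qs[j] - seg$end)
        near <- which(gap == min(gap))
        out[qi[j]] <- mean(seg$value[near])
      }
    }
  }
  out
}

#' Per-probe copy-number matrix from segmented profiles
#'
#' @param seg data.frame as read by [read_seg()] (all samples stacked).
#' @param probes `GRanges` of probes with `probe_id`.
#' @param samples optional sample order (default: order of appearance).
#' @return numeric matrix probes x samples.
#' @export
cnv_matrix <- function(seg, probes, samples = unique(seg$sample_id)) {
  m <- vapply(samples, function(s) {
    pcf_value_at_probe(seg[seg$sample_id == s, , drop = FALSE], probes)
  }, numeric(length(probes)))
  rownames(m) <- as.character(probes$probe_id)
  m
}

#' In-cis Spearman correlation of expression with copy number
#'
#' @param expr numeric matrix probes x samples (tumor samples).
#' @param cn numeric matrix of matching dimensions and order.
#' @return named numeric vector of per-probe Spearman rho (`NA` when
#'   either vector is constant or contains missing values only).
#' @export
cis_spearman <- function(expr, cn) {
  stopifnot(identical(dim(expr), dim(cn)))
  if (ncol(expr) < 3) stop("need at least 3 paired samples")
  rho <- vapply(seq_len(nrow(expr)), function(i) {
    x <- cn[i, ]; y <- expr[i, ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    suppressWarnings(cor(x[ok], y[ok], method = "spearman"))
  }, 1)
  names(rho) <- rownames(expr)
  rho
}

#' Fraction of probes whose expression variation is explained by copy
#' number
#'
#' Per probe, ordinary least squares of expression on the matched
#' copy-number value across tumor samples; slope p-values are BH
#' adjusted and a probe counts as copy-number explained when its FDR is
#' below `fdr_cut`.  Probes with zero copy-number variance are excluded
#' from the denominator.
#'
#' @param expr numeric matrix probes x samples.
#' @param cn matching copy-number matrix.
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return list with `fraction` (headline count-of-significant
#'   fraction), `mean_r_squared` (pooled variance-decomposition summary)
#'   and `table` (per-probe `CisResult`s: `probe_id`, `spearman_rho`,
#'   `slope`, `r_squared`, `p`, `fdr`, `cnv_explained`).
#' @export
fraction_variance_explained <- function(expr, cn, fdr_cut = 0.05) {
  stopifnot(identical(dim(expr), dim(cn)))
  n <- ncol(expr)
  if (n < 4) stop("need at least 4 samples")
  mx <- rowMeans(cn); my <- rowMeans(expr)
  dx <- cn - mx; dy <- expr - my
  sxx <- rowSums(dx^2); syy <- rowSums(dy^2); sxy <- rowSums(dx * dy)
  usable <- sxx > 0
  slope <- ifelse(usable, sxy / sxx, NA_real_)
  r2 <- ifelse(usable & syy > 0, sxy^2 / (sxx * syy),
               ifelse(usable, 0, NA_real_))
  r2 <- pmin(r2, 1)
  tstat <- ifelse(usable & r2 < 1,
                  sign(slope) * sqrt(r2 * (n - 2) / (1 - r2)),
                  ifelse(usable, Inf * sign(slope), NA_real_))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  fdr <- rep(NA_real_, length(p))
  fdr[usable] <- bh_adjust(p[usable])
  explained <- fdr < fdr_cut
  tab <- data.frame(probe_id = rownames(expr),
                    spearman_rho = cis_spearman(expr, cn),
                    slope = slope, r_squared = r2, p = p, fdr = fdr,
                    cnv_explained = explained, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(fraction = mean(explained[usable]),
       mean_r_squared = mean(r2[usable]),
       table = tab)
}
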