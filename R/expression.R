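# Preprocessing and differential expression on log2 intensities:
# quantile normalisation, nonspecific filtering against negative-control
# background, and empirical Bayes moderated t/F statistics with
# Benjamini-Hochberg FDR control.  The variance moderation uses the
# classical hierarchical model s0^2 * F(d, d0) for residual variances,
# with (d0, s0^2) estimated by closed-form moment matching on the log
# sample variances.

#' Quantile normalisation between arrays
#'
#' Forces every column to the same empirical distribution (the row-wise
#' mean of the sorted columns); within-column ranks are preserved and
#' ties receive the average of the values they span.
#'
#' @param mat numeric matrix, probes x samples (>= 2 columns).
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Nonspecific filtering against negative-control background
#'
#' A probe is retained iff (a) its intensity exceeds the per-array
#' background threshold (mean of the array's negative-control spots plus
#' `sd_multiplier` times their standard deviation) in at least
#' `min_arrays` arrays, and (b) its interquartile range across arrays is
#' at least `iqr_min`.  Negative-control rows are never retained.
#'
#' @param mat numeric matrix, probes x samples (negative controls
#'   included as rows).
#' @param negative_control_ids rownames of the negative-control spots.
#' @param min_arrays minimum number of above-background arrays
#'   (default 4).
#' @param sd_multiplier multiplier on the negative-control SD
#'   (default 3).
#' @param iqr_min minimum row IQR (default 0.5).
#' @return character vector of retained probe ids.
#' @export
nonspecific_filter <- function(mat, negative_control_ids, min_arrays = 4,
                               sd_multiplier = 3, iqr_min = 0.5) {
  nc <- intersect(negative_control_ids, rownames(mat))
  if (!length(nc)) stop("no negative-control spots found in the matrix")
  ncm <- mat[nc, , drop = FALSE]
  thresh <- colMeans(ncm) + sd_multiplier * apply(ncm, 2, sd)
  cand <- setdiff(rownames(mat), nc)
  x <- mat[cand, , drop = FALSE]
  above <- rowSums(sweep(x, 2, thresh, `>`)) >= min_arrays
  spread <- apply(x, 1, IQR) >= iqr_min
  cand[above & spread]
}

# Newton inversion of the trigamma function (solve trigamma(x) = y)
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

# moment-matching fit of the variance prior: log s^2 is log-F shifted;
# matching mean/variance of log s^2 gives closed-form d0 and s0^2
.squeeze_var <- function(s2, df, d0_override = NULL) {
  z <- log(s2)
  fin <- is.finite(z)
  e <- z[fin] - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (!is.finite(evar)) evar <- 0
  if (evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # homoskedastic limit: all true variances equal; pooled mean is the MLE
    d0 <- Inf
    s0_sq <- mean(s2[fin])
  }
  if (!is.null(d0_override)) d0 <- d0_override
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + df * s2) / (d0 + df)
  list(d0 = d0, s0_sq = s0_sq, df_residual = df, s2_post = s2_post)
}

.design_matrix <- function(groups, batch = NULL) {
  groups <- droplevels(as.factor(groups))
  X <- stats::model.matrix(~groups)
  if (!is.null(batch)) {
    batch <- droplevels(as.factor(batch))
    if (nlevels(batch) > 1) X <- stats::model.matrix(~groups + batch)
  }
  list(X = X, groups = groups)
}

#' Moderated two-group t-statistics
#'
#' Fits a per-probe linear model with a two-level group factor (and an
#' optional additive batch covariate), shrinks the residual variances
#' towards a common prior by empirical Bayes, and tests the group
#' contrast with `d0 + df` degrees of freedom.  The contrast is
#' second level minus first level of `groups` (so with levels
#' `normal`, `tumor` the fold change is tumor - normal).
#'
#' @param mat numeric matrix, probes x samples.
#' @param groups two-level factor/character, one entry per column.
#' @param batch optional batch labels (additive covariate).
#' @param fdr_cut FDR significance cutoff recorded in the result
#'   (default 0.05).
#' @param d0_override force the prior degrees of freedom: `0` gives the
#'   ordinary per-probe t, `Inf` the fully pooled-variance t.
#' @return list with `table` (data.frame: `probe_id`, `log2fc`, `t`,
#'   `p`, `fdr`, `significant`, `direction`) and `fit` (the
#'   `ModerationFit`: `d0`, `s0_sq`, `df_residual`, `s2_post`).
#' @export
fit_moderated_t <- function(mat, groups, batch = NULL, fdr_cut = 0.05,
                            d0_override = NULL) {
  dm <- .design_matrix(groups, batch)
  X <- dm$X; groups <- dm$groups
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (min(table(groups)) < 2) stop("each group needs >= 2 samples")
  n <- ncol(mat); p <- ncol(X)
  df <- n - p
  if (df <= 0) stop("zero residual degrees of freedom")
  fit <- stats::lm.fit(X, t(mat))
  coefs <- t(fit$coefficients)
  res <- fit$residuals
  s2 <- colSums(res^2) / df
  sq <- .squeeze_var(s2, df, d0_override)
  ci <- 2L  # group coefficient (intercept first)
  v <- diag(solve(crossprod(X)))[ci]
  lfc <- coefs[, ci]
  tstat <- lfc / sqrt(sq$s2_post * v)
  df_total <- df + sq$d0
  pval <- 2 * pt(-abs(tstat), df = df_total)
  fdr <- bh_adjust(pval)
  lev2 <- levels(groups)[2]
  tab <- data.frame(
    probe_id = rownames(mat), log2fc = unname(lfc), t = unname(tstat),
    p = unname(pval), fdr = unname(fdr), significant = unname(fdr < fdr_cut),
    direction = ifelse(lfc > 0, paste0("up_in_", lev2),
                       paste0("down_in_", lev2)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, fit = sq)
}

#' Moderated F-statistics across subtype means
#'
#' Tests, per probe, whether the mean expression is equal across all
#' levels of `subtypes` (optionally adjusting for batch), using the same
#' empirical Bayes variance shrinkage as [fit_moderated_t()].  With two
#' levels the statistic equals the squared moderated t.
#'
#' @param mat numeric matrix, probes x samples.
#' @param subtypes factor with >= 2 levels, one entry per column.
#' @param batch optional batch labels.
#' @param fdr_cut FDR cutoff recorded in the result (default 0.1; a less
#'   stringent default than the two-group contrast, reflecting the
#'   smaller per-level sample sizes).
#' @param d0_override force the prior degrees of freedom.
#' @return list with `table` (`probe_id`, `f`, `p`, `fdr`,
#'   `significant`) and `fit`.
#' @export
fit_moderated_f <- function(mat, subtypes, batch = NULL, fdr_cut = 0.1,
                            d0_override = NULL) {
  subtypes <- droplevels(as.factor(subtypes))
  k <- nlevels(subtypes)
  if (k < 2) stop("need >= 2 subtype levels")
  if (sum(table(subtypes) >= 2) < 2) stop("need >= 2 samples in >= 2 levels")
  dm <- .design_matrix(subtypes, batch)
  X <- dm$X
  X0 <- X[, !grepl("^groups", colnames(X)), drop = FALSE]
  n <- ncol(mat)
  df <- n - ncol(X)
  if (df <= 0) stop("zero residual degrees of freedom")
  fit1 <- stats::lm.fit(X, t(mat))
  fit0 <- stats::lm.fit(X0, t(mat))
  rss1 <- colSums(fit1$residuals^2)
  rss0 <- colSums(fit0$residuals^2)
  s2 <- rss1 / df
  sq <- .squeeze_var(s2, df, d0_override)
  df1 <- k - 1
  fstat <- ((rss0 - rss1) / df1) / sq$s2_post
  pval <- pf(fstat, df1, df + sq$d0, lower.tail = FALSE)
  fdr <- bh_adjust(pval)
  tab <- data.frame(probe_id = rownames(mat), f = unname(fstat),
                    p = unname(pval), fdr = unname(fdr),
                    significant = unname(fdr < fdr_cut),
                    stringsAsFactors = FALSE)
  list(table = tab, fit = sq)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate,
#' clipped to 1 and monotone in the p-value ranks.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}
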