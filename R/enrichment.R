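# Annotation-overlap enrichment of DE probes.  A probe counts as
# overlapping when at least `min_fraction` (default 90%) of it lies
# inside a single annotation interval.  The 2x2 table compares DE probes
# against the full background list of array probes (which, as stated,
# includes the DE probes); odds are overlap/(total - overlap) and the
# odds ratio their quotient, tested by Fisher's exact test with an exact
# conditional 95% CI.

#' Count annotation overlaps for a DE set against the array background
#'
#' @param de_probes `GRanges` of DE probes (must be a subset of the
#'   background, by `probe_id` when present).
#' @param background_probes `GRanges` of all probes on the array.
#' @param track `GRanges` annotation track.
#' @param min_fraction minimum single-interval overlap fraction
#'   (default 0.9).
#' @param strand_mode strand filter passed to [overlap_fraction()].
#' @param union evaluate coverage against the union of track intervals
#'   instead of the best single interval.
#' @param annotation,direction labels carried into the result.
#' @return list of class `overlap_count` with the four counts.
#' @export
count_annotation_overlaps <- function(de_probes, background_probes, track,
                                      min_fraction = 0.9,
                                      strand_mode = "ignore", union = FALSE,
                                      annotation = "track",
                                      direction = "all") {
  if (!length(background_probes)) stop("empty background probe set")
  if (!is.null(de_probes$probe_id) && !is.null(background_probes$probe_id) &&
      !all(de_probes$probe_id %in% background_probes$probe_id)) {
    stop("DE probes must be a subset of the background")
  }
  de_ov <- sum(overlap_fraction(de_probes, track, strand_mode,
                                union = union) >= min_fraction)
  bg_ov <- sum(overlap_fraction(background_probes, track, strand_mode,
                                union = union) >= min_fraction)
  structure(list(annotation = annotation, direction = direction,
                 n_de_overlap = de_ov, n_de_total = length(de_probes),
                 n_bg_overlap = bg_ov, n_bg_total = length(background_probes)),
            class = "overlap_count")
}

#' Fisher's exact enrichment of an overlap count
#'
#' Builds the 2x2 table (DE overlap / DE non-overlap vs background
#' overlap / background non-overlap), reports observed and background
#' odds, their ratio, the conditional maximum-likelihood odds ratio, the
#' exact 95% CI and the two-sided exact p-value (summing all tables at
#' most as probable as the observed one).  Zero margins give 0 or `Inf`
#' odds with a one-sided CI, as returned by the exact test.
#'
#' @param counts `overlap_count` object.
#' @param conf_level confidence level (default 0.95).
#' @param background_exclusive subtract the DE counts from the
#'   background before testing (sensitivity-analysis mode; the default
#'   keeps DE probes inside the background list, as defined).
#' @return one-row data.frame (class `enrichment_result`).
#' @export
fisher_enrichment <- function(counts, conf_level = 0.95,
                              background_exclusive = FALSE) {
  stopifnot(inherits(counts, "overlap_count"))
  a <- counts$n_de_overlap; b <- counts$n_de_total - a
  cc <- counts$n_bg_overlap; d <- counts$n_bg_total - counts$n_bg_overlap
  if (counts$n_de_total < 1) stop("need at least one DE probe")
  if (background_exclusive) { cc <- cc - a; d <- d - b }
  odds_obs <- if (b == 0) Inf else a / b
  odds_bg <- if (d == 0) Inf else cc / d
  or <- if (is.infinite(odds_obs) && is.infinite(odds_bg)) NaN else
    odds_obs / odds_bg
  ft <- fisher.test(matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE),
                    conf.level = conf_level)
  out <- data.frame(annotation = counts$annotation,
                    direction = counts$direction,
                    n_de_overlap = a, n_de_total = counts$n_de_total,
                    n_bg_overlap = counts$n_bg_overlap,
                    n_bg_total = counts$n_bg_total,
                    odds_observed = odds_obs, odds_background = odds_bg,
                    odds_ratio = or,
                    or_cmle = unname(ft$estimate),
                    ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
                    p = ft$p.value, stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Enrichment of a DE probe set across a collection of tracks
#'
#' Convenience wrapper running [count_annotation_overlaps()] and
#' [fisher_enrichment()] per named track.
#'
#' @inheritParams count_annotation_overlaps
#' @param tracks named list of `GRanges`.
#' @param ... passed to [count_annotation_overlaps()].
#' @return data.frame, one row per track.
#' @export
enrich_tracks <- function(de_probes, background_probes, tracks,
                          direction = "all", ...) {
  stopifnot(length(names(tracks)) == length(tracks))
  res <- lapply(names(tracks), function(nm) {
    fisher_enrichment(count_annotation_overlaps(
      de_probes, background_probes, tracks[[nm]], annotation = nm,
      direction = direction, ...))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' One-sided hypergeometric gene-set over-representation test
#'
#' Tests each gene set for over-representation of DE genes, with the
#' universe restricted to genes measured on the array that passed
#' nonspecific filtering.  Sets are intersected with the universe before
#' testing.
#'
#' @param de_genes character vector of DE gene ids (must be a subset of
#'   the universe).
#' @param universe_genes character vector, the gene universe.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return data.frame with one row per set: `set`, `p`,
#'   `expected_count`, `observed_count`, `set_size`, `odds_ratio`.
#' @export
hypergeometric_geneset_test <- function(de_genes, universe_genes, gene_sets) {
  universe_genes <- unique(universe_genes)
  if (!length(universe_genes)) stop("empty gene universe")
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% universe_genes)) {
    stop("DE genes must be a subset of the universe")
  }
  N <- length(universe_genes); k <- length(de_genes)
  res <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe_genes)
    m <- length(s)
    obs <- length(intersect(s, de_genes))
    p <- phyper(obs - 1, m, N - m, k, lower.tail = FALSE)
    numer <- obs * (N - m - k + obs)
    denom <- (k - obs) * (m - obs)
    or <- if (denom == 0) Inf else numer / denom
    data.frame(set = nm, p = p, expected_count = m * k / N,
               observed_count = obs, set_size = m, odds_ratio = or,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compare conservation score distributions by two-sample KS
#'
#' Compares per-probe mean conservation scores of two probe groups by a
#' two-sample Kolmogorov-Smirnov test and returns the empirical
#' cumulative distribution curves for plotting.
#'
#' @param scores_a,scores_b numeric vectors (>= 2 values each).
#' @param labels length-2 character vector naming the groups.
#' @return list with `statistic`, `p.value` and `ecdf` (long-format
#'   data.frame: `group`, `score`, `ecdf`).
#' @export
conservation_ecdf_compare <- function(scores_a, scores_b,
                                      labels = c("a", "b")) {
  if (length(scores_a) < 2 || length(scores_b) < 2) {
    stop("need at least 2 scores per group")
  }
  ks <- suppressWarnings(ks.test(scores_a, scores_b))
  mk <- function(x, lab) {
    x <- sort(x)
    data.frame(group = lab, score = x, ecdf = seq_along(x) / length(x),
               stringsAsFactors = FALSE)
  }
  list(statistic = unname(ks$statistic), p.value = ks$p.value,
       ecdf = rbind(mk(scores_a, labels[1]), mk(scores_b, labels[2])))
}
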