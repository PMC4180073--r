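# Consistency calls for chromatin-associated lncRNA regions (CARs).
# CAR strand is unknown, so every probe overlapping a CAR by at least
# one nucleotide counts, regardless of reading direction.  A CAR with
# significant overlapping probes is consistent_down when all their fold
# changes are negative, consistent_up when all are positive, otherwise
# inconsistent (a zero fold change among significant probes also counts
# as inconsistent).

#' Classify CARs by direction-consistency of their DE probes
#'
#' @param cars `GRanges` with a `car_id` metadata column (strand
#'   ignored).
#' @param probes `GRanges` of expression probes with `probe_id`.
#' @param de_table DE results (columns `probe_id`, `log2fc`, `fdr`).
#' @param fdr_cut significance cutoff (default 0.05).
#' @return list with `records` (data.frame `car_id`, `call`, `n_probes`,
#'   `n_significant`) and `summary` (named counts per call).  CARs with
#'   no probe on the array are called `not_represented` and excluded
#'   from the summary denominators.
#' @export
classify_cars <- function(cars, probes, de_table, fdr_cut = 0.05) {
  stopifnot("car_id" %in% names(mcols(cars)))
  hits <- suppressWarnings(findOverlaps(cars, probes, ignore.strand = TRUE))
  sig <- de_table[de_table$fdr < fdr_cut, , drop = FALSE]
  calls <- character(length(cars))
  n_probes <- integer(length(cars))
  n_sig <- integer(length(cars))
  for (i in seq_along(cars)) {
    pidx <- subjectHits(hits)[queryHits(hits) == i]
    ids <- as.character(probes$probe_id[pidx])
    n_probes[i] <- length(ids)
    if (!length(ids)) { calls[i] <- "not_represented"; next }
    lfc <- sig$log2fc[match(intersect(ids, sig$probe_id), sig$probe_id)]
    n_sig[i] <- length(lfc)
    calls[i] <- if (!length(lfc)) "not_significant"
      else if (all(lfc < 0)) "consistent_down"
      else if (all(lfc > 0)) "consistent_up"
      else "inconsistent"
  }
  records <- data.frame(car_id = as.character(cars$car_id), call = calls,
                        n_probes = n_probes, n_significant = n_sig,
                        stringsAsFactors = FALSE)
  lev <- c("consistent_down", "consistent_up", "inconsistent",
           "not_significant", "not_represented")
  summary <- vapply(lev, function(l) sum(calls == l), 1L)
  list(records = records, summary = summary)
}
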