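# The three-step coding-evidence filter.  Probes overlapping
# protein-coding exons on any strand are coding (or, when the overlap is
# opposite-strand only and no same-strand coding segment covers the
# probe, antisense non-coding).  Remaining probes are discarded when a
# significant coding-potential segment covers them (step 2) or when,
# outside the coding-scan coverage mask, a translated protein-similarity
# hit covers them (step 3).  Survivors are bona fide non-coding,
# intronic when inside a protein-coding gene span, else intergenic.

#' Bundle coding-evidence tracks
#'
#' @param coding_segments stranded `GRanges` with numeric `p` metadata
#'   column (p-value of a coding-potential segment; deliberately not
#'   multiplicity-adjusted, to minimise regions falsely called
#'   non-coding).
#' @param coverage_mask `GRanges` where the coding scan had enough
#'   alignment depth to classify at all; segments must lie inside it.
#' @param protein_hits `GRanges` of translated similarity hits against
#'   known proteins.
#' @param p_threshold significance cutoff on segment p-values
#'   (default 0.05).
#' @return list of class `coding_evidence`.
#' @export
coding_evidence <- function(coding_segments, coverage_mask, protein_hits,
                            p_threshold = 0.05) {
  stopifnot(is(coding_segments, "GRanges"), is(coverage_mask, "GRanges"),
            is(protein_hits, "GRanges"))
  if (!"p" %in% names(mcols(coding_segments))) {
    stop("coding_segments need a 'p' metadata column")
  }
  p <- coding_segments$p
  if (any(p <= 0 | p > 1)) stop("segment p-values must lie in (0, 1]")
  if (length(coding_segments) &&
      !all(.covered_fraction(coding_segments, coverage_mask) >= 1)) {
    stop("coding segments must lie inside the coverage mask")
  }
  structure(list(coding_segments = coding_segments,
                 coverage_mask = coverage_mask,
                 protein_hits = protein_hits,
                 p_threshold = p_threshold),
            class = "coding_evidence")
}

#' Classify probes into coding / non-coding strata
#'
#' Applies the three-step filter and the antisense rule, assigning every
#' probe exactly one stratum:
#' `coding_exonic`, `antisense_noncoding`, `excluded_coding_evidence`,
#' `excluded_protein_similarity`, `bona_fide_intronic` or
#' `bona_fide_intergenic`.
#'
#' @param probes `GRanges` with `probe_id`, `role`, `uniquely_mapped`
#'   metadata; only uniquely mapped expression probes are admitted.
#' @param models `gene_models`; the union of protein-coding exon sources
#'   should already be merged into the models passed here.
#' @param evidence `coding_evidence` object.
#' @param genome optional named chromosome lengths; probes on
#'   chromosomes absent from it raise an error.
#' @param step2_strand `"any"` (default, conservative: a significant
#'   segment on either strand disqualifies an intronic/intergenic probe;
#'   the coding scan runs in all six reading frames) or `"same"`.
#' @return data.frame with columns `probe_id`, `stratum`.
#' @export
classify_probes <- function(probes, models, evidence, genome = NULL,
                            step2_strand = c("any", "same")) {
  step2_strand <- match.arg(step2_strand)
  stopifnot(is(evidence, "coding_evidence"))
  probes <- probes[probes$role == "expression"]
  if (!all(probes$uniquely_mapped)) {
    stop("all expression probes entering classification must be uniquely mapped")
  }
  if (!is.null(genome)) {
    bad <- !(as.character(seqnames(probes)) %in% names(genome))
    if (any(bad)) {
      stop("probes on unknown chromosome: ",
           paste(unique(as.character(seqnames(probes))[bad]), collapse = ", "))
    }
  }
  pc_exons <- exon_track(models, biotype = "protein_coding")
  pc_spans <- models$genes[models$genes$biotype == "protein_coding"]
  sig_seg <- evidence$coding_segments[
    evidence$coding_segments$p < evidence$p_threshold]

  ex_any <- overlaps_any_nt(probes, pc_exons, "ignore")
  ex_same <- overlaps_any_nt(probes, pc_exons, "same")
  seg_same <- overlaps_any_nt(probes, sig_seg, "same")
  seg_any <- overlaps_any_nt(probes, sig_seg, "ignore")
  in_mask <- .covered_fraction(probes, evidence$coverage_mask) > 0
  prot <- overlaps_any_nt(probes, evidence$protein_hits, "ignore")
  in_span <- overlaps_any_nt(probes, pc_spans, "ignore")

  stratum <- character(length(probes))
  antisense <- ex_any & !ex_same & !seg_same
  stratum[ex_any] <- ifelse(antisense[ex_any], "antisense_noncoding",
                            "coding_exonic")
  rest <- !ex_any
  step2 <- rest & (if (step2_strand == "any") seg_any else seg_same)
  stratum[step2] <- "excluded_coding_evidence"
  rest <- rest & !step2
  step3 <- rest & !in_mask & prot
  stratum[step3] <- "excluded_protein_similarity"
  rest <- rest & !step3
  stratum[rest] <- ifelse(in_span[rest], "bona_fide_intronic",
                          "bona_fide_intergenic")
  data.frame(probe_id = probes$probe_id, stratum = stratum,
             stringsAsFactors = FALSE)
}

#' Calibrate the coding-evidence significance threshold
#'
#' For a grid of candidate p-value cutoffs, computes sensitivity (the
#' fraction of known protein-coding exons covered by a significant
#' segment at that cutoff) and specificity (the fraction of matched
#' random intervals -- typically sampled to preserve the exon length
#' distribution and repeat content -- NOT covered by one).
#'
#' @param cutoffs numeric vector of candidate p-value cutoffs.
#' @param positives `GRanges` of known coding exons.
#' @param negatives `GRanges` of matched sampled intervals (see
#'   [sample_matched_intervals()]).
#' @param evidence `coding_evidence` object.
#' @return data.frame with columns `cutoff`, `sensitivity`,
#'   `specificity`; sensitivity is non-decreasing and specificity
#'   non-increasing in the cutoff.
#' @export
calibrate_coding_threshold <- function(cutoffs, positives, negatives,
                                       evidence) {
  stopifnot(is(evidence, "coding_evidence"))
  if (!length(evidence$coding_segments)) stop("empty coding evidence")
  if (!length(positives) || !length(negatives)) {
    stop("positive and negative sets must be non-empty")
  }
  segs <- evidence$coding_segments
  res <- lapply(sort(cutoffs), function(ct) {
    sig <- segs[segs$p < ct]
    data.frame(cutoff = ct,
               sensitivity = mean(overlaps_any_nt(positives, sig, "ignore")),
               specificity = mean(!overlaps_any_nt(negatives, sig, "ignore")))
  })
  do.call(rbind, res)
}
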