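# Interval engine: overlap fractions, any-nucleotide overlap queries,
# nearest protein-coding gene, and matched random-interval sampling.
# All coordinates are held in GRanges (1-based, closed); BED input is
# converted on read by rtracklayer.  Strand "*" means unknown and is
# treated as compatible with either strand in strand-filtered queries
# (the array design targets both strands for unknown-strand loci).

#' Construct a gene-model set
#'
#' Bundles gene spans and their exons into a validated container used by
#' all interval queries.  Exons of a gene must share one chromosome and
#' strand; overlapping exons are merged.  The span of a gene is the range
#' covering all of its exons.
#'
#' @param genes `GRanges` of gene spans with metadata columns `gene_id`,
#'   `name` and `biotype` (one of `"protein_coding"`, `"lncRNA"`,
#'   `"other"`).
#' @param exons `GRangesList` named by `gene_id`, one element per gene.
#' @return An object of class `gene_models` with elements `genes` and
#'   `exons`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(is(genes, "GRanges"), is(exons, "GRangesList"))
  need <- c("gene_id", "name", "biotype")
  if (!all(need %in% names(mcols(genes)))) {
    stop("gene spans need metadata columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  if (!setequal(names(exons), genes$gene_id)) {
    stop("exon list names must match gene_ids")
  }
  if (!length(genes)) {
    return(structure(list(genes = genes,
                          exons = GenomicRanges::GRangesList()),
                     class = "gene_models"))
  }
  exons <- exons[as.character(genes$gene_id)]
  merged <- lapply(exons, function(e) {
    if (length(unique(as.character(seqnames(e)))) != 1L ||
        length(unique(as.character(strand(e)))) != 1L) {
      stop("all exons of a gene must share one chromosome and strand")
    }
    GenomicRanges::reduce(e)
  })
  exons <- GenomicRanges::GRangesList(merged)
  # recompute spans from merged exons so span == range(exons) always holds
  sp_chrom <- vapply(merged, function(e) as.character(seqnames(e))[1], "")
  if (any(sp_chrom != as.character(seqnames(genes)))) {
    stop("exons must lie on the gene's chromosome")
  }
  spans <- GRanges(factor(sp_chrom, levels = GenomeInfoDb::seqlevels(genes)),
                   IRanges(vapply(merged, function(e) min(start(e)), 1L),
                           vapply(merged, function(e) max(end(e)), 1L)),
                   strand = strand(genes),
                   seqlengths = GenomeInfoDb::seqlengths(genes))
  mcols(spans) <- mcols(genes)
  structure(list(genes = spans, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  bt <- table(x$genes$biotype)
  cat("gene_models:", length(x$genes), "genes (",
      paste(names(bt), as.integer(bt), collapse = ", "), ")\n")
  invisible(x)
}

#' All exons of a gene-model set as one track
#'
#' @param models `gene_models` object.
#' @param biotype optional biotype filter (e.g. `"protein_coding"`).
#' @return `GRanges` of exons carrying a `gene_id` column.
#' @export
exon_track <- function(models, biotype = NULL) {
  keep <- models$genes
  if (!is.null(biotype)) keep <- keep[keep$biotype %in% biotype]
  ex <- models$exons[as.character(keep$gene_id)]
  out <- unlist(ex, use.names = FALSE)
  out$gene_id <- rep(as.character(keep$gene_id), lengths(ex))
  out
}

#' Intron track of a gene-model set
#'
#' Introns are the gene span minus its merged exons.
#'
#' @inheritParams exon_track
#' @return `GRanges` of introns with a `gene_id` column.
#' @export
intron_track <- function(models, biotype = NULL) {
  keep <- models$genes
  if (!is.null(biotype)) keep <- keep[keep$biotype %in% biotype]
  if (!length(keep)) return(GRanges(gene_id = character(0)))
  ex <- unlist(models$exons[as.character(keep$gene_id)], use.names = FALSE)
  intr <- GenomicRanges::setdiff(keep, ex, ignore.strand = FALSE)
  hits <- suppressWarnings(findOverlaps(intr, keep, ignore.strand = FALSE, type = "within"))
  intr <- intr[queryHits(hits)]
  intr$gene_id <- as.character(keep$gene_id)[subjectHits(hits)]
  intr
}

# concatenate GRanges (list or ...), dropping empties and silencing the
# harmless seqlevel-merge warning when inputs saw different chromosomes
.c_gr <- function(xs) {
  xs <- xs[vapply(xs, length, 1L) > 0]
  if (!length(xs)) return(GRanges())
  if (length(xs) == 1) return(xs[[1]])
  suppressWarnings(do.call(c, xs))
}

# strand compatibility of query/subject hit pairs under a filter mode;
# "*" on either side is compatible with anything
.strand_ok <- function(qs, ss, strand_mode) {
  qs <- as.character(qs); ss <- as.character(ss)
  unknown <- qs == "*" | ss == "*"
  switch(strand_mode,
    ignore   = rep(TRUE, length(qs)),
    same     = unknown | qs == ss,
    opposite = unknown | qs != ss,
    stop("unknown strand_mode: ", strand_mode)
  )
}

#' Maximum single-interval overlap fraction
#'
#' For each query interval, the maximum over *single* track intervals of
#' (overlapping bases / query length).  This is the quantity behind the
#' "at least 90% of the probe inside one annotation interval" overlap
#' rule; two abutting track intervals each covering half the probe give
#' 0.5, not 1.  Set `union = TRUE` to instead measure coverage by the
#' union of all passing track intervals.
#'
#' @param query `GRanges` of probes/intervals (positive widths).
#' @param track `GRanges` annotation track.
#' @param strand_mode `"ignore"`, `"same"` or `"opposite"`; `"*"` strands
#'   match anything.
#' @param union measure coverage by the union of track intervals instead
#'   of the best single interval.
#' @return numeric vector in \[0, 1\], one value per query; intervals on
#'   chromosomes absent from the track get 0.
#' @export
overlap_fraction <- function(query, track,
                             strand_mode = c("ignore", "same", "opposite"),
                             union = FALSE) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(all(width(query) > 0L))
  out <- numeric(length(query))
  if (!length(track) || !length(query)) return(out)
  if (union) track <- .filtered_union(query, track, strand_mode)
  hits <- suppressWarnings(findOverlaps(query, track, ignore.strand = TRUE))
  if (!length(hits)) return(out)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  if (!union) {
    ok <- .strand_ok(strand(query)[qh], strand(track)[sh], strand_mode)
    qh <- qh[ok]; sh <- sh[ok]
  }
  if (!length(qh)) return(out)
  ov <- width(pintersect(granges(query)[qh], granges(track)[sh],
                         ignore.strand = TRUE))
  frac <- ov / width(query)[qh]
  if (union) {
    agg <- tapply(frac, qh, sum)   # union track is disjoint per strand-pass
  } else {
    agg <- tapply(frac, qh, max)
  }
  out[as.integer(names(agg))] <- as.numeric(agg)
  pmin(out, 1)
}

# reduce the track per query-strand-compatibility; for union mode we
# simply reduce the whole track when mode is ignore, otherwise keep
# stranded reduction and let the per-pair strand filter run downstream.
.filtered_union <- function(query, track, strand_mode) {
  if (strand_mode == "ignore") {
    return(GenomicRanges::reduce(track, ignore.strand = TRUE))
  }
  GenomicRanges::reduce(track, ignore.strand = FALSE)
}

#' Any-nucleotide overlap
#'
#' TRUE iff at least one base of the query lies in at least one track
#' interval passing the strand filter.
#'
#' @inheritParams overlap_fraction
#' @return logical vector, one value per query.
#' @export
overlaps_any_nt <- function(query, track,
                            strand_mode = c("ignore", "same", "opposite")) {
  strand_mode <- match.arg(strand_mode)
  out <- logical(length(query))
  if (!length(track) || !length(query)) return(out)
  hits <- suppressWarnings(findOverlaps(query, track, ignore.strand = TRUE))
  if (!length(hits)) return(out)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  ok <- .strand_ok(strand(query)[qh], strand(track)[sh], strand_mode)
  out[unique(qh[ok])] <- TRUE
  out
}

#' Nearest protein-coding gene
#'
#' For each query interval, the nearest protein-coding gene and the gap
#' distance in bases, independent of reading strand.  In `gene_body` mode
#' the distance is 0 when the interval overlaps the gene span and
#' otherwise the number of bases between the interval and the nearest
#' span boundary.  In `tss` mode the distance is measured to the
#' strand-aware transcription start coordinate.  Ties are broken by the
#' lexicographically smallest `gene_id` (deterministic).
#'
#' @param query `GRanges` of intervals.
#' @param models `gene_models` object (only `protein_coding` genes are
#'   considered).
#' @param mode `"gene_body"` or `"tss"`.
#' @return data.frame with columns `gene_id` (NA if no protein-coding
#'   gene shares the chromosome) and `distance` (`Inf` sentinel in that
#'   case).
#' @export
nearest_protein_coding_gene <- function(query, models,
                                        mode = c("gene_body", "tss")) {
  mode <- match.arg(mode)
  genes <- models$genes[models$genes$biotype == "protein_coding"]
  if (!length(genes)) stop("no protein-coding genes in the model set")
  ord <- order(as.character(genes$gene_id))
  genes <- genes[ord]
  n <- length(query)
  gene_id <- rep(NA_character_, n)
  distance <- rep(Inf, n)
  if (!n) return(data.frame(gene_id = gene_id, distance = distance))
  qchrom <- as.character(seqnames(query))
  gchrom <- as.character(seqnames(genes))
  if (mode == "tss") {
    pos <- ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
  }
  for (chr in unique(qchrom)) {
    qi <- which(qchrom == chr)
    gi <- which(gchrom == chr)
    if (!length(gi)) next
    qs <- start(query)[qi]; qe <- end(query)[qi]
    if (mode == "gene_body") {
      gs <- start(genes)[gi]; ge <- end(genes)[gi]
      # gap bases between closed intervals; 0 when overlapping or abutting
      d <- pmax(outer(qs, ge, function(q, g) q - g - 1L),
                outer(qe, gs, function(q, g) g - q - 1L), 0L)
    } else {
      p <- pos[gi]
      d <- pmax(outer(qs, p, function(q, g) q - g),
                outer(qe, p, function(q, g) g - q), 0L)
    }
    best <- max.col(-d, ties.method = "first")
    gene_id[qi] <- as.character(genes$gene_id)[gi[best]]
    distance[qi] <- d[cbind(seq_along(qi), best)]
  }
  data.frame(gene_id = gene_id, distance = distance,
             stringsAsFactors = FALSE)
}

# union-coverage fraction of each interval by a (reduced) track
.covered_fraction <- function(x, track) {
  track <- GenomicRanges::reduce(track, ignore.strand = TRUE)
  out <- numeric(length(x))
  hits <- suppressWarnings(findOverlaps(x, track, ignore.strand = TRUE))
  if (!length(hits)) return(out)
  ov <- width(pintersect(granges(x)[queryHits(hits)],
                         granges(track)[subjectHits(hits)],
                         ignore.strand = TRUE))
  agg <- tapply(ov, queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out / width(x)
}

#' Sample random intervals matched to a template set
#'
#' Draws `n` intervals uniformly over the allowed genomic space (the
#' genome minus an exclusion track), with lengths drawn with replacement
#' from the template lengths.  With `matching = "length_and_repeat"`,
#' candidates are rejection-sampled until their repeat-base fraction lies
#' within `repeat_tol` of their template's; this mirrors null sets built
#' by sampling intergenic intervals that preserve the length distribution
#' and repeat content of protein-coding exons.
#'
#' @param n number of intervals to draw.
#' @param templates `GRanges` of template intervals (lengths, and repeat
#'   fractions when matching repeats, are taken from these).
#' @param genome named integer vector of chromosome lengths.
#' @param exclusion `GRanges` to avoid entirely, or `NULL`.
#' @param matching `"length_only"` or `"length_and_repeat"`.
#' @param repeat_track `GRanges` of repeat elements (required when
#'   matching repeat content).
#' @param repeat_tol absolute tolerance on the repeat fraction (default
#'   0.1).
#' @param max_attempts rejection-sampling budget per interval.
#' @param seed optional integer seed; results are deterministic given it.
#' @return `GRanges` of `n` sampled intervals (strand `*`).
#' @export
sample_matched_intervals <- function(n, templates, genome, exclusion = NULL,
                                     matching = c("length_only",
                                                  "length_and_repeat"),
                                     repeat_track = NULL, repeat_tol = 0.1,
                                     max_attempts = 10000, seed = NULL) {
  matching <- match.arg(matching)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(templates) > 0, n >= 0)
  if (matching == "length_and_repeat" && is.null(repeat_track)) {
    stop("repeat_track required for length_and_repeat matching")
  }
  gspace <- GRanges(names(genome),
                    IRanges(1L, as.integer(unname(genome))))
  allowed <- if (is.null(exclusion) || !length(exclusion)) gspace else
    GenomicRanges::setdiff(gspace, exclusion, ignore.strand = TRUE)
  if (!length(allowed)) stop("exclusion track covers the whole genome")
  a_chrom <- as.character(seqnames(allowed))
  a_start <- start(allowed); a_w <- width(allowed)
  idx <- sample.int(length(templates), n, replace = TRUE)
  lens <- width(templates)[idx]
  if (n == 0) return(GRanges())
  if (any(lens > max(a_w))) {
    stop("no allowed segment can host an interval of length ", max(lens))
  }
  t_rf <- if (matching == "length_and_repeat")
    .covered_fraction(templates, repeat_track) else NULL

  # vectorised uniform draw over all valid placements, per unique length
  draw <- function(lens_sub) {
    st <- integer(length(lens_sub)); ch <- character(length(lens_sub))
    for (L in unique(lens_sub)) {
      at <- which(lens_sub == L)
      host <- which(a_w >= L)
      w <- a_w[host] - L + 1
      s <- host[sample.int(length(host), length(at), replace = TRUE,
                           prob = w)]
      off <- as.integer(floor(runif(length(at)) * (a_w[s] - L + 1)))
      st[at] <- a_start[s] + off
      ch[at] <- a_chrom[s]
    }
    GRanges(ch, IRanges(st, width = lens_sub))
  }

  if (matching == "length_only") {
    out <- draw(lens)
  } else {
    out_start <- integer(n); out_chrom <- character(n)
    todo <- seq_len(n)
    for (round in seq_len(max_attempts)) {
      if (!length(todo)) break
      cand <- draw(lens[todo])
      rf <- .covered_fraction(cand, repeat_track)
      ok <- abs(rf - t_rf[idx[todo]]) <= repeat_tol
      out_start[todo[ok]] <- start(cand)[ok]
      out_chrom[todo[ok]] <- as.character(seqnames(cand))[ok]
      todo <- todo[!ok]
    }
    if (length(todo)) {
      i <- todo[1]
      stop("rejection sampling failed after ", max_attempts,
           " attempts: no interval of length ", lens[i],
           " with repeat fraction within ", repeat_tol, " of ",
           signif(t_rf[idx[i]], 3))
    }
    out <- GRanges(out_chrom, IRanges(out_start, width = lens))
  }
  strand(out) <- "*"
  out
}
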