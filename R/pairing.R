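# Pairing of non-coding DE probes with protein-coding genes and
# converse/synonymous quadrant classification.  Intergenic probes pair
# with their nearest protein-coding gene (nearest among ALL
# protein-coding genes, the pair then retained only if that gene is
# itself DE), intronic probes with their host gene, antisense probes
# with the gene whose exon they overlap on the opposite strand.
# Exclusion rule for potentially unannotated distant exons: same-strand
# pairs are accepted only when the two fold changes have opposite signs;
# opposite-strand (or unknown-strand) pairs are always accepted.

#' Gene-level fold change from exonic probes
#'
#' The gene-level log2 fold change is the signed fold change of the
#' significantly DE exonic probe with the maximal absolute fold change.
#' Genes with no significant exonic probe are omitted (they cannot enter
#' pairing).
#'
#' @param de_table DE result data.frame from [fit_moderated_t()]
#'   (columns `probe_id`, `log2fc`, `fdr`).
#' @param exonic_map data.frame mapping exonic probes to genes (columns
#'   `probe_id`, `gene_id`).
#' @param fdr_cut significance cutoff (default 0.05).
#' @return data.frame `gene_id`, `gene_log2fc`.
#' @export
gene_level_fold_change <- function(de_table, exonic_map, fdr_cut = 0.05) {
  m <- merge(exonic_map, de_table, by = "probe_id")
  m <- m[m$fdr < fdr_cut, , drop = FALSE]
  if (!nrow(m)) {
    return(data.frame(gene_id = character(0), gene_log2fc = numeric(0)))
  }
  m <- m[order(m$gene_id, -abs(m$log2fc), m$probe_id), ]
  keep <- !duplicated(m$gene_id)
  data.frame(gene_id = m$gene_id[keep], gene_log2fc = m$log2fc[keep],
             stringsAsFactors = FALSE)
}

.quadrant <- function(probe_lfc, gene_lfc) {
  ifelse(probe_lfc > 0 & gene_lfc <= 0, "converse_probe_up_gene_down",
  ifelse(probe_lfc <= 0 & gene_lfc > 0, "converse_probe_down_gene_up",
  ifelse(probe_lfc > 0, "synonymous_both_up", "synonymous_both_down")))
}

#' Build lncRNA-mRNA pairs
#'
#' Pairs every significant non-coding probe with a protein-coding gene
#' according to its stratum and applies the strand exclusion rule (see
#' the module header).  Rejected same-strand synonymous pairs are kept
#' in the output with `accepted = FALSE`.
#'
#' @param probes `GRanges` with `probe_id` metadata.
#' @param probe_class data.frame from [classify_probes()].
#' @param de_table DE results (columns `probe_id`, `log2fc`, `fdr`).
#' @param models `gene_models`.
#' @param exonic_map data.frame `probe_id`, `gene_id` for coding exonic
#'   probes (used for gene-level fold changes).
#' @param fdr_cut significance cutoff applied to both sides
#'   (default 0.05).
#' @return data.frame of pair records: `probe_id`, `gene_id`,
#'   `relation`, `probe_log2fc`, `gene_log2fc`, `distance`, `quadrant`,
#'   `accepted`.
#' @export
build_lnc_mrna_pairs <- function(probes, probe_class, de_table, models,
                                 exonic_map, fdr_cut = 0.05) {
  gene_fc <- gene_level_fold_change(de_table, exonic_map, fdr_cut)
  de_sig <- de_table[de_table$fdr < fdr_cut, , drop = FALSE]
  nc_strata <- c(bona_fide_intergenic = "intergenic_proximal",
                 bona_fide_intronic = "intronic",
                 antisense_noncoding = "antisense_overlap")
  cls <- probe_class[probe_class$stratum %in% names(nc_strata) &
                     probe_class$probe_id %in% de_sig$probe_id, ,
                     drop = FALSE]
  if (!nrow(cls)) {
    return(data.frame(probe_id = character(0), gene_id = character(0),
                      relation = character(0), probe_log2fc = numeric(0),
                      gene_log2fc = numeric(0), distance = numeric(0),
                      quadrant = character(0), accepted = logical(0)))
  }
  pid <- as.character(probes$probe_id)
  pc_spans <- models$genes[models$genes$biotype == "protein_coding"]
  pc_exons <- exon_track(models, biotype = "protein_coding")
  rows <- vector("list", nrow(cls))
  for (i in seq_len(nrow(cls))) {
    id <- cls$probe_id[i]
    stratum <- cls$stratum[i]
    pr <- probes[match(id, pid)]
    gid <- NA_character_; dist <- NA_real_
    if (stratum == "bona_fide_intergenic") {
      nn <- nearest_protein_coding_gene(pr, models, mode = "gene_body")
      gid <- nn$gene_id; dist <- nn$distance
    } else if (stratum == "bona_fide_intronic") {
      host <- pc_spans[overlaps_any_nt(pc_spans, pr, "ignore")]
      if (!length(host)) {
        stop("intronic probe ", id, " has no host protein-coding gene")
      }
      gid <- sort(as.character(host$gene_id))[1]
      dist <- 0
    } else { # antisense_overlap
      hit_ex <- pc_exons[overlaps_any_nt(pc_exons, pr, "ignore")]
      ok <- .strand_ok(rep(as.character(strand(pr)), length(hit_ex)),
                       as.character(strand(hit_ex)), "opposite")
      hit_ex <- hit_ex[ok]
      if (!length(hit_ex)) next  # exon overlap vanished (shouldn't happen)
      gid <- sort(unique(as.character(hit_ex$gene_id)))[1]
      dist <- 0
    }
    if (is.na(gid) || !(gid %in% gene_fc$gene_id)) next  # gene not DE
    plfc <- de_sig$log2fc[match(id, de_sig$probe_id)]
    glfc <- gene_fc$gene_log2fc[match(gid, gene_fc$gene_id)]
    gstrand <- as.character(strand(pc_spans))[
      match(gid, as.character(pc_spans$gene_id))]
    pstrand <- as.character(strand(pr))
    same_strand <- pstrand != "*" && gstrand != "*" && pstrand == gstrand
    quad <- .quadrant(plfc, glfc)
    accepted <- !(same_strand && sign(plfc) == sign(glfc))
    rows[[i]] <- data.frame(probe_id = id, gene_id = gid,
                            relation = unname(nc_strata[stratum]),
                            probe_log2fc = plfc, gene_log2fc = glfc,
                            distance = dist, quadrant = quad,
                            accepted = accepted, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(probe_id = character(0), gene_id = character(0),
                      relation = character(0), probe_log2fc = numeric(0),
                      gene_log2fc = numeric(0), distance = numeric(0),
                      quadrant = character(0), accepted = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' Quadrant summary of accepted pairs
#'
#' Counts, per relation and quadrant, the unique protein-coding genes (a
#' gene counts in a quadrant when at least one accepted pair places it
#' there) and the probes involved.
#'
#' @param pairs data.frame from [build_lnc_mrna_pairs()].
#' @return data.frame `relation`, `quadrant`, `n_genes`, `n_probes`.
#' @export
quadrant_counts <- function(pairs) {
  quads <- c("converse_probe_up_gene_down", "converse_probe_down_gene_up",
             "synonymous_both_up", "synonymous_both_down")
  rels <- c("intergenic_proximal", "intronic", "antisense_overlap")
  acc <- pairs[pairs$accepted, , drop = FALSE]
  out <- expand.grid(relation = rels, quadrant = quads,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_genes <- mapply(function(r, q) {
    length(unique(acc$gene_id[acc$relation == r & acc$quadrant == q]))
  }, out$relation, out$quadrant)
  out$n_probes <- mapply(function(r, q) {
    length(unique(acc$probe_id[acc$relation == r & acc$quadrant == q]))
  }, out$relation, out$quadrant)
  out[order(out$relation, out$quadrant), ]
}

#' KS test of observed nearest-gene distances against a matched null
#'
#' Compares the distances of intergenic non-coding DE probes to their
#' nearest protein-coding gene against distances of random length-60
#' intergenic intervals (generated by [sample_matched_intervals()] with
#' the gene spans excluded).
#'
#' @param observed numeric vector of observed distances.
#' @param null numeric vector of null distances.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list `statistic`, `p.value`.
#' @export
distance_to_nearest_ks <- function(observed, null,
                                   alternative = "two.sided") {
  if (!length(observed) || !length(null)) stop("empty distance sample")
  ks <- suppressWarnings(ks.test(observed, null, alternative = alternative))
  list(statistic = unname(ks$statistic), p.value = ks$p.value)
}
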